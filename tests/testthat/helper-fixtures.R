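# Shared fixtures: small deterministic cohorts and rosters built in code.

default_cfg <- task_config()

# Deterministic roster of noiseless, zero-latency threshold agents with a
# fixed k grid (for recovery-style tests).
k_grid_roster <- function(ks, b = 0.8, noise_temp = 0, latency_mean = 0) {
  tibble::tibble(
    subject_id = sprintf("G%03d", seq_along(ks)),
    sex = rep_len(c("M", "F"), length(ks)),
    k_true = ks, b_true = b, noise_temp = noise_temp,
    latency_mean = latency_mean, seed = seq_along(ks))
}

# The largest scheduled volume at or below a threshold: what a noiseless
# threshold agent's observed rejection volume must be.
grid_snap <- function(v_star, config = default_cfg) {
  pos <- 2L
  repeat {
    v <- scheduled_volume(pos, config)
    if (v <= v_star) return(v)
    pos <- pos + 1L
  }
}

# A tiny threshold cohort reused across test files (4 subjects x 24 sessions).
tiny_cohort <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- generate_cohort(
        cohort_spec(n_per_sex = 2, noise_temp = 0, latency_mean = 0,
                    seed = 42),
        default_cfg)
    }
    val
  }
})
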