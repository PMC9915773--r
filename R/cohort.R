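#' Deterministic leave-after-n policy
#'
#' Leaves every patch after exactly `n` rewards. Useful as a brute-force
#' building block (enumerating fixed-n policies recovers the MVT optimum).
#'
#' @param n Rewards to collect per visit.
#' @return A decision rule for [simulate_session()].
#' @export
fixed_n_policy <- function(n) {
  if (!is.finite(n) || n < 1 || n != floor(n))
    stop("`n` must be a positive integer", call. = FALSE)
  force(n)
  function(cod_s, next_position, next_volume, elapsed_time) {
    if (next_position > n) "leave" else "stay"
  }
}

#' MVT-optimal policy for a given changeover delay
#'
#' Leaves after exactly [optimal_n()] rewards in every patch: the
#' rate-maximizing reference agent.
#'
#' @param config A [task_config()].
#' @param cod_s Changeover delay of the session the policy will play.
#' @return A decision rule for [simulate_session()].
#' @export
mvt_policy <- function(config = task_config(), cod_s = config$cod_s) {
  fixed_n_policy(optimal_n(cod_s, config))
}

#' Hyperbolic indifference-threshold policy
#'
#' The generative agent of the synthetic cohort. The subject values the
#' replenished alternative patch (amount `A`, delayed by the COD) at
#' `v* = b * A / (1 + k * cod_s)` — the hyperbolic discounting form — and
#' leaves the current patch when the next scheduled volume has depleted to
#' that indifference threshold or below. With logistic choice noise the
#' leave probability at each decision is
#' `plogis((v* - next_volume) / noise_temp)`; `noise_temp = 0` gives the
#' deterministic threshold rule (leave iff `next_volume <= v*`).
#'
#' @param subject A list or one-row data frame with `k_true`, `b_true` and
#'   `noise_temp` (uL), e.g. one row of a [generate_cohort()] roster.
#' @param cod_s Changeover delay of the session the policy will play.
#' @param config A [task_config()]; supplies `A = initial_volume`.
#' @return A decision rule for [simulate_session()].
#' @export
#' @examples
#' p <- threshold_policy(list(k_true = 0.1, b_true = 0.8, noise_temp = 0), 24)
threshold_policy <- function(subject, cod_s, config = task_config()) {
  k <- as.numeric(subject$k_true)
  b <- as.numeric(subject$b_true)
  temp <- as.numeric(subject$noise_temp)
  if (!is.finite(k) || k < 0) stop("`k_true` must be >= 0", call. = FALSE)
  if (!is.finite(b) || b <= 0 || b > 1)
    stop("`b_true` must lie in (0, 1]", call. = FALSE)
  if (is.na(temp) || temp < 0)
    stop("`noise_temp` must be >= 0", call. = FALSE)
  v_star <- b * config$initial_volume / (1 + k * cod_s)
  function(cod_s, next_position, next_volume, elapsed_time) {
    if (temp == 0) {
      if (next_volume <= v_star) "leave" else "stay"
    } else {
      p_leave <- stats::plogis((v_star - next_volume) / temp)
      if (stats::runif(1L) < p_leave) "leave" else "stay"
    }
  }
}

#' Specification of a synthetic cohort
#'
#' Describes the population the generator draws subjects from: per-sex
#' lognormal discount rates `k`, per-sex truncated-normal bias `b`, a shared
#' logistic choice-noise temperature, a mean response latency, and the
#' master seed. The defaults describe a moderately heterogeneous cohort
#' (median k 0.1 1/s, geometric SD 2.5, bias centred on 0.8 — the largest
#' bias observable from patch-leaving, since the first forgone volume is one
#' depletion step below the full reward) with mild choice noise and ~0.5-s
#' response latencies.
#'
#' @param n_per_sex Subjects per sex.
#' @param k_median,k_gsd Named per-sex (`M`, `F`) median and geometric SD of
#'   the lognormal discount-rate distribution (1/s). A geometric SD of 1
#'   collapses to the median. Scalars are recycled to both sexes.
#' @param b_mean,b_sd Named per-sex mean and SD of the bias, truncated to
#'   (0, 1].
#' @param noise_temp Logistic choice-noise temperature (uL); 0 = noiseless.
#' @param latency_mean Mean exponential response latency (s); 0 = none.
#' @param seed Master seed; every subject derives a private substream from
#'   it, so generation is reproducible and independent of iteration order.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_sex = 100,
                        k_median = c(M = 0.1, F = 0.1),
                        k_gsd = c(M = 2.5, F = 2.5),
                        b_mean = c(M = 0.8, F = 0.8),
                        b_sd = c(M = 0.05, F = 0.05),
                        noise_temp = 5,
                        latency_mean = 0.5,
                        seed = 1L) {
  per_sex <- function(x, what) {
    if (length(x) == 1L) x <- c(M = unname(x), F = unname(x))
    if (!all(c("M", "F") %in% names(x)))
      stop("`", what, "` must be named with sexes M and F", call. = FALSE)
    x[c("M", "F")]
  }
  spec <- list(
    n_per_sex = as.integer(n_per_sex),
    k_median = per_sex(k_median, "k_median"),
    k_gsd = per_sex(k_gsd, "k_gsd"),
    b_mean = per_sex(b_mean, "b_mean"),
    b_sd = per_sex(b_sd, "b_sd"),
    noise_temp = as.numeric(noise_temp),
    latency_mean = as.numeric(latency_mean),
    seed = as.integer(seed)
  )
  if (spec$n_per_sex < 1) stop("`n_per_sex` must be >= 1", call. = FALSE)
  if (any(spec$k_median <= 0)) stop("`k_median` must be > 0", call. = FALSE)
  if (any(spec$k_gsd < 1)) stop("`k_gsd` must be >= 1", call. = FALSE)
  if (any(spec$b_mean <= 0 | spec$b_mean > 1))
    stop("`b_mean` must lie in (0, 1]", call. = FALSE)
  if (any(spec$b_sd < 0)) stop("`b_sd` must be >= 0", call. = FALSE)
  if (spec$noise_temp < 0) stop("`noise_temp` must be >= 0", call. = FALSE)
  if (spec$latency_mean < 0) stop("`latency_mean` must be >= 0", call. = FALSE)
  structure(spec, class = "cohort_spec")
}

# Private, order-independent substream seed for subject `index`.
subject_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647
}

#' Draw one subject's generative parameters
#'
#' Draws `k_true` from the sex's lognormal and `b_true` from the sex's
#' truncated normal (rejection sampling into (0, 1]), deterministically given
#' the spec's seed and the subject's index.
#'
#' @param sex `"M"` or `"F"`.
#' @param spec A [cohort_spec()].
#' @param index Subject draw index (1-based, unique across the cohort).
#' @return A one-row tibble: `subject_id`, `sex`, `k_true`, `b_true`,
#'   `noise_temp`, `latency_mean`, `seed` (the subject's substream seed).
#' @export
make_subject <- function(sex, spec = cohort_spec(), index = 1L) {
  sex <- match.arg(sex, c("M", "F"))
  sseed <- subject_seed(spec$seed, index)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(sseed)
  k <- stats::rlnorm(1L, meanlog = log(spec$k_median[[sex]]),
                     sdlog = log(spec$k_gsd[[sex]]))
  b <- spec$b_mean[[sex]]
  if (spec$b_sd[[sex]] > 0) {
    repeat {
      b <- stats::rnorm(1L, spec$b_mean[[sex]], spec$b_sd[[sex]])
      if (b > 0 && b <= 1) break
    }
  }
  tibble::tibble(
    subject_id = sprintf("%s%03d", sex, index),
    sex = sex, k_true = k, b_true = b,
    noise_temp = spec$noise_temp,
    latency_mean = spec$latency_mean,
    seed = sseed)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a full synthetic study dataset
#'
#' Simulates every subject of a cohort through the complete session schedule
#' (`n_cycles` repetitions of `cod_cycle`, in order), each session played by
#' the subject's policy. Two policies are available: `"threshold"` — the
#' hyperbolic indifference-threshold agent parameterized by the subject's
#' `k_true`/`b_true` ([threshold_policy()]), the generative counterpart of
#' the discounting fit — and `"mvt"` — the rate-maximizing reference agent
#' ([mvt_policy()]), for which latencies and choice noise are disabled so
#' its sessions are exactly optimal.
#'
#' @param spec A [cohort_spec()].
#' @param config A [task_config()].
#' @param policy `"threshold"` or `"mvt"`.
#' @param roster Optional pre-built roster (as returned in `$roster`) to
#'   simulate instead of drawing subjects — e.g. a deterministic k grid for
#'   parameter-recovery studies.
#' @return A list: `sessions` (list of `patch_session` records, in subject
#'   then schedule order) and `roster` (tibble of ground-truth
#'   [make_subject()] parameters, for recovery tests).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_per_sex = 2, seed = 7))
#' length(coh$sessions) # 4 subjects x 24 sessions
generate_cohort <- function(spec = cohort_spec(), config = task_config(),
                            policy = c("threshold", "mvt"),
                            roster = NULL) {
  policy <- match.arg(policy)
  if (is.null(roster)) {
    roster <- dplyr::bind_rows(lapply(c("M", "F"), function(sx) {
      dplyr::bind_rows(lapply(seq_len(spec$n_per_sex), function(i) {
        make_subject(sx, spec, index = (if (sx == "M") 0L else spec$n_per_sex) + i)
      }))
    }))
  } else {
    roster <- tibble::as_tibble(roster)
    needed <- c("subject_id", "sex", "k_true", "b_true", "noise_temp",
                "latency_mean", "seed")
    if (!all(needed %in% names(roster)))
      stop("`roster` must have columns ",
           paste(needed, collapse = ", "), call. = FALSE)
  }
  schedule <- rep(config$cod_cycle, times = config$n_cycles)
  sessions <- vector("list", nrow(roster) * length(schedule))
  pos <- 1L
  for (r in seq_len(nrow(roster))) {
    subj <- roster[r, ]
    old <- .Random.seed_save()
    set.seed(subj$seed)
    for (si in seq_along(schedule)) {
      cod <- schedule[si]
      pol <- if (policy == "mvt") mvt_policy(config, cod)
             else threshold_policy(subj, cod, config)
      latm <- if (policy == "mvt") 0 else subj$latency_mean
      sessions[[pos]] <- simulate_session(
        pol, config, cod_s = cod,
        subject_id = subj$subject_id, sex = subj$sex,
        session_index = si, latency_mean = latm)
      pos <- pos + 1L
    }
    .Random.seed_restore(old)
  }
  list(sessions = sessions, roster = roster)
}
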