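#' Task configuration for the sequential patch depletion procedure
#'
#' Bundles every environmental constant of the task: the initial reward
#' volume delivered on patch entry, the multiplicative retention factor
#' applied to each successive "stay" reward, the fixed interval separating
#' rewards within a patch, the changeover delay (COD) imposed on leaving,
#' the session caps, and the session schedule over which the COD varies.
#'
#' Defaults reproduce the standard procedure: a 150 uL entry reward reduced
#' 20% per presentation (retention 0.8), a 4-s inter-reward interval,
#' sessions capped at 10 min or 5 mL (whichever comes first), and a 6-session
#' COD cycle (0, 0, 6, 12, 18, 24 s) repeated 4 times with the first 0-s
#' session of each cycle excluded from analysis.
#'
#' @param initial_volume Volume (uL) of the first reward in every patch.
#' @param decay_fraction Multiplicative retention per reward; the k-th reward
#'   in a patch is `initial_volume * decay_fraction^(k-1)`. Must be in (0, 1).
#' @param inter_reward_interval Seconds between successive rewards while
#'   staying in a patch.
#' @param cod_s Changeover delay (s) for a single simulated session; ignored
#'   by schedule-level functions, which use `cod_cycle`.
#' @param session_max_duration Session time cap in seconds.
#' @param session_volume_cap Cumulative volume cap in uL; the reward that
#'   would exceed it is truncated to the cap and ends the session.
#' @param cod_cycle Ordered per-session CODs making up one schedule cycle.
#' @param n_cycles Number of times the cycle is repeated.
#' @param exclude_first_session_of_cycle Drop the first session of each cycle
#'   (the repeated 0-s session) from analysis.
#' @return A `patch_task_config` list.
#' @export
#' @examples
#' cfg <- task_config()
#' scheduled_volume(1:4, cfg)
task_config <- function(initial_volume = 150,
                        decay_fraction = 0.8,
                        inter_reward_interval = 4,
                        cod_s = 6,
                        session_max_duration = 600,
                        session_volume_cap = 5000,
                        cod_cycle = c(0, 0, 6, 12, 18, 24),
                        n_cycles = 4,
                        exclude_first_session_of_cycle = TRUE) {
  cfg <- list(
    initial_volume = as.numeric(initial_volume),
    decay_fraction = as.numeric(decay_fraction),
    inter_reward_interval = as.numeric(inter_reward_interval),
    cod_s = as.numeric(cod_s),
    session_max_duration = as.numeric(session_max_duration),
    session_volume_cap = as.numeric(session_volume_cap),
    cod_cycle = as.numeric(cod_cycle),
    n_cycles = as.integer(n_cycles),
    exclude_first_session_of_cycle = isTRUE(exclude_first_session_of_cycle)
  )
  if (!is.finite(cfg$initial_volume) || cfg$initial_volume <= 0)
    stop("`initial_volume` must be a positive volume (uL)", call. = FALSE)
  if (!is.finite(cfg$decay_fraction) ||
      cfg$decay_fraction <= 0 || cfg$decay_fraction >= 1)
    stop("`decay_fraction` must lie strictly between 0 and 1", call. = FALSE)
  if (!is.finite(cfg$inter_reward_interval) || cfg$inter_reward_interval <= 0)
    stop("`inter_reward_interval` must be positive (s)", call. = FALSE)
  if (!is.finite(cfg$cod_s) || cfg$cod_s < 0)
    stop("`cod_s` must be non-negative (s)", call. = FALSE)
  if (!is.finite(cfg$session_max_duration) || cfg$session_max_duration <= 0)
    stop("`session_max_duration` must be positive (s)", call. = FALSE)
  if (!is.finite(cfg$session_volume_cap) || cfg$session_volume_cap <= 0)
    stop("`session_volume_cap` must be positive (uL)", call. = FALSE)
  if (length(cfg$cod_cycle) < 1 || any(!is.finite(cfg$cod_cycle)) ||
      any(cfg$cod_cycle < 0))
    stop("`cod_cycle` must be a vector of non-negative delays (s)",
         call. = FALSE)
  if (cfg$n_cycles < 1)
    stop("`n_cycles` must be at least 1", call. = FALSE)
  structure(cfg, class = "patch_task_config")
}

#' @export
print.patch_task_config <- function(x, ...) {
  cat("<patch_task_config>\n")
  cat(sprintf("  reward schedule : %g uL, retention %g per reward, every %g s\n",
              x$initial_volume, x$decay_fraction, x$inter_reward_interval))
  cat(sprintf("  session caps    : %g s or %g uL\n",
              x$session_max_duration, x$session_volume_cap))
  cat(sprintf("  COD schedule    : [%s] s x %d cycles%s\n",
              paste(x$cod_cycle, collapse = ", "), x$n_cycles,
              if (x$exclude_first_session_of_cycle)
                " (first session of cycle excluded)" else ""))
  invisible(x)
}

#' Scheduled reward volume at a patch position
#'
#' The k-th reward collected without leaving a patch is the initial volume
#' geometrically depleted: `initial_volume * decay_fraction^(k-1)`. Volumes
#' are continuous uL; no rounding is applied (the canonical schedule 150,
#' 120, 96, 76.8, ... is exact under pure geometric decay).
#'
#' @param position Reward index within a visit, 1-based. Vectorized.
#' @param config A [task_config()].
#' @return Volume(s) in uL.
#' @export
scheduled_volume <- function(position, config = task_config()) {
  if (length(position) == 0) return(numeric(0))
  if (any(!is.finite(position)) || any(position < 1) ||
      any(position != floor(position)))
    stop("`position` must be a positive integer reward index", call. = FALSE)
  config$initial_volume * config$decay_fraction^(position - 1)
}

#' Simulate one session of the patch depletion task
#'
#' Runs the event loop of the procedure for an arbitrary stay/leave policy:
#' an entry reward is delivered immediately on patch entry; while the policy
#' stays, one reward is delivered every `inter_reward_interval` seconds at
#' the next scheduled (depleted) volume; on a leave the changeover delay is
#' imposed with no reward available anywhere, the alternative patch is
#' entered, and its schedule is reset to the initial volume. The session
#' terminates the instant either cap is reached: a reward that would exceed
#' the cumulative volume cap is truncated to the cap and ends the session,
#' and no event is scheduled at or beyond the time cap.
#'
#' The two response topographies of the live task (re-poking after the fixed
#' interval vs. holding the snout in the receptacle) are equivalent in reward
#' timing, so the simulator models a single decision point per reward.
#' Optional per-decision response latencies (exponential, quantized to 1 ms)
#' can be enabled so that time-based measures are not degenerate; the default
#' is zero latency, making sessions exactly periodic for deterministic
#' policies.
#'
#' @param policy A decision rule: `function(cod_s, next_position,
#'   next_volume, elapsed_time)` returning `"stay"` or `"leave"`. Stochastic
#'   policies may draw from the session RNG stream. See [threshold_policy()],
#'   [mvt_policy()], [fixed_n_policy()].
#' @param config A [task_config()].
#' @param cod_s Changeover delay for this session (defaults to the config's).
#' @param subject_id,sex,session_index Labels carried into the record.
#' @param latency_mean Mean of the exponential per-response latency (s);
#'   0 disables latencies.
#' @return A `patch_session` record: labels, a list of visits (each with
#'   `patch_id`, `entry_time`, `exit_time` — `NA` if the session ended
#'   in-patch —, `reward_times`, `reward_volumes`, `preceded_by_cod`),
#'   `termination` (`"time_cap"` or `"volume_cap"`), `total_volume` and
#'   `total_time`.
#' @export
#' @examples
#' s <- simulate_session(fixed_n_policy(2), task_config(), cod_s = 6)
#' s$termination
simulate_session <- function(policy, config = task_config(),
                             cod_s = config$cod_s,
                             subject_id = "S1", sex = "M",
                             session_index = 1L,
                             latency_mean = 0) {
  if (!is.function(policy)) stop("`policy` must be a function", call. = FALSE)
  if (!is.finite(cod_s) || cod_s < 0)
    stop("`cod_s` must be non-negative", call. = FALSE)
  # all event times live on the 1-ms grid of the decimal text representation,
  # so a written log parses back to bit-identical times
  quant <- function(t) as.numeric(sprintf("%.3f", t))
  lat <- if (latency_mean > 0) {
    function() quant(stats::rexp(1L, rate = 1 / latency_mean))
  } else {
    function() 0
  }
  t_max <- config$session_max_duration
  cap <- config$session_volume_cap
  iri <- config$inter_reward_interval

  visits <- list()
  total <- 0
  termination <- NULL
  end_time <- NA_real_

  patch <- "A"
  entry_time <- lat()
  preceded <- FALSE
  r_times <- numeric(0)
  r_vols <- numeric(0)
  pos <- 1L
  t_now <- entry_time
  exit_time <- NA_real_

  close_visit <- function(exit) {
    visits[[length(visits) + 1L]] <<- list(
      patch_id = patch, entry_time = entry_time, exit_time = exit,
      reward_times = r_times, reward_volumes = r_vols,
      preceded_by_cod = preceded)
  }

  if (entry_time >= t_max) {
    # pathological latency draw before the first poke; empty session
    return(structure(list(
      subject_id = subject_id, sex = sex,
      session_index = as.integer(session_index), cod_s = cod_s,
      visits = list(), termination = "time_cap",
      total_volume = 0, total_time = t_max), class = "patch_session"))
  }

  for (iter in seq_len(1e6L)) {
    v <- scheduled_volume(pos, config)
    truncated <- (total + v) >= cap
    if (truncated) v <- cap - total
    r_times <- c(r_times, t_now)
    r_vols <- c(r_vols, v)
    total <- total + v
    if (truncated) {
      termination <- "volume_cap"
      end_time <- t_now
      close_visit(NA_real_)
      break
    }
    decision <- policy(cod_s, pos + 1L, scheduled_volume(pos + 1L, config),
                       t_now)
    if (!is.character(decision) || length(decision) != 1L ||
        !decision %in% c("stay", "leave"))
      stop("policy returned an invalid decision (must be \"stay\" or \"leave\")",
           call. = FALSE)
    if (decision == "stay") {
      t_next <- quant(t_now + iri + lat())
      if (t_next >= t_max) {
        termination <- "time_cap"
        end_time <- t_max
        close_visit(NA_real_)
        break
      }
      t_now <- t_next
      pos <- pos + 1L
    } else {
      exit <- quant(t_now + lat())
      if (exit >= t_max) {
        termination <- "time_cap"
        end_time <- t_max
        close_visit(NA_real_)
        break
      }
      close_visit(exit)
      t_entry <- quant(exit + cod_s + lat())
      if (t_entry >= t_max) {
        termination <- "time_cap"
        end_time <- t_max
        break
      }
      patch <- if (patch == "A") "B" else "A"
      entry_time <- t_entry
      preceded <- TRUE
      r_times <- numeric(0)
      r_vols <- numeric(0)
      pos <- 1L
      t_now <- t_entry
    }
  }
  if (is.null(termination))
    stop("session did not terminate within the event budget; ",
         "check the task configuration", call. = FALSE)

  structure(list(
    subject_id = subject_id, sex = sex,
    session_index = as.integer(session_index), cod_s = cod_s,
    visits = visits, termination = termination,
    total_volume = total, total_time = end_time
  ), class = "patch_session")
}

#' @export
print.patch_session <- function(x, ...) {
  cat(sprintf("<patch_session> %s (%s) session %d, COD %g s\n",
              x$subject_id, x$sex, x$session_index, x$cod_s))
  cat(sprintf("  %d visits, %.1f uL in %.3f s, terminated by %s\n",
              length(x$visits), x$total_volume, x$total_time, x$termination))
  invisible(x)
}

#' Check a session record against the task invariants
#'
#' Verifies the structural rules every well-formed session must satisfy:
#' each visit starts at the initial volume and depletes geometrically (the
#' session's final reward may be truncated to the volume cap), patch
#' identities alternate, times are ordered, within-visit reward gaps are at
#' least the inter-reward interval, inter-visit gaps are at least the COD
#' (exactly the COD under zero latency), and the session totals respect both
#' caps.
#'
#' @param record A `patch_session`.
#' @param config The [task_config()] it was produced under.
#' @param tol Numeric tolerance for the floating-point comparisons.
#' @return Character vector of violation descriptions; empty if valid.
#' @export
validate_session <- function(record, config = task_config(), tol = 1e-8) {
  bad <- character(0)
  note <- function(...) bad <<- c(bad, sprintf(...))
  vs <- record$visits
  nv <- length(vs)
  vol_sum <- 0
  last_exit <- NULL
  for (i in seq_len(nv)) {
    v <- vs[[i]]
    k <- length(v$reward_volumes)
    if (k == 0) {
      note("visits[%d]: no rewards recorded", i)
      next
    }
    sched <- scheduled_volume(seq_len(k), config)
    dev <- abs(v$reward_volumes - sched)
    allow_trunc <- (i == nv) && identical(record$termination, "volume_cap")
    chk <- if (allow_trunc) dev[-k] else dev
    if (any(chk > tol))
      note("visits[%d]: reward_volumes violate geometric decay (first offending position %d)",
           i, which(dev > tol)[1])
    if (allow_trunc && dev[k] > tol &&
        v$reward_volumes[k] > sched[k] + tol)
      note("visits[%d]: truncated final reward exceeds its scheduled volume", i)
    if (k > 1) {
      gaps <- diff(v$reward_times)
      if (any(gaps < config$inter_reward_interval - tol))
        note("visits[%d]: within-visit reward gap shorter than the inter-reward interval", i)
    }
    if (!is.na(v$exit_time) && v$exit_time < v$entry_time - tol)
      note("visits[%d]: exit_time precedes entry_time", i)
    if (is.na(v$exit_time) && i < nv)
      note("visits[%d]: missing exit_time on a non-final visit", i)
    if (i > 1) {
      prev <- vs[[i - 1]]
      if (v$patch_id == prev$patch_id)
        note("visits[%d]: patch_id does not alternate", i)
      if (!is.na(prev$exit_time) &&
          v$entry_time < prev$exit_time + record$cod_s - tol)
        note("visits[%d]: inter-visit gap shorter than the changeover delay", i)
      if (!isTRUE(v$preceded_by_cod))
        note("visits[%d]: preceded_by_cod must be TRUE after the first visit", i)
    } else if (isTRUE(v$preceded_by_cod)) {
      note("visits[1]: preceded_by_cod must be FALSE on the first visit")
    }
    vol_sum <- vol_sum + sum(v$reward_volumes)
  }
  if (abs(vol_sum - record$total_volume) > tol * max(1, vol_sum))
    note("total_volume: %.6f does not equal the sum of reward volumes %.6f",
         record$total_volume, vol_sum)
  if (record$total_volume > config$session_volume_cap + tol)
    note("total_volume: exceeds the session volume cap")
  if (record$total_time > config$session_max_duration + tol)
    note("total_time: exceeds the session time cap")
  if (!record$termination %in% c("time_cap", "volume_cap"))
    note("termination: must be \"time_cap\" or \"volume_cap\"")
  bad
}
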