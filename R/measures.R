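#' Visits entering the dependent-measure calculations
#'
#' The first and final patch visits of a session — together with their
#' associated patch changes — are excluded from all dependent measures: in
#' the first patch the subject has not yet experienced the session's COD,
#' and the final patch is cut short by session termination. A session with
#' two or fewer visits therefore contributes nothing.
#'
#' @param session A `patch_session`.
#' @return List of the included visits (possibly empty).
#' @export
included_visits <- function(session) {
  n <- length(session$visits)
  if (n <= 2) return(list())
  session$visits[2:(n - 1)]
}

#' Percent deviation from the optimal rejection volume
#'
#' `(optimal - observed) / optimal * 100`. Positive values indicate
#' overharvesting (the subject stayed until the forgone volume had dropped
#' below the optimum); negative values indicate underharvesting (leaving
#' while the forgone volume was still above the optimum).
#'
#' @param observed Observed rejection volume (uL).
#' @param optimal Optimal rejection volume (uL), same convention; must be
#'   positive.
#' @return Percent deviation. Vectorized.
#' @export
#' @examples
#' pct_volume_deviation(96, 120) # 20: overharvest by one depletion step
pct_volume_deviation <- function(observed, optimal) {
  if (any(!is.na(optimal) & optimal <= 0))
    stop("`optimal` rejection volume must be positive", call. = FALSE)
  (optimal - observed) / optimal * 100
}

#' Percent deviation from the optimal time in patch
#'
#' `(optimal - observed) / optimal * 100`, with the sign convention that
#' negative values mean the subject stayed *longer* than optimal and
#' positive values that it left sooner. At a 0-s COD the optimal time in
#' patch is 0 (leave after the entry reward) and the percent deviation is
#' undefined; it is returned as `NA` rather than an error so schedule-level
#' summaries can carry it as missing.
#'
#' @param observed Observed mean time in patch (s).
#' @param optimal Optimal time in patch (s).
#' @return Percent deviation, or `NA` where `optimal <= 0`. Vectorized.
#' @export
#' @examples
#' pct_time_deviation(8, 4) # -100: stayed twice as long as optimal
pct_time_deviation <- function(observed, optimal) {
  out <- ifelse(!is.na(optimal) & optimal > 0,
                (optimal - observed) / optimal * 100,
                NA_real_)
  out
}

harvest_class_of <- function(pct_vol_dev, tol = 1e-9) {
  ifelse(is.na(pct_vol_dev), NA_character_,
         ifelse(pct_vol_dev > tol, "over",
                ifelse(pct_vol_dev < -tol, "under", "optimal")))
}

#' Dependent measures of a single session
#'
#' Computes, over the included visits ([included_visits()]):
#' * `water_rate` — summed reward volume divided by the span from the first
#'   included visit's entry to the last included visit's exit, in uL/min.
#'   With `rate_includes_cod = TRUE` (default) that span contains the
#'   interior changeover delays, matching the overall-intake-rate framing of
#'   the MVT; setting it `FALSE` divides by summed in-patch time only.
#' * `n_patch_changes` — the number of included visits (each ends with a
#'   leave).
#' * `time_in_patch` — mean visit duration (exit - entry), s.
#' * `rejection_volume` — mean over visits of the next scheduled volume at
#'   departure (`scheduled_volume(n_rewards + 1)`), the indifference point.
#' * `pct_volume_deviation` — observed rejection volume against the
#'   benchmark's `optimal_next_volume` (the optimal policy's forgone volume
#'   under the same next-scheduled convention, so an optimal agent scores
#'   exactly 0).
#' * `pct_time_deviation` — observed against optimal time in patch (`NA` at
#'   COD 0, where the optimal time is 0).
#' * `harvest_class` — `"over"`, `"optimal"` or `"under"` by the sign of the
#'   volume deviation.
#'
#' Sessions with two or fewer visits yield all measures missing.
#'
#' @param session A `patch_session`.
#' @param benchmark The [mvt_benchmark()] row for the session's COD.
#' @param config A [task_config()].
#' @param rate_includes_cod Include interior CODs in the rate denominator.
#' @return A one-row tibble.
#' @export
session_measures <- function(session, benchmark = NULL,
                             config = task_config(),
                             rate_includes_cod = TRUE) {
  if (is.null(benchmark)) benchmark <- mvt_benchmark(session$cod_s, config)
  if (!isTRUE(all.equal(benchmark$cod_s, session$cod_s)))
    stop("benchmark COD (", benchmark$cod_s,
         ") does not match session COD (", session$cod_s, ")", call. = FALSE)
  inc <- included_visits(session)
  base <- tibble::tibble(
    subject_id = session$subject_id, sex = session$sex,
    session_index = session$session_index, cod_s = session$cod_s,
    water_rate = NA_real_, n_patch_changes = NA_real_,
    time_in_patch = NA_real_, rejection_volume = NA_real_,
    pct_time_deviation = NA_real_, pct_volume_deviation = NA_real_,
    harvest_class = NA_character_)
  if (length(inc) == 0) return(base)

  vols <- vapply(inc, function(v) sum(v$reward_volumes), numeric(1))
  durs <- vapply(inc, function(v) v$exit_time - v$entry_time, numeric(1))
  rejs <- vapply(inc, function(v)
    scheduled_volume(length(v$reward_volumes) + 1L, config), numeric(1))

  denom_s <- if (rate_includes_cod) {
    inc[[length(inc)]]$exit_time - inc[[1]]$entry_time
  } else {
    sum(durs)
  }
  base$water_rate <- if (denom_s > 0) sum(vols) / denom_s * 60 else Inf
  base$n_patch_changes <- length(inc)
  base$time_in_patch <- mean(durs)
  base$rejection_volume <- mean(rejs)
  base$pct_volume_deviation <-
    pct_volume_deviation(base$rejection_volume, benchmark$optimal_next_volume)
  base$pct_time_deviation <-
    pct_time_deviation(base$time_in_patch, benchmark$optimal_time_in_patch)
  base$harvest_class <- harvest_class_of(base$pct_volume_deviation)
  base
}

# Map session_index -> (cycle, position within cycle) under the config's
# schedule, and decide inclusion per the analysis rules: keep the last two
# cycles; drop the first session of each cycle when configured (the repeated
# 0-s session the subject runs before re-experiencing the week's CODs).
schedule_inclusion <- function(session_index, config) {
  len <- length(config$cod_cycle)
  cycle <- (session_index - 1L) %/% len + 1L
  pos <- (session_index - 1L) %% len + 1L
  keep <- cycle > config$n_cycles - 2L
  if (config$exclude_first_session_of_cycle) keep <- keep & pos != 1L
  keep
}

#' Per-COD dependent measures for one subject
#'
#' Averages session-level measures over the analyzed sessions of the
#' schedule: the last two cycles, with the first session of each cycle
#' excluded (so under the default 4-cycle schedule every COD averages
#' exactly two sessions). Missing session measures propagate to missing
#' per-COD measures rather than being imputed; the harvest class is
#' re-derived from the averaged volume deviation.
#'
#' @param sessions List of one subject's `patch_session` records covering
#'   the schedule (session_index 1..`n_cycles * length(cod_cycle)`).
#' @param config A [task_config()].
#' @param benchmarks Optional [benchmark_table()] covering the schedule's
#'   CODs (computed if omitted).
#' @param rate_includes_cod Passed to [session_measures()].
#' @return A tibble with one row per COD of the schedule (ascending).
#' @export
subject_delay_measures <- function(sessions, config = task_config(),
                                   benchmarks = NULL,
                                   rate_includes_cod = TRUE) {
  if (length(sessions) == 0)
    stop("no sessions supplied", call. = FALSE)
  sid <- unique(vapply(sessions, function(s) s$subject_id, character(1)))
  if (length(sid) != 1)
    stop("`sessions` must all belong to one subject", call. = FALSE)
  cods <- sort(unique(config$cod_cycle))
  if (is.null(benchmarks)) benchmarks <- benchmark_table(cods, config)

  idx <- vapply(sessions, function(s) s$session_index, integer(1))
  keep <- schedule_inclusion(idx, config)
  per_session <- dplyr::bind_rows(lapply(sessions[keep], function(s) {
    bm <- benchmarks[benchmarks$cod_s == s$cod_s, , drop = FALSE]
    if (nrow(bm) != 1)
      stop("no benchmark for COD ", s$cod_s, call. = FALSE)
    session_measures(s, bm, config, rate_includes_cod)
  }))

  out <- dplyr::bind_rows(lapply(cods, function(cod) {
    rows <- per_session[per_session$cod_s == cod, , drop = FALSE]
    bm <- benchmarks[benchmarks$cod_s == cod, , drop = FALSE]
    if (nrow(rows) == 0) {
      return(tibble::tibble(
        subject_id = sid, sex = sessions[[1]]$sex, cod_s = cod,
        n_sessions = 0L, water_rate = NA_real_, n_patch_changes = NA_real_,
        time_in_patch = NA_real_, rejection_volume = NA_real_,
        pct_time_deviation = NA_real_, pct_volume_deviation = NA_real_,
        harvest_class = NA_character_))
    }
    avg <- function(x) mean(x) # NA propagates by design
    pvd <- avg(rows$pct_volume_deviation)
    tibble::tibble(
      subject_id = sid, sex = rows$sex[1], cod_s = cod,
      n_sessions = nrow(rows),
      water_rate = avg(rows$water_rate),
      n_patch_changes = avg(rows$n_patch_changes),
      time_in_patch = avg(rows$time_in_patch),
      rejection_volume = avg(rows$rejection_volume),
      pct_time_deviation = if (bm$optimal_time_in_patch > 0)
        avg(rows$pct_time_deviation) else NA_real_,
      pct_volume_deviation = pvd,
      harvest_class = harvest_class_of(pvd))
  }))
  out
}

#' Dependent measures for every subject of a cohort
#'
#' Applies [subject_delay_measures()] to each subject's sessions.
#'
#' @param sessions List of `patch_session` records (all subjects).
#' @param config A [task_config()].
#' @param rate_includes_cod Passed to [session_measures()].
#' @return A tibble with one row per subject x COD.
#' @export
cohort_measures <- function(sessions, config = task_config(),
                            rate_includes_cod = TRUE) {
  ids <- vapply(sessions, function(s) s$subject_id, character(1))
  benchmarks <- benchmark_table(sort(unique(config$cod_cycle)), config)
  dplyr::bind_rows(lapply(split(sessions, factor(ids, levels = unique(ids))),
                          subject_delay_measures,
                          config = config, benchmarks = benchmarks,
                          rate_includes_cod = rate_includes_cod))
}

#' Distribution of harvest classes by changeover delay
#'
#' Classifies each subject at each COD by the sign of its percent volume
#' deviation (positive = overharvest, zero = optimal, negative =
#' underharvest) and tabulates percentages, which sum to 100 per COD over
#' the subjects with a defined deviation.
#'
#' @param measures A [cohort_measures()] table.
#' @return A tibble: `cod_s`, `n`, `pct_over`, `pct_optimal`, `pct_under`.
#' @export
harvest_distribution <- function(measures) {
  if (nrow(measures) == 0) stop("empty measures table", call. = FALSE)
  measures |>
    dplyr::filter(!is.na(.data$harvest_class)) |>
    dplyr::group_by(.data$cod_s) |>
    dplyr::summarise(
      n = dplyr::n(),
      pct_over = mean(.data$harvest_class == "over") * 100,
      pct_optimal = mean(.data$harvest_class == "optimal") * 100,
      pct_under = mean(.data$harvest_class == "under") * 100,
      .groups = "drop")
}
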