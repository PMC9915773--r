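event_log_cols <- c("subject_id", "sex", "session_index", "cod_s",
                    "event_type", "time_s", "patch_id", "volume_ul")
event_types <- c("patch_entry", "reward", "leave", "cod_start", "cod_end",
                 "session_end")

session_events <- function(s) {
  type <- character(0)
  time <- numeric(0)
  patch <- character(0)
  vol <- numeric(0)
  for (i in seq_along(s$visits)) {
    v <- s$visits[[i]]
    k <- length(v$reward_times)
    closing <- !is.na(v$exit_time)
    interior <- closing && i < length(s$visits)
    type <- c(type, "patch_entry", rep("reward", k),
              if (closing) "leave", if (interior) c("cod_start", "cod_end"))
    time <- c(time, v$entry_time, v$reward_times,
              if (closing) v$exit_time,
              if (interior) c(v$exit_time, v$exit_time + s$cod_s))
    patch <- c(patch, v$patch_id, rep(v$patch_id, k),
               if (closing) v$patch_id,
               if (interior) rep(NA_character_, 2))
    vol <- c(vol, NA_real_, v$reward_volumes,
             if (closing) NA_real_, if (interior) rep(NA_real_, 2))
  }
  type <- c(type, "session_end")
  time <- c(time, s$total_time)
  patch <- c(patch, NA_character_)
  vol <- c(vol, NA_real_)
  tibble::tibble(
    subject_id = s$subject_id, sex = s$sex,
    session_index = s$session_index, cod_s = s$cod_s,
    event_type = type,
    time_s = sprintf("%.3f", time),
    patch_id = patch,
    # %.17g guarantees a bit-exact double round trip for the volumes
    volume_ul = ifelse(is.na(vol), NA_character_, sprintf("%.17g", vol)))
}

#' Write session records as an event-log CSV
#'
#' One row per behavioral event (`patch_entry`, `reward`, `leave`,
#' `cod_start`, `cod_end`, `session_end`), with columns `subject_id`, `sex`,
#' `session_index`, `cod_s`, `event_type`, `time_s` (3 decimals — the
#' simulator's 1-ms resolution), `patch_id` and `volume_ul` (empty except on
#' reward rows). UTF-8, "." decimal separator, LF line endings, header row
#' mandatory. The format round-trips through [read_event_log()].
#'
#' @param sessions A `patch_session` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(sessions, path) {
  if (inherits(sessions, "patch_session")) sessions <- list(sessions)
  tab <- dplyr::bind_rows(lapply(sessions, session_events))
  readr::write_csv(tab, path, na = "", eol = "\n")
  invisible(path)
}

#' Read an event-log CSV back into session records
#'
#' Parses the dialect written by [write_event_log()] and reconstructs the
#' `patch_session` records; writing then reading is the identity on every
#' field. Malformed headers, unknown event types, and non-monotone
#' timestamps within a session raise errors naming the offending line.
#' The termination reason is re-derived from the totals: a session whose
#' cumulative volume reached the config's cap ended by `volume_cap`,
#' otherwise by `time_cap` (exact under the truncate-to-cap rule).
#'
#' @param path Event-log CSV path.
#' @param config The [task_config()] the log was produced under (supplies
#'   the caps used to re-derive the termination reason).
#' @return A list of `patch_session` records (possibly empty).
#' @export
read_event_log <- function(path, config = task_config()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  hdr <- strsplit(readr::read_lines(path, n_max = 1L), ",")[[1]]
  if (!identical(hdr, event_log_cols))
    stop("malformed event-log header in ", path, ": expected columns ",
         paste(event_log_cols, collapse = ","), call. = FALSE)
  tab <- readr::read_csv(
    path, na = "",
    col_types = readr::cols(
      subject_id = readr::col_character(),
      sex = readr::col_character(),
      session_index = readr::col_integer(),
      cod_s = readr::col_double(),
      event_type = readr::col_character(),
      time_s = readr::col_character(),
      patch_id = readr::col_character(),
      volume_ul = readr::col_character()),
    progress = FALSE)
  if (nrow(tab) == 0) return(list())
  # strtod via as.numeric is correctly rounded, giving bit-exact doubles
  tab$time_s <- as.numeric(tab$time_s)
  tab$volume_ul <- as.numeric(tab$volume_ul)
  tab$line <- seq_len(nrow(tab)) + 1L # header is line 1
  bad_type <- !tab$event_type %in% event_types
  if (any(bad_type))
    stop("unknown event_type \"", tab$event_type[bad_type][1],
         "\" at line ", tab$line[bad_type][1], call. = FALSE)

  key <- paste(tab$subject_id, tab$session_index, sep = "\r")
  out <- lapply(split(tab, factor(key, levels = unique(key))), function(g) {
    mono <- diff(g$time_s) < 0
    if (any(mono))
      stop("non-monotone timestamps within session at line ",
           g$line[which(mono)[1] + 1L], call. = FALSE)
    visits <- list()
    cur <- NULL
    total_time <- NA_real_
    for (i in seq_len(nrow(g))) {
      ev <- g$event_type[i]
      if (ev == "patch_entry") {
        if (!is.null(cur))
          stop("patch_entry before previous visit closed at line ",
               g$line[i], call. = FALSE)
        cur <- list(patch_id = g$patch_id[i], entry_time = g$time_s[i],
                    exit_time = NA_real_, reward_times = numeric(0),
                    reward_volumes = numeric(0),
                    preceded_by_cod = length(visits) > 0)
      } else if (ev == "reward") {
        if (is.null(cur))
          stop("reward outside a patch visit at line ", g$line[i],
               call. = FALSE)
        cur$reward_times <- c(cur$reward_times, g$time_s[i])
        cur$reward_volumes <- c(cur$reward_volumes, g$volume_ul[i])
      } else if (ev == "leave") {
        if (is.null(cur))
          stop("leave outside a patch visit at line ", g$line[i],
               call. = FALSE)
        cur$exit_time <- g$time_s[i]
        visits[[length(visits) + 1L]] <- cur
        cur <- NULL
      } else if (ev == "session_end") {
        total_time <- g$time_s[i]
      } # cod_start / cod_end carry no state
    }
    if (!is.null(cur)) visits[[length(visits) + 1L]] <- cur
    if (is.na(total_time))
      stop("session without a session_end row (subject ", g$subject_id[1],
           ", session ", g$session_index[1], ")", call. = FALSE)
    # sequential double-precision accumulation, matching the simulator's
    # running total bit for bit
    total_volume <- 0
    for (v in visits) for (vol in v$reward_volumes)
      total_volume <- total_volume + vol
    structure(list(
      subject_id = g$subject_id[1], sex = g$sex[1],
      session_index = g$session_index[1], cod_s = g$cod_s[1],
      visits = visits,
      termination = if (total_volume >= config$session_volume_cap - 1e-6)
        "volume_cap" else "time_cap",
      total_volume = total_volume, total_time = total_time),
      class = "patch_session")
  })
  names(out) <- NULL
  out
}

#' Flatten sessions into a visit table
#'
#' One row per patch visit: entry/exit times, reward count, the last volume
#' collected and the next volume that was scheduled (the visit's rejection
#' volume).
#'
#' @param sessions A `patch_session` or list of them.
#' @param config A [task_config()] (for the scheduled next volume).
#' @return A tibble.
#' @export
visit_table <- function(sessions, config = task_config()) {
  if (inherits(sessions, "patch_session")) sessions <- list(sessions)
  dplyr::bind_rows(lapply(sessions, function(s) {
    if (length(s$visits) == 0) return(NULL)
    dplyr::bind_rows(lapply(seq_along(s$visits), function(i) {
      v <- s$visits[[i]]
      k <- length(v$reward_volumes)
      tibble::tibble(
        subject_id = s$subject_id, session_index = s$session_index,
        cod_s = s$cod_s, visit_index = i, patch_id = v$patch_id,
        entry_time_s = v$entry_time, exit_time_s = v$exit_time,
        n_rewards = k,
        last_volume_ul = if (k > 0) v$reward_volumes[k] else NA_real_,
        next_scheduled_ul = scheduled_volume(k + 1L, config))
    }))
  }))
}

#' Read a run configuration from YAML or JSON
#'
#' The file mirrors the constructors' field names: a `task:` block for
#' [task_config()], a `cohort:` block for [cohort_spec()], and optional
#' top-level `policy`, `rate_includes_cod`, `auc_normalize_by`, `seed` and
#' `out_dir` entries.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `task`, `cohort`, `policy`,
#'   `rate_includes_cod`, `auc_normalize_by`, `seed`, `out_dir`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be a .yaml or .json file", call. = FALSE)
  }
  task <- do.call(task_config, as.list(raw$task %||% list()))
  cohort_args <- as.list(raw$cohort %||% list())
  if (!is.null(raw$seed) && is.null(cohort_args$seed))
    cohort_args$seed <- raw$seed
  cohort <- do.call(cohort_spec, cohort_args)
  policy <- raw$policy %||% "threshold"
  if (!policy %in% c("threshold", "mvt"))
    stop("`policy` must be \"threshold\" or \"mvt\"", call. = FALSE)
  auc_by <- raw$auc_normalize_by %||% "A"
  if (!auc_by %in% c("A", "v0"))
    stop("`auc_normalize_by` must be \"A\" or \"v0\"", call. = FALSE)
  list(task = task, cohort = cohort, policy = policy,
       rate_includes_cod = isTRUE(raw$rate_includes_cod %||% TRUE),
       auc_normalize_by = auc_by,
       seed = cohort$seed, out_dir = raw$out_dir %||% ".")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Simulates a cohort (or ingests an existing event log), validates every
#' session, and writes the complete report bundle to `out_dir`:
#' `benchmarks.csv`, `events.csv`, `roster.csv` (simulated runs only),
#' `measures.csv`, `harvest_distribution.csv`, `discount_fits.csv`,
#' `composites.csv`, `correlations.csv` (per-sex Pearson matrices, long
#' form), `correlation_comparisons.csv` (the dependent-correlation z-test
#' table) and `manifest.json` (seed, configuration hash, package version).
#' Outputs are byte-identical across runs with the same configuration; on
#' any stage failure the partial outputs are removed.
#'
#' @param config A list as returned by [read_run_config()]; missing pieces
#'   default to [task_config()] / [cohort_spec()].
#' @param out_dir Output directory (created if needed); overrides
#'   `config$out_dir`.
#' @param events Optional path to an existing event-log CSV to analyze
#'   instead of simulating.
#' @return Invisibly, a list of the computed tables.
#' @export
run_pipeline <- function(config = list(), out_dir = config$out_dir %||% ".",
                         events = NULL) {
  task <- config$task %||% task_config()
  spec <- config$cohort %||% cohort_spec()
  policy <- config$policy %||% "threshold"
  ric <- config$rate_includes_cod %||% TRUE
  auc_by <- config$auc_normalize_by %||% "A"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(x, p, na = "", eol = "\n")
    written <<- c(written, p)
    p
  }
  stage <- "setup"
  tryCatch({
    stage <- "benchmark"
    cods <- sort(unique(task$cod_cycle))
    bench <- benchmark_table(cods, task)
    emit(bench, "benchmarks.csv")

    stage <- "simulate"
    if (is.null(events)) {
      coh <- generate_cohort(spec, task, policy = policy)
      sessions <- coh$sessions
      emit(coh$roster, "roster.csv")
      p <- file.path(out_dir, "events.csv")
      write_event_log(sessions, p)
      written <- c(written, p)
    } else {
      sessions <- read_event_log(events, task)
    }

    stage <- "validate"
    for (s in sessions) {
      v <- validate_session(s, task)
      if (length(v) > 0)
        stop("session ", s$subject_id, "/", s$session_index,
             " failed validation: ", v[1], call. = FALSE)
    }

    stage <- "measures"
    measures <- cohort_measures(sessions, task, rate_includes_cod = ric)
    emit(measures, "measures.csv")
    emit(harvest_distribution(measures), "harvest_distribution.csv")

    stage <- "discounting"
    fits <- discount_fits(measures, A = task$initial_volume,
                          normalize_by = auc_by)
    emit(fits, "discount_fits.csv")

    stage <- "corrstats"
    composites <- suppressMessages(composite_scores(measures, fits))
    emit(composites, "composites.csv")
    mats <- pearson_matrix(composites, by_sex = TRUE)
    long <- dplyr::bind_rows(lapply(names(mats), function(g) {
      r <- mats[[g]]$r; p <- mats[[g]]$p
      pairs <- which(upper.tri(r), arr.ind = TRUE)
      tibble::tibble(sex = g,
                     var1 = rownames(r)[pairs[, 1]],
                     var2 = colnames(r)[pairs[, 2]],
                     r = r[pairs], p = p[pairs], n = mats[[g]]$n)
    }))
    emit(long, "correlations.csv")
    emit(comparison_table(composites), "correlation_comparisons.csv")

    stage <- "manifest"
    manifest <- list(
      package = "patchdep",
      version = as.character(utils::packageVersion("patchdep")),
      seed = spec$seed,
      policy = policy,
      rate_includes_cod = ric,
      auc_normalize_by = auc_by,
      config_hash = rlang::hash(list(task = unclass(task),
                                     cohort = unclass(spec),
                                     policy = policy, ric = ric,
                                     auc_by = auc_by)),
      n_sessions = length(sessions))
    p <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, p)

    invisible(list(benchmarks = bench, measures = measures, fits = fits,
                   composites = composites, correlations = long,
                   comparisons = comparison_table(composites),
                   manifest = manifest))
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage \"", stage, "\": ",
         conditionMessage(e), call. = FALSE)
  })
}
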