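#' Composite scores across delays
#'
#' Builds the subject-level composite table used for the correlation
#' analyses: each delay-varying measure (volume deviation VD, time
#' deviation TD, time in patch TIP, patch changes PC, water rate WR) is
#' summed across the tested delays, and the per-subject discounting scalars
#' (k, AUC) are carried through. TD is undefined at a 0-s COD (the optimal
#' time in patch is zero there), so its composite sums the positive delays
#' only.
#'
#' Subjects missing any required per-delay value, or without a converged
#' discounting fit, are listwise-dropped with a message.
#'
#' @param measures A [cohort_measures()] table.
#' @param fits A [discount_fits()] table.
#' @return A tibble: `subject_id`, `sex`, `k`, `auc`, `volume_deviation`,
#'   `time_deviation`, `time_in_patch`, `patch_changes`, `water_rate`.
#' @export
composite_scores <- function(measures, fits) {
  cods <- sort(unique(measures$cod_s))
  n_cod <- length(cods)
  comp <- measures |>
    dplyr::group_by(.data$subject_id, .data$sex) |>
    dplyr::summarise(
      complete = dplyr::n() == n_cod &&
        !anyNA(.data$water_rate) && !anyNA(.data$n_patch_changes) &&
        !anyNA(.data$time_in_patch) && !anyNA(.data$pct_volume_deviation) &&
        !anyNA(.data$pct_time_deviation[.data$cod_s > 0]) &&
        all(is.finite(.data$water_rate)),
      volume_deviation = sum(.data$pct_volume_deviation),
      time_deviation = sum(.data$pct_time_deviation[.data$cod_s > 0]),
      time_in_patch = sum(.data$time_in_patch),
      patch_changes = sum(.data$n_patch_changes),
      water_rate = sum(.data$water_rate),
      .groups = "drop") |>
    dplyr::left_join(fits[, c("subject_id", "k", "auc", "converged")],
                     by = "subject_id")
  usable <- comp$complete & !is.na(comp$k) & comp$converged
  if (any(!usable)) {
    message(sum(!usable), " subject(s) dropped from composites ",
            "(missing per-delay measures or discounting fit): ",
            paste(utils::head(comp$subject_id[!usable], 10), collapse = ", "),
            if (sum(!usable) > 10) ", ..." else "")
  }
  comp[usable, c("subject_id", "sex", "k", "auc", "volume_deviation",
                 "time_deviation", "time_in_patch", "patch_changes",
                 "water_rate")]
}

composite_vars <- c(k = "k", AUC = "auc", VD = "volume_deviation",
                    TD = "time_deviation", TIP = "time_in_patch",
                    PC = "patch_changes", WR = "water_rate")

#' Pearson correlation matrices over the composite variables
#'
#' Pairwise-complete Pearson correlations (and two-tailed p values from the
#' t distribution) among the seven composite variables — k, AUC, VD, TD,
#' TIP, PC, WR — computed per sex by default. Zero-variance variables yield
#' missing correlations.
#'
#' @param composites A [composite_scores()] table.
#' @param by_sex Compute one matrix per sex (default) or one pooled matrix.
#' @return A named list (by sex, or `"all"`) of lists with elements `r`,
#'   `p` (7x7 matrices) and `n`.
#' @export
pearson_matrix <- function(composites, by_sex = TRUE) {
  groups <- if (by_sex) split(composites, composites$sex)
            else list(all = composites)
  lapply(groups, function(g) {
    if (nrow(g) < 4) stop("need at least 4 subjects per group", call. = FALSE)
    x <- as.matrix(g[, unname(composite_vars)])
    colnames(x) <- names(composite_vars)
    sds <- apply(x, 2, stats::sd)
    r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
    r[sds == 0, ] <- NA
    r[, sds == 0] <- NA
    diag(r)[sds > 0] <- 1
    n <- nrow(x)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    diag(p) <- NA
    list(r = r, p = p, n = n)
  })
}

#' Fisher r-to-z transformation
#'
#' `0.5 * log((1 + r) / (1 - r))` = `atanh(r)`; strictly increasing and odd.
#'
#' @param r Correlation(s), strictly inside (-1, 1).
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("`r` must lie strictly between -1 and 1", call. = FALSE)
  atanh(r)
}

#' Meng-Rosenthal-Rubin z-test for two dependent overlapping correlations
#'
#' Compares the correlations of two variables with a common third variable
#' measured on the same subjects: given `r_y1 = cor(y, x1)`,
#' `r_y2 = cor(y, x2)` and `r_12 = cor(x1, x2)`,
#' \deqn{z = (z_{r_{y1}} - z_{r_{y2}}) \sqrt{\frac{N - 3}{2 (1 - r_{12}) h}}}
#' with `rbar2 = (r_y1^2 + r_y2^2) / 2`,
#' `f = min(1, (1 - r_12) / (2 (1 - rbar2)))` (the cap follows the original
#' recommendation) and `h = (1 - f * rbar2) / (1 - rbar2)`. The p value is
#' two-tailed normal. Swapping the compared variables negates z.
#'
#' @param r_y1,r_y2 Correlations of the common variable with the two
#'   compared variables, |r| < 1.
#' @param r_12 Correlation between the two compared variables, < 1.
#' @param N Number of subjects, > 3.
#' @return A list with `z` and `p`.
#' @export
#' @examples
#' meng_z_test(0.6, 0.3, 0.2, 100)
meng_z_test <- function(r_y1, r_y2, r_12, N) {
  if (N <= 3) stop("`N` must exceed 3", call. = FALSE)
  if (any(abs(c(r_y1, r_y2)) >= 1) || abs(r_12) > 1)
    stop("correlations must lie in (-1, 1)", call. = FALSE)
  if (r_12 >= 1) stop("`r_12` = 1 is degenerate", call. = FALSE)
  rbar2 <- (r_y1^2 + r_y2^2) / 2
  f <- min(1, (1 - r_12) / (2 * (1 - rbar2)))
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (fisher_z(r_y1) - fisher_z(r_y2)) *
    sqrt((N - 3) / (2 * (1 - r_12) * h))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Dependent-correlation comparisons between discounting and
#' reward-maximization variables
#'
#' For each patch-utilization variable (TIP, PC, WR) as the common
#' variable, compares the strength of its correlation with each
#' delay-discounting variable (k, AUC) against its correlation with each
#' reward-maximization variable (VD, TD) using [meng_z_test()]: 4
#' comparisons x 3 common variables = 12 cells per sex, the layout of the
#' classical comparison table. The z sign is
#' `fisher_z(r(common, DD)) - fisher_z(r(common, RM))` scaled: positive
#' when the discounting correlation is the stronger (more positive) one.
#'
#' @param composites A [composite_scores()] table.
#' @param by_sex Compare within each sex (default) or pooled.
#' @return A tibble: `sex`, `comparison` (e.g. `"k vs. VD"`),
#'   `common_variable`, `r_common_dd`, `r_common_rm`, `r_dd_rm`, `N`, `z`,
#'   `p`.
#' @export
comparison_table <- function(composites, by_sex = TRUE) {
  mats <- pearson_matrix(composites, by_sex = by_sex)
  dd_vars <- c("k", "AUC")
  rm_vars <- c("VD", "TD")
  common_vars <- c("TIP", "PC", "WR")
  dplyr::bind_rows(lapply(names(mats), function(g) {
    r <- mats[[g]]$r
    n <- mats[[g]]$n
    grid <- expand.grid(dd = dd_vars, rm = rm_vars, common = common_vars,
                        stringsAsFactors = FALSE)
    dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
      dd <- grid$dd[i]; rmv <- grid$rm[i]; cm <- grid$common[i]
      tst <- meng_z_test(r[cm, dd], r[cm, rmv], r[dd, rmv], n)
      tibble::tibble(
        sex = g, comparison = paste(dd, "vs.", rmv), common_variable = cm,
        r_common_dd = r[cm, dd], r_common_rm = r[cm, rmv],
        r_dd_rm = r[dd, rmv], N = n, z = tst$z, p = tst$p)
    }))
  }))
}
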