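#' Bias parameter from the zero-delay indifference point
#'
#' The bias `b` is fixed, not fitted: `b * A` must equal the subject's
#' indifference point at a 0-s delay, so `b = v0 / A`. In this task the
#' observable ceiling is one depletion step below the full reward (a subject
#' can reject at most the second scheduled volume), so under the default
#' schedule `b <= 0.8`.
#'
#' @param v0 Indifference point at zero delay (uL), in (0, A].
#' @param A Alternative-patch amount (uL), positive.
#' @return The bias `b` in (0, 1].
#' @export
bias_parameter <- function(v0, A) {
  if (!is.finite(A) || A <= 0) stop("`A` must be positive", call. = FALSE)
  if (any(!is.finite(v0)) || any(v0 <= 0) || any(v0 > A))
    stop("`v0` must lie in (0, A]", call. = FALSE)
  v0 / A
}

#' Hyperbolic discounted value
#'
#' `V = b * A / (1 + k * D)`: the subjective value of amount `A` delayed by
#' `D` seconds under hyperbolic discounting with rate `k` and bias `b`.
#'
#' @param D Delay (s), >= 0. Vectorized.
#' @param b Bias in (0, 1].
#' @param k Discount rate (1/s), >= 0.
#' @param A Amount (uL).
#' @return Value(s) in uL.
#' @export
#' @examples
#' hyperbolic_value(c(0, 6, 12, 18, 24), b = 0.8, k = 0.1, A = 150)
hyperbolic_value <- function(D, b, k, A) {
  if (any(!is.finite(D)) || any(D < 0)) stop("`D` must be >= 0", call. = FALSE)
  if (!is.finite(k) || k < 0) stop("`k` must be >= 0", call. = FALSE)
  b * A / (1 + k * D)
}

#' Fit the hyperbolic discount rate to indifference points
#'
#' Fixes the bias from the 0-s point (`b = v0 / A`) and estimates `k` by
#' least squares on the remaining points, minimizing
#' `sum((v_D - b*A/(1+k*D))^2)` over `k` in `[0, k_max]`. The objective is
#' evaluated on a log-spaced grid and refined by bounded scalar
#' minimization ([stats::optimize()], tolerance 1e-10) in the bracketing
#' interval, which is robust to the flat objectives produced by shallow
#' discounters; the boundary values `k = 0` and `k = k_max` are always
#' candidates, so flat profiles return exactly `k = 0`.
#'
#' @param indifference_points Indifference points (uL) by delay, in (0, A].
#' @param delays Delays (s), same length, containing 0 and at least two
#'   positive delays.
#' @param A Alternative-patch amount (uL).
#' @param k_max Upper search bound for `k` (1/s).
#' @return A one-row tibble: `b`, `k`, `sse` (uL^2), `converged`.
#' @export
#' @examples
#' v <- hyperbolic_value(c(0, 6, 12, 18, 24), 0.8, 0.1, 150)
#' fit_k(v, c(0, 6, 12, 18, 24), A = 150)
fit_k <- function(indifference_points, delays, A = 150, k_max = 100) {
  v <- as.numeric(indifference_points)
  d <- as.numeric(delays)
  if (length(v) != length(d))
    stop("points and delays must have equal length", call. = FALSE)
  if (length(d) < 3) stop("need at least 3 delays", call. = FALSE)
  if (any(!is.finite(v)) || any(!is.finite(d)))
    stop("non-finite indifference points or delays", call. = FALSE)
  if (!any(d == 0)) stop("a 0-s delay point is required to fix b",
                         call. = FALSE)
  if (any(v <= 0) || any(v > A))
    stop("indifference points must lie in (0, A]", call. = FALSE)

  b <- bias_parameter(v[d == 0][1], A)
  dp <- d[d > 0]
  vp <- v[d > 0]
  if (length(dp) < 2) stop("need at least two positive delays", call. = FALSE)
  sse <- function(k) sum((vp - b * A / (1 + k * dp))^2)

  grid <- c(0, 10^seq(-4, log10(k_max), length.out = 80), k_max)
  obj <- vapply(grid, sse, numeric(1))
  i <- which.min(obj)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  k_hat <- grid[i]
  f_hat <- obj[i]
  converged <- TRUE
  if (hi > lo) {
    opt <- stats::optimize(sse, interval = c(lo, hi), tol = 1e-10)
    if (opt$objective < f_hat) {
      k_hat <- opt$minimum
      f_hat <- opt$objective
    }
  }
  # prefer the exact boundary when it is as good (flat profiles -> k = 0)
  if (sse(0) <= f_hat + 1e-18) {
    k_hat <- 0
    f_hat <- sse(0)
  }
  tibble::tibble(b = b, k = k_hat, sse = f_hat, converged = converged)
}

#' Normalized area under the discounting curve
#'
#' Trapezoidal area of the indifference-point curve with both axes
#' normalized — delays by the maximum delay, values by the alternative
#' amount `A` (default) or by the subject's own 0-s point
#' (`normalize_by = "v0"`). Lies in [0, 1] when all points are in [0, A];
#' smaller values indicate steeper discounting (more overharvesting).
#'
#' @param indifference_points Indifference points (uL) by delay.
#' @param delays Delays (s), sorted strictly ascending, max > 0.
#' @param A Alternative-patch amount (uL).
#' @param normalize_by `"A"` or `"v0"`.
#' @return Dimensionless area.
#' @export
#' @examples
#' auc_normalized(c(120, 100, 80, 60, 40), c(0, 6, 12, 18, 24)) # 0.5333
auc_normalized <- function(indifference_points, delays, A = 150,
                           normalize_by = c("A", "v0")) {
  normalize_by <- match.arg(normalize_by)
  v <- as.numeric(indifference_points)
  d <- as.numeric(delays)
  if (length(v) != length(d) || length(d) < 2)
    stop("need matched points and at least two delays", call. = FALSE)
  if (any(diff(d) <= 0))
    stop("delays must be sorted strictly ascending", call. = FALSE)
  if (max(d) <= 0) stop("maximum delay must be positive", call. = FALSE)
  denom <- if (normalize_by == "A") A else {
    if (d[1] != 0) stop("`normalize_by = \"v0\"` needs a 0-s point first",
                        call. = FALSE)
    v[1]
  }
  x <- d / max(d)
  y <- v / denom
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Hyperbolic fits and AUC for every subject of a cohort
#'
#' Takes the per-subject x COD rejection volumes (indifference points) from
#' [cohort_measures()] and returns one [fit_k()] + [auc_normalized()] row
#' per subject. Subjects with any missing indifference point cannot be fit
#' and are returned with missing estimates (`converged = FALSE`).
#'
#' @param measures A [cohort_measures()] table.
#' @param A Alternative-patch amount (uL).
#' @param k_max Upper search bound for `k`.
#' @param normalize_by AUC normalization, `"A"` or `"v0"`.
#' @return A tibble: `subject_id`, `sex`, `b`, `k`, `auc`, `sse`,
#'   `converged`.
#' @export
discount_fits <- function(measures, A = 150, k_max = 100,
                          normalize_by = c("A", "v0")) {
  normalize_by <- match.arg(normalize_by)
  by_subj <- split(measures, factor(measures$subject_id,
                                    levels = unique(measures$subject_id)))
  dplyr::bind_rows(lapply(by_subj, function(m) {
    m <- m[order(m$cod_s), , drop = FALSE]
    base <- tibble::tibble(
      subject_id = m$subject_id[1], sex = m$sex[1],
      b = NA_real_, k = NA_real_, auc = NA_real_, sse = NA_real_,
      converged = FALSE)
    if (any(is.na(m$rejection_volume)) || !any(m$cod_s == 0))
      return(base)
    fit <- fit_k(m$rejection_volume, m$cod_s, A = A, k_max = k_max)
    base$b <- fit$b
    base$k <- fit$k
    base$sse <- fit$sse
    base$converged <- fit$converged
    base$auc <- auc_normalized(m$rejection_volume, m$cod_s, A = A,
                               normalize_by = normalize_by)
    base
  }))
}
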