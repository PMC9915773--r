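# A synthetic composite table with known structure, built directly.
fake_composites <- function(n = 40, seed = 1) {
  set.seed(seed)
  k <- exp(rnorm(n, log(0.1), 0.8))
  tibble::tibble(
    subject_id = sprintf("X%03d", 1:n),
    sex = rep(c("M", "F"), length.out = n),
    k = k,
    auc = 1 / (1 + 5 * k) + rnorm(n, 0, 0.02),
    volume_deviation = 200 * k + rnorm(n, 0, 5),
    time_deviation = -300 * k + rnorm(n, 0, 8),
    time_in_patch = 50 + 100 * k + rnorm(n, 0, 4),
    patch_changes = 60 - 80 * k + rnorm(n, 0, 4),
    water_rate = 3000 + rnorm(n, 0, 100))
}

test_that("composite scores sum measures across delays", {
  coh <- tiny_cohort()
  m <- cohort_measures(coh$sessions, default_cfg)
  f <- discount_fits(m)
  comp <- suppressMessages(composite_scores(m, f))
  for (id in comp$subject_id) {
    sub <- m[m$subject_id == id, ]
    expect_equal(comp$patch_changes[comp$subject_id == id],
                 sum(sub$n_patch_changes))
    expect_equal(comp$time_deviation[comp$subject_id == id],
                 sum(sub$pct_time_deviation[sub$cod_s > 0]))
  }
  # a measure constant across the five delays composites to 5x its value
  m2 <- m
  m2$n_patch_changes <- 3.0
  comp2 <- suppressMessages(composite_scores(m2, f))
  expect_true(all(comp2$patch_changes == 15.0))
})

test_that("subjects with incomplete measures are listwise-dropped", {
  coh <- tiny_cohort()
  m <- cohort_measures(coh$sessions, default_cfg)
  f <- discount_fits(m)
  drop_id <- m$subject_id[1]
  m$rejection_volume[m$subject_id == drop_id & m$cod_s == 12] <- NA
  m$pct_volume_deviation[m$subject_id == drop_id & m$cod_s == 12] <- NA
  f2 <- discount_fits(m)
  expect_message(comp <- composite_scores(m, f2), "dropped")
  expect_false(drop_id %in% comp$subject_id)
})

test_that("pearson_matrix agrees with a two-pass covariance computation", {
  comp <- fake_composites(30)
  mats <- pearson_matrix(comp, by_sex = FALSE)
  x <- as.matrix(comp[, c("k", "auc", "volume_deviation", "time_deviation",
                          "time_in_patch", "patch_changes", "water_rate")])
  n <- nrow(x)
  manual <- diag(7)
  for (i in 1:7) {
    for (j in 1:7) {
      xi <- x[, i] - mean(x[, i])
      xj <- x[, j] - mean(x[, j])
      manual[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  expect_equal(unname(mats$all$r), manual, tolerance = 1e-12)
  expect_equal(unname(diag(mats$all$r)), rep(1, 7))
  # x and -x correlate at -1: encode by making auc a mirror of k
  comp2 <- comp
  comp2$auc <- -comp2$k
  m2 <- pearson_matrix(comp2, by_sex = FALSE)$all$r
  expect_equal(m2["k", "AUC"], -1)
  # zero variance propagates as missing
  comp3 <- comp
  comp3$water_rate <- 5
  m3 <- pearson_matrix(comp3, by_sex = FALSE)$all$r
  expect_true(all(is.na(m3["WR", c("k", "AUC", "VD")])))
})

test_that("fisher transform is odd, increasing, and matches closed form", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.76), 0.5 * log(1.76 / 0.24))
  expect_equal(round(fisher_z(0.76), 4), 0.9962)
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_error(fisher_z(1), "strictly between")
})

test_that("the dependent-correlation z-test behaves at its fixed points", {
  eq <- meng_z_test(0.4, 0.4, 0.3, 50)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  a <- meng_z_test(0.6, 0.3, 0.2, 100)
  b <- meng_z_test(0.3, 0.6, 0.2, 100)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  expect_error(meng_z_test(0.5, 0.4, 1, 100), "degenerate|\\(-1, 1\\)")
  expect_error(meng_z_test(0.5, 0.4, 0.2, 3), "exceed 3")
})

test_that("the z-test decision agrees with a Monte-Carlo oracle", {
  # oracle: sampling distribution of the Fisher-z difference under the
  # matched null (equal population correlations), simulated trivariate
  # normals; compare the rejection decision at alpha = 0.05
  r_y1 <- 0.6; r_y2 <- 0.3; r_12 <- 0.2; n <- 100
  obs <- meng_z_test(r_y1, r_y2, r_12, n)
  rbar <- (r_y1 + r_y2) / 2
  sigma <- matrix(c(1, rbar, rbar, rbar, 1, r_12, rbar, r_12, 1), 3, 3)
  set.seed(7)
  reps <- 4000
  diffs <- replicate(reps, {
    x <- MASS::mvrnorm(n, rep(0, 3), sigma)
    r <- stats::cor(x)
    fisher_z(r[1, 2]) - fisher_z(r[1, 3])
  })
  d_obs <- fisher_z(r_y1) - fisher_z(r_y2)
  p_mc <- mean(abs(diffs) >= abs(d_obs))
  expect_identical(obs$p < 0.05, p_mc < 0.05)
  expect_lt(obs$p, 0.05) # this configuration clearly rejects
  expect_lt(p_mc, 0.05)
})

test_that("comparison_table mirrors the comparison-by-common-variable layout", {
  comp <- fake_composites(60)
  tab <- comparison_table(comp, by_sex = TRUE)
  expect_equal(nrow(tab), 2 * 4 * 3) # 4 comparisons x 3 common vars per sex
  expect_setequal(unique(tab$comparison),
                  c("k vs. VD", "k vs. TD", "AUC vs. VD", "AUC vs. TD"))
  expect_setequal(unique(tab$common_variable), c("TIP", "PC", "WR"))
  expect_true(all(abs(c(tab$r_common_dd, tab$r_common_rm, tab$r_dd_rm)) <= 1))
  # null cohort: no systematic signal
  set.seed(11)
  nullc <- fake_composites(80)
  for (v in c("k", "auc", "volume_deviation", "time_deviation",
              "time_in_patch", "patch_changes", "water_rate"))
    nullc[[v]] <- rnorm(80)
  tab0 <- comparison_table(nullc, by_sex = FALSE)
  expect_lt(mean(abs(tab0$z) > 1.96), 0.3)
})

test_that("power grows with N when TD is built from PC plus noise", {
  build <- function(n, seed) {
    set.seed(seed)
    pc <- rnorm(n)
    tibble::tibble(
      subject_id = sprintf("P%04d", 1:n), sex = "M",
      k = rnorm(n), auc = rnorm(n),
      volume_deviation = rnorm(n),
      time_deviation = pc + rnorm(n, 0, 0.5),
      time_in_patch = rnorm(n), patch_changes = pc,
      water_rate = rnorm(n))
  }
  z_small <- comparison_table(build(30, 2), by_sex = FALSE)
  z_large <- comparison_table(build(300, 2), by_sex = FALSE)
  pick <- function(tab) abs(tab$z[tab$comparison == "k vs. TD" &
                                    tab$common_variable == "PC"])
  expect_gt(pick(z_large), pick(z_small))
})
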