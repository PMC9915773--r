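test_that("first and final patches are excluded from the measures", {
  s <- simulate_session(fixed_n_policy(2), default_cfg, cod_s = 6)
  inc <- included_visits(s)
  expect_equal(length(inc), length(s$visits) - 2)
  expect_equal(length(inc), 17) # 19-visit session
  expect_true(all(vapply(inc, function(v) length(v$reward_volumes),
                         numeric(1)) == 2))
  two <- s
  two$visits <- s$visits[1:2]
  expect_equal(included_visits(two), list())
})

test_that("deviation percentages carry the documented sign conventions", {
  expect_equal(pct_volume_deviation(120, 120), 0)
  expect_equal(pct_volume_deviation(96, 120), 20)   # overharvest positive
  expect_equal(pct_volume_deviation(144, 120), -20) # underharvest negative
  expect_error(pct_volume_deviation(96, 0), "positive")
  expect_equal(pct_time_deviation(4, 4), 0)
  expect_equal(pct_time_deviation(8, 4), -100) # staying longer is negative
  expect_equal(pct_time_deviation(2, 4), 50)
  expect_true(is.na(pct_time_deviation(3, 0))) # undefined at COD 0
})

test_that("session measures match the worked rejection-volume example", {
  s <- simulate_session(fixed_n_policy(2), default_cfg, cod_s = 6)
  bm <- mvt_benchmark(6, default_cfg)
  m <- session_measures(s, bm, default_cfg)
  # a visit ending after 150 + 120 uL forgoes the 96-uL third reward
  expect_equal(m$rejection_volume, 96)
  expect_equal(m$time_in_patch, 4) # two rewards 4 s apart, zero latency
  expect_equal(m$n_patch_changes, 17)
  expect_equal(m$pct_volume_deviation, 0) # matched-convention optimum
  expect_equal(m$pct_time_deviation, 0)
  expect_identical(m$harvest_class, "optimal")
  # rate denominator spans first included entry to last included exit:
  # 17 visits of 4 s in-patch plus 16 interior 10-s cycles' COD share
  span <- (17 - 1) * 10 + 4
  expect_equal(m$water_rate, 17 * 270 / span * 60)
  # excluding CODs divides by in-patch time only
  m2 <- session_measures(s, bm, default_cfg, rate_includes_cod = FALSE)
  expect_equal(m2$water_rate, 17 * 270 / (17 * 4) * 60)
  expect_error(session_measures(s, mvt_benchmark(12, default_cfg),
                                default_cfg), "does not match")
})

test_that("sessions with two or fewer visits yield missing measures", {
  s <- simulate_session(function(...) "stay", default_cfg, cod_s = 24)
  m <- session_measures(s, mvt_benchmark(24, default_cfg), default_cfg)
  expect_true(is.na(m$water_rate) && is.na(m$rejection_volume) &&
                is.na(m$harvest_class))
})

test_that("subject averaging keeps the last two cycles minus the lead session", {
  coh <- tiny_cohort()
  one <- coh$sessions[1:24]
  m <- subject_delay_measures(one, default_cfg)
  expect_equal(nrow(m), 5)
  expect_equal(m$cod_s, c(0, 6, 12, 18, 24))
  expect_equal(m$n_sessions, rep(2L, 5)) # cycles 3-4 only
  # which session indices were used: last two cycles are sessions 13..24,
  # minus the first session of each cycle (13 and 19)
  kept <- (13:24)[!(13:24) %in% c(13, 19)]
  bm <- benchmark_table(c(0, 6, 12, 18, 24), default_cfg)
  per <- do.call(rbind, lapply(one[kept], function(s) {
    session_measures(s, bm[bm$cod_s == s$cod_s, ], default_cfg)
  }))
  manual <- tapply(per$rejection_volume, per$cod_s, mean)
  expect_equal(as.numeric(manual), m$rejection_volume)
  # identical sessions average to either one (noiseless agents)
  expect_equal(m$rejection_volume,
               per$rejection_volume[match(m$cod_s, per$cod_s)])
})

test_that("the noiseless k = 0.1 subject rejects 31.457 uL at COD 24", {
  roster <- k_grid_roster(0.1)
  coh <- generate_cohort(roster = roster, config = default_cfg)
  m <- cohort_measures(coh$sessions, default_cfg)
  expect_equal(m$rejection_volume[m$cod_s == 24],
               scheduled_volume(8, default_cfg), tolerance = 1e-12)
  expect_equal(round(m$rejection_volume[m$cod_s == 24], 3), 31.457)
})

test_that("harvest distribution conserves percentages and classifies signs", {
  coh <- generate_cohort(roster = k_grid_roster(c(0.02, 0.08, 0.3)),
                         config = default_cfg)
  m <- cohort_measures(coh$sessions, default_cfg)
  h <- harvest_distribution(m)
  expect_equal(h$pct_over + h$pct_optimal + h$pct_under, rep(100, nrow(h)))
  # all-optimal cohort: MVT agents sit exactly on the reference line
  spec <- cohort_spec(n_per_sex = 2, seed = 1)
  mv <- generate_cohort(spec, default_cfg, policy = "mvt")
  hm <- harvest_distribution(cohort_measures(mv$sessions, default_cfg))
  expect_equal(hm$pct_optimal, rep(100, nrow(hm)))
})

test_that("low-k noiseless cohorts overharvest less as the delay grows", {
  # assessed over positive delays: at zero travel cost the matched-convention
  # deviation places every b <= 0.8 threshold agent exactly at the
  # observable optimum (see the methods vignette)
  ks <- exp(seq(log(0.005), log(0.05), length.out = 12))
  coh <- generate_cohort(roster = k_grid_roster(ks), config = default_cfg)
  m <- cohort_measures(coh$sessions, default_cfg)
  h <- harvest_distribution(m[m$cod_s > 0, ])
  h <- h[order(h$cod_s), ]
  expect_true(all(diff(h$pct_over) <= 0))
  expect_gt(h$pct_over[1], 0) # some genuine overharvesting at the short COD
})

test_that("patch changes fall and time in patch rises with COD", {
  ks <- exp(seq(log(0.02), log(0.5), length.out = 8))
  coh <- generate_cohort(roster = k_grid_roster(ks), config = default_cfg)
  m <- cohort_measures(coh$sessions, default_cfg)
  for (id in unique(m$subject_id)) {
    sub <- m[m$subject_id == id & m$cod_s > 0, ]
    sub <- sub[order(sub$cod_s), ]
    if (anyNA(sub$n_patch_changes)) next
    expect_true(all(diff(sub$n_patch_changes) <= 1e-9))
    expect_true(all(diff(sub$time_in_patch) >= -1e-9))
  }
})
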