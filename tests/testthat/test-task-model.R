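test_that("scheduled volumes deplete geometrically from the entry reward", {
  expect_identical(scheduled_volume(1, default_cfg), 150)
  expect_equal(scheduled_volume(2, default_cfg), 120)
  expect_equal(scheduled_volume(3, default_cfg), 96)
  expect_equal(scheduled_volume(4, default_cfg), 150 * 0.8^3) # 76.8 by hand
  expect_equal(scheduled_volume(1:3, default_cfg), c(150, 120, 96))
  expect_error(scheduled_volume(0, default_cfg), "positive integer")
  expect_error(scheduled_volume(-2, default_cfg), "positive integer")
  expect_error(scheduled_volume(1.5, default_cfg), "positive integer")
})

test_that("task_config rejects out-of-range constants", {
  expect_error(task_config(initial_volume = 0), "initial_volume")
  expect_error(task_config(decay_fraction = 1), "decay_fraction")
  expect_error(task_config(decay_fraction = 0), "decay_fraction")
  expect_error(task_config(inter_reward_interval = -1), "inter_reward")
  expect_error(task_config(session_volume_cap = 0), "volume_cap")
  expect_error(task_config(cod_cycle = c(0, -6)), "cod_cycle")
})

test_that("a leave-after-2 session at COD 6 matches the hand-built event loop", {
  s <- simulate_session(fixed_n_policy(2), default_cfg, cod_s = 6)
  # hand oracle: each complete visit takes 270 uL in a 10-s cycle
  # (entry reward, +4 s second reward, leave, 6-s COD); the 5000-uL cap is
  # crossed on the 19th patch entry (18 * 270 = 4860), whose entry reward is
  # truncated to 140 at t = 18 * 10 = 180 s.
  expect_identical(s$termination, "volume_cap")
  expect_equal(length(s$visits), 19)
  expect_equal(s$total_volume, 5000)
  expect_equal(s$total_time, 180)
  expect_lt(s$total_time, default_cfg$session_max_duration)
  complete <- s$visits[-length(s$visits)]
  for (v in complete) expect_equal(v$reward_volumes, c(150, 120))
  expect_equal(s$visits[[19]]$reward_volumes, 140)
  expect_true(is.na(s$visits[[19]]$exit_time))
  # patches alternate starting at A; every later visit follows a changeover
  expect_equal(vapply(s$visits, `[[`, "", "patch_id")[1:4],
               c("A", "B", "A", "B"))
  expect_false(s$visits[[1]]$preceded_by_cod)
  expect_true(all(vapply(s$visits[-1], `[[`, TRUE, "preceded_by_cod")))
})

test_that("a never-leave session at COD 0 is bounded by the geometric series", {
  s <- simulate_session(function(...) "stay", default_cfg, cod_s = 0)
  expect_equal(length(s$visits), 1)
  # series limit 150 / 0.2 = 750 uL < 5000 uL, so time is the binding cap;
  # rewards at 0, 4, ..., 596 s: 150 of them
  n <- length(s$visits[[1]]$reward_volumes)
  expect_equal(n, 150)
  expect_equal(s$total_volume, 150 * (1 - 0.8^n) / 0.2)
  expect_lt(s$total_volume, default_cfg$session_volume_cap)
  expect_identical(s$termination, "time_cap")
  expect_equal(s$total_time, 600)
  expect_equal(diff(s$visits[[1]]$reward_times), rep(4, n - 1))
})

test_that("sessions replay bit-identically under the same seed", {
  spec <- list(k_true = 0.15, b_true = 0.8, noise_temp = 8)
  run <- function() {
    set.seed(99)
    simulate_session(threshold_policy(spec, 12, default_cfg), default_cfg,
                     cod_s = 12, latency_mean = 0.5)
  }
  expect_identical(run(), run())
})

test_that("simulated sessions self-validate and caps are never exceeded", {
  set.seed(3)
  pols <- list(fixed_n_policy(1), fixed_n_policy(3),
               threshold_policy(list(k_true = 0.3, b_true = 0.7,
                                     noise_temp = 10), 18, default_cfg))
  for (pol in pols) {
    for (cod in c(0, 6, 24)) {
      for (lat in c(0, 0.5)) {
        s <- simulate_session(pol, default_cfg, cod_s = cod,
                              latency_mean = lat)
        expect_identical(validate_session(s, default_cfg), character(0))
        expect_lte(s$total_volume, default_cfg$session_volume_cap + 1e-9)
        expect_lte(s$total_time, default_cfg$session_max_duration)
        for (v in s$visits) {
          k <- length(v$reward_volumes)
          trunc_ok <- identical(s$termination, "volume_cap") &&
            identical(v, s$visits[[length(s$visits)]])
          chk <- if (trunc_ok) seq_len(k - 1) else seq_len(k)
          expect_equal(v$reward_volumes[chk],
                       scheduled_volume(chk, default_cfg))
        }
      }
    }
  }
})

test_that("validate_session pinpoints corrupted records", {
  s <- simulate_session(fixed_n_policy(2), default_cfg, cod_s = 6)
  bad <- s
  bad$visits[[2]]$reward_volumes[2] <- 130 # 150 * 0.8 != 130
  expect_match(validate_session(bad, default_cfg), "geometric decay",
               all = FALSE)
  bad2 <- s
  bad2$total_volume <- 5100
  v <- validate_session(bad2, default_cfg)
  expect_match(v, "volume cap", all = FALSE)
  bad3 <- s
  bad3$visits[[3]]$patch_id <- bad3$visits[[2]]$patch_id
  expect_match(validate_session(bad3, default_cfg), "alternate", all = FALSE)
})

test_that("an invalid policy decision raises a protocol error", {
  expect_error(
    simulate_session(function(...) "hop", default_cfg, cod_s = 6),
    "invalid decision")
  expect_error(
    simulate_session(function(...) c("stay", "stay"), default_cfg, cod_s = 6),
    "invalid decision")
})
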