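test_that("the fast-IPI threshold is the nearest-rank pooled quantile", {
  expect_equal(ipi_threshold(c(0.2, 0.4, 0.6, 0.8, 1.0), 0.40), 0.4)
  expect_equal(ipi_threshold(rep(0.7, 20), 0.40), 0.7)
  # closed-form exponential quantile at q = 0.40: -ln(0.6)
  ipis <- withr::with_seed(8, rexp(1e5, 1))
  expect_equal(ipi_threshold(ipis, 0.40), -log(0.6), tolerance = 0.02)
  expect_error(ipi_threshold(numeric(0)), class = "sfiadapt_invalid_input")
})

test_that("first-press censoring at 5 s is exact", {
  expect_equal(first_press_time(c(2.1, 7.3, 9.0)), 7.3)
  expect_equal(first_press_time(6.0), 6.0)
  expect_true(is.na(first_press_time(c(1.0, 4.9))))
})

test_that("burst detection matches the worked examples", {
  expect_equal(first_burst_time(c(6.0, 6.2, 6.4, 9.0), 0.3), 6.0)
  expect_equal(first_burst_time(c(6.0, 8.0, 8.1, 8.2), 0.3), 8.0)
  expect_true(is.na(first_burst_time(c(6.0, 8.0, 10.0), 0.3)))
  # a qualifying triple before 5 s is skipped, a later one is found
  expect_equal(first_burst_time(c(1.0, 1.1, 1.2, 7.0, 7.1, 7.2), 0.3), 7.0)
})

test_that("burst detection agrees with a brute-force triple scan", {
  withr::with_seed(17, {
    for (i in 1:2000) {
      p <- random_presses()
      thr <- runif(1, 0.1, 5)
      expect_identical(first_burst_time(p, thr),
                       brute_force_burst(p, thr))
    }
  })
})

test_that("rate smoothing is a centred edge-truncated moving average", {
  # three presses, one per second
  sm <- smoothed_rate_series(c(0.5, 1.5, 2.5), 3)
  expect_equal(sm$rate, c(1, 1, 1))
  expect_equal(sm$smoothed, c(1, 1, 1))
  # a lone burst bin spreads into its neighbours
  sm2 <- smoothed_rate_series(c(2.1, 2.5, 2.9), 5)
  expect_equal(sm2$rate, c(0, 0, 3, 0, 0))
  expect_equal(sm2$smoothed, c(0, 1, 1, 1, 0))
  # no presses at all
  sm3 <- smoothed_rate_series(numeric(0), 4)
  expect_equal(sm3$smoothed, rep(0, 4))
})

test_that("session-average press rate is total presses over total time", {
  trials <- tibble::tibble(
    subject_id = "a", day = 1L, block_index = 1L,
    trial_index_in_block = 1L, fi_duration = 12,
    press_times = list(c(10, 20)), reward_time = 20
  )
  expect_equal(session_baseline_rate(trials)$baseline_rate, 0.1)
  # Poisson MLE recovery on a homogeneous session
  ag <- agent_params(baseline_rate = 0, high_rate = 0.8, weber_cv = 0,
                     threshold_fraction = 1e-3, consumption_delay = 0)
  s <- simulate_session(sfi_protocol(), ag, seed = 31)
  est <- session_baseline_rate(s)$baseline_rate
  se <- sqrt(0.8 / sum(s$reward_time))
  expect_lt(abs(est - 0.8), 3 * se)
})

test_that("rate-increase detection finds the doubling time", {
  # deterministic series: crossing at bin [14, 15)
  p <- c(6, 10, seq(14.05, 20, by = 0.25))
  t14 <- rate_increase_time(p, 21, baseline_rate = 0.5)
  expect_equal(t14, 13) # smoothing pulls the crossing one bin early
  expect_true(rate_increase_time(p, 21, baseline_rate = 0.5) >= 5)
  # no crossing anywhere
  expect_true(is.na(rate_increase_time(c(6, 10, 14), 20, baseline_rate = 2)))
  # median detected step time on piecewise-constant Poisson trials
  ag <- agent_params(baseline_rate = 0.05, high_rate = 1, weber_cv = 0,
                     initial_estimate = 40, consumption_delay = 0)
  detected <- withr::with_seed(57, replicate(500, {
    tr <- simulate_trial(40, 40, ag) # step at t = 20
    rate_increase_time(tr$press_times, tr$reward_time, baseline_rate = 0.2)
  }))
  expect_gte(median(detected, na.rm = TRUE), 19)
  expect_lte(median(detected, na.rm = TRUE), 22)
})

test_that("the start-time table is censored, restricted and pairwise-missing", {
  st <- default_start_times()
  metrics <- c("first_press", "first_burst", "rate_increase", "change_point")
  # censoring: no estimate below 5 s, ever; none beyond the trial end
  trials <- default_cohort()
  key <- c("subject_id", "day", "block_index", "trial_index_in_block")
  merged <- dplyr::left_join(st, trials, by = key)
  for (m in metrics) {
    expect_true(all(st[[m]] >= 5, na.rm = TRUE))
    expect_true(all(merged[[m]] <= merged$reward_time, na.rm = TRUE))
  }
  # restricted to the first five blocks even though sessions run longer
  expect_lte(max(st$block_index), 5)
  expect_gt(max(default_cohort()$block_index), 5)
  # when both are defined, the burst's first press is itself a press >= 5 s
  both <- !is.na(st$first_press) & !is.na(st$first_burst)
  expect_true(all(st$first_press[both] <= st$first_burst[both]))
})

test_that("a trial with no admissible presses is missing on all metrics", {
  trials <- tibble::tibble(
    subject_id = c("a", "a"), day = 1L, block_index = 1L,
    trial_index_in_block = 1:2, fi_duration = 12,
    press_times = list(c(1.0, 4.0, 4.5), c(6, 6.4, 6.8, 7.2, 12.1)),
    reward_time = c(4.5, 12.1)
  )
  st <- estimate_start_times(trials)
  expect_true(all(is.na(unlist(st[1, c("first_press", "first_burst",
                                       "rate_increase", "change_point")]))))
  expect_equal(st$first_press[2], 6)
})
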