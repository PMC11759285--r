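make_table <- function(values_by_block, fis, subject = "a") {
  purrr::imap_dfr(values_by_block, function(v, b) {
    tibble::tibble(
      subject_id = subject, day = 1L, block_index = as.integer(b),
      trial_index_in_block = seq_along(v), fi_duration = fis[b],
      first_press = v, first_burst = v, rate_increase = v, change_point = v
    )
  })
}

test_that("blockwise means use pairwise deletion", {
  tab <- make_table(list(c(10, 20, NA), c(NA, NA, NA), c(7, 7, 7)),
                    fis = c(24, 36, 48))
  bw <- blockwise_means(tab)
  expect_equal(bw$first_press, c(15, NA, 7))
  expect_equal(bw$change_point, c(15, NA, 7))
})

test_that("transition classification follows the rank-gap rule", {
  durations <- c(12, 24, 36, 48, 60)
  cls <- classify_transition(36, 48, durations)
  expect_equal(cls$direction, "increase")
  expect_equal(cls$magnitude, "small")
  cls <- classify_transition(60, 24, durations)
  expect_equal(cls$direction, "decrease")
  expect_equal(cls$magnitude, "large")
  cls <- classify_transition(12, 36, durations)
  expect_equal(cls$direction, "increase")
  expect_equal(cls$magnitude, "intermediate")
  expect_error(classify_transition(11, 36, durations),
               class = "sfiadapt_invalid_input")
  expect_error(classify_transition(36, 36, durations),
               class = "sfiadapt_invalid_input")
})

test_that("transition records apply the shortest-duration exclusion", {
  tab <- make_table(list(rep(8, 13), rep(9, 13), rep(10, 13)),
                    fis = c(12, 48, 24))
  # burst-family metrics drop transitions touching the shortest duration
  rec_burst <- build_transition_records(tab, "first_burst")
  expect_equal(unique(rec_burst$transition_index), 2L) # only 48 -> 24
  # first press keeps every transition
  rec_fp <- build_transition_records(tab, "first_press")
  expect_setequal(unique(rec_fp$transition_index), c(1L, 2L))
  # 5-block session: at most 4 records per metric
  tab5 <- make_table(rep(list(rep(8, 13)), 5), fis = c(24, 36, 48, 60, 12))
  expect_lte(dplyr::n_distinct(
    build_transition_records(tab5, "first_press")$transition_index
  ), 4L)
})

test_that("normalisation maps the previous-block mean to exactly 100%", {
  tab <- make_table(list(rep(20, 13), rep(20, 13)), fis = c(36, 48))
  rec <- build_transition_records(tab, "first_press")
  expect_true(all(rec$normalized_pct == 100, na.rm = TRUE))
  curves <- adaptation_curves(rec)
  expect_true(all(curves$mean_pct == 100))
  # substituting each record's own previous-block mean gives exactly 100%
  st <- default_start_times()
  rec2 <- build_transition_records(st, "first_burst")
  self <- 100 * (rec2$prev_block_mean / rec2$prev_block_mean)
  expect_true(all(self == 100))
})

test_that("the one-shot noiseless agent jumps to new/prev x 100% at trial 2", {
  ag <- agent_params(baseline_rate = 0, high_rate = 100, weber_cv = 0,
                     learning_rate = 1)
  s <- simulate_cohort(sfi_protocol(), ag, n_subjects = 4, seed = 77)
  st <- estimate_start_times(s)
  rec <- build_transition_records(st, "first_press",
                                  exclude_shortest = FALSE)
  inc <- rec[rec$direction == "increase" & rec$post_trial >= 2, ]
  # from trial 2 on, start = 0.5 * new FI while PB mean tracks the block mix
  expected <- 100 * (0.5 * inc$next_fi) / inc$prev_block_mean
  expect_equal(inc$normalized_pct, expected, tolerance = 0.01)
  # trial-2 normalised jump is larger for large than for small increases
  t2 <- rec[rec$post_trial == 2 & rec$direction == "increase", ]
  expect_gt(min(t2$normalized_pct[t2$magnitude == "large"]),
            max(t2$normalized_pct[t2$magnitude == "small"]))
})

test_that("gradual learners approach the new interval monotonically", {
  # delta rule with a fixed experienced interval converges geometrically
  est <- 36
  track <- numeric(6)
  for (i in 1:6) {
    est <- agent_update_estimate(est, 60, 0.2)
    track[i] <- est
  }
  expect_true(all(diff(track) > 0))
  expect_equal(track[1], 40.8)
  expect_lt(max(track), 60)
})

test_that("adaptation latency is 2 for one-shot and later for slow learners", {
  st_fast <- default_start_times()
  rec_fast <- build_transition_records(st_fast, "first_burst")
  lat_fast <- glance(adaptation_latency(rec_fast))
  expect_true(all(lat_fast$latency == 2))

  st_slow <- cached("slow_start_times",
                    estimate_start_times(gradual_cohort(0.05)))
  rec_slow <- build_transition_records(st_slow, "first_burst")
  lat_slow <- glance(adaptation_latency(rec_slow))
  expect_true(all(is.na(lat_slow$latency) | lat_slow$latency > 2))
})

test_that("latency is non-increasing in the learning rate", {
  lat_of <- function(lr, seed) {
    trials <- gradual_cohort(lr, n_subjects = 10, seed = seed)
    st <- estimate_start_times(trials)
    rec <- build_transition_records(st, "first_burst")
    l <- glance(adaptation_latency(rec))$latency
    mean(ifelse(is.na(l), 11, l)) # no detection counts as beyond the window
  }
  lats <- c(lat_of(1, 404), lat_of(0.2, 404), lat_of(0.05, 404))
  expect_true(all(diff(lats) >= 0))
})

test_that("correlations with FI duration build up over post-trials", {
  st <- default_start_times()
  ct <- post_transition_correlations(st, metrics = "first_burst")
  expect_equal(nrow(ct), 4L)
  # trial 1: the animal cannot yet know the new FI
  expect_lt(abs(ct$r[ct$post_trial == 1]), 0.3)
  # trial 2: significant positive correlation
  expect_gt(ct$r[ct$post_trial == 2], 0)
  expect_lt(ct$p_value[ct$post_trial == 2], 0.05)
  # stabilises: trial 4 at least as structured as trial 2
  expect_gte(ct$r_squared[ct$post_trial == 4],
             0.8 * ct$r_squared[ct$post_trial == 2])
  # degenerate input: constant FI -> missing result
  tab <- make_table(list(rep(8, 13), rep(9, 13)), fis = c(36, 36.0001))
  tab$fi_duration <- 36
  ct0 <- post_transition_correlations(tab, trial_indices = 1,
                                      metrics = "first_press")
  expect_true(is.na(ct0$r))
  # perfect linear relation
  tab2 <- purrr::map_dfr(1:5, function(b) {
    tibble::tibble(
      subject_id = letters[1:3], day = 1L, block_index = b,
      trial_index_in_block = 1L, fi_duration = c(12, 36, 60) + b,
      first_press = 0.5 * (c(12, 36, 60) + b),
      first_burst = NA_real_, rate_increase = NA_real_,
      change_point = NA_real_
    )
  })
  ct2 <- post_transition_correlations(tab2, trial_indices = 1,
                                      metrics = "first_press")
  expect_equal(ct2$r, 1)
  expect_equal(ct2$r_squared, 1)
})

test_that("reversing block order swaps increase and decrease curves", {
  st <- noiseless_start_times()
  rec <- build_transition_records(st, "first_press",
                                  exclude_shortest = FALSE)
  # reverse each session's block order and rebuild
  st_rev <- st |>
    dplyr::group_by(subject_id, day) |>
    dplyr::mutate(block_index = max(block_index) - block_index + 1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(subject_id, day, block_index, trial_index_in_block)
  rec_rev <- build_transition_records(st_rev, "first_press",
                                      exclude_shortest = FALSE)
  tally <- function(r) table(r$direction[r$post_trial == 1])
  expect_equal(unname(tally(rec)[["increase"]]),
               unname(tally(rec_rev)[["decrease"]]))
  expect_equal(unname(tally(rec)[["decrease"]]),
               unname(tally(rec_rev)[["increase"]]))
})

test_that("blockwise scaling recovers the threshold fraction", {
  g <- glance(blockwise_scaling(noiseless_start_times()))
  for (m in c("first_burst", "rate_increase", "change_point")) {
    expect_equal(g$slope[g$metric == m], 0.5, tolerance = 0.1)
  }
  # first press is shallower when baseline pressing intrudes, but the
  # blockwise means still increase with FI duration
  bw <- blockwise_means(noiseless_start_times())
  fp_means <- tapply(bw$first_press, bw$fi_duration, mean, na.rm = TRUE)
  expect_true(all(diff(fp_means) > 0))
  expect_gt(g$slope[g$metric == "first_press"], 0)
})
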