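test_that("the exponential-Gamma marginal likelihood is exact", {
  # closed form by hand: a = b = 1, one IPI of 1 -> 1/(1+1)^2
  expect_equal(marginal_loglik_exp(1.0, shape = 1, rate0 = 1), log(0.25))
  # sufficiency: depends on the data only through (n, sum)
  x <- withr::with_seed(3, rexp(20, 2))
  expect_equal(marginal_loglik_exp(x, 1.3, 0.7),
               marginal_loglik_exp(rev(x), 1.3, 0.7))
  # quadrature oracle: integrate the likelihood against the Gamma prior
  x50 <- withr::with_seed(4, rexp(50, 2))
  quad <- stats::integrate(
    function(r) {
      exp(length(x50) * log(r) - r * sum(x50) +
            stats::dgamma(r, shape = 1.5, rate = 2, log = TRUE))
    },
    lower = 0, upper = Inf, rel.tol = 1e-10
  )
  expect_equal(marginal_loglik_exp(x50, 1.5, 2), log(quad$value),
               tolerance = 1e-6)
  expect_error(marginal_loglik_exp(c(1, -1), 1, 1),
               class = "sfiadapt_invalid_input")
})

test_that("the best-split Bayes factor lands on the true rate change", {
  cfg <- cprl_config(prior_rate = 2)
  # ten slow then ten fast IPIs: split at index 10
  bf <- bayes_factor_change(c(rep(5, 10), rep(0.25, 10)), cfg)
  expect_equal(bf$split_index, 10)
  expect_gt(bf$bayes_factor, 10)
  # constant sequences stay below criterion
  bf0 <- bayes_factor_change(rep(1, 30), cfg)
  expect_lt(bf0$bayes_factor, 10)
  # a single admissible split
  bf1 <- bayes_factor_change(c(1, 1), cfg)
  expect_equal(bf1$split_index, 1)
  # too few IPIs -> empty result
  expect_equal(nrow(bayes_factor_change(1.5, cfg)), 0L)
})

test_that("online first-detection equals exhaustive (prefix, split) search", {
  cfg <- cprl_config()
  withr::with_seed(23, {
    for (i in 1:300) {
      # half null sequences, half with a rate step
      p <- if (i %% 2 == 0) {
        cumsum(rexp(sample(4:30, 1), 0.5))
      } else {
        n1 <- sample(2:10, 1)
        n2 <- sample(2:15, 1)
        cumsum(c(rexp(n1, 0.2), rexp(n2, 3)))
      }
      got <- first_change_point(p, cfg, min_start_time = 0)
      want <- brute_force_first_change(p, cfg, min_start = 0)
      expect_equal(got$change_index, as.integer(want$index))
      expect_equal(got$change_time, as.numeric(want$time))
    }
  })
})

test_that("raising the Bayes-factor criterion never hastens detection", {
  withr::with_seed(29, {
    for (i in 1:100) {
      p <- cumsum(c(rexp(8, 0.3), rexp(10, 2)))
      t10 <- first_change_point(p, cprl_config(bf_threshold = 10),
                                min_start_time = 0)$change_time
      t100 <- first_change_point(p, cprl_config(bf_threshold = 100),
                                 min_start_time = 0)$change_time
      if (is.na(t10)) {
        expect_true(is.na(t100)) # no detection can appear at a stricter bar
      } else if (!is.na(t100)) {
        expect_gte(t100, t10)
      }
    }
  })
})

test_that("Bayes factors are scale-invariant when the prior scale follows", {
  x <- withr::with_seed(31, c(rexp(8, 0.5), rexp(8, 4)))
  for (c_scale in c(0.1, 3, 40)) {
    bf_a <- bayes_factor_change(x, cprl_config(prior_rate = 1.7))
    bf_b <- bayes_factor_change(x * c_scale,
                                cprl_config(prior_rate = 1.7 * c_scale))
    expect_equal(bf_a$log_bf, bf_b$log_bf)
    expect_equal(bf_a$split_index, bf_b$split_index)
  }
})

test_that("detection is calibrated: rare on null sequences, fast on steps", {
  cfg <- cprl_config()
  # false positives on exchangeable exponential IPIs
  fp <- withr::with_seed(37, mean(replicate(500, {
    p <- cumsum(rexp(30, 1))
    !is.na(first_change_point(p, cfg, min_start_time = 0)$change_time)
  })))
  expect_lte(fp, 0.05)
  # power and timing on an 8x rate step with 15 IPIs per segment
  res <- withr::with_seed(41, replicate(500, {
    p <- cumsum(c(rexp(15, 0.25), rexp(15, 2)))
    true_t <- p[16]
    ct <- first_change_point(p, cfg, min_start_time = 0)$change_time
    c(hit = !is.na(ct), err = abs(ct - true_t))
  }))
  expect_gte(mean(res["hit", ]), 0.80)
  expect_lte(median(res["err", ], na.rm = TRUE), 3)
})

test_that("a trial with too few presses yields a missing change point", {
  expect_true(is.na(first_change_point(c(6, 9), cprl_config())$change_time))
  expect_true(is.na(first_change_point(numeric(0),
                                       cprl_config())$change_time))
})
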