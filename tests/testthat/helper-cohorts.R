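# Shared simulated cohorts, built once per test run and cached.
# Sizes are kept moderate so the default suite stays fast; the acceptance
# tests use the same cached objects.

.sfi_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .sfi_cache)) {
    assign(name, force(expr), envir = .sfi_cache)
  }
  get(name, envir = .sfi_cache)
}

# default study cohort: one-shot scalar-timing agent, 20 subjects
default_cohort <- function() {
  cached("default_cohort", simulate_cohort(
    sfi_protocol(), agent_params(), n_subjects = 20, seed = 101
  ))
}

default_start_times <- function() {
  cached("default_start_times", estimate_start_times(default_cohort()))
}

# noiseless one-shot agent cohort for exact-scaling checks
noiseless_cohort <- function() {
  cached("noiseless_cohort", simulate_cohort(
    sfi_protocol(), agent_params(weber_cv = 0), n_subjects = 10, seed = 202
  ))
}

noiseless_start_times <- function() {
  cached("noiseless_start_times", estimate_start_times(noiseless_cohort()))
}

# gradual learner for latency contrasts
gradual_cohort <- function(learning_rate = 0.05, n_subjects = 20,
                           seed = 303) {
  key <- sprintf("gradual_%g_%d_%d", learning_rate, n_subjects, seed)
  cached(key, simulate_cohort(
    sfi_protocol(), agent_params(learning_rate = learning_rate),
    n_subjects = n_subjects, seed = seed
  ))
}

# brute-force oracle for the burst scan: check every consecutive triple
brute_force_burst <- function(presses, threshold, min_start = 5,
                              burst_length = 3) {
  n <- length(presses)
  if (n < burst_length) return(NA_real_)
  for (i in seq_len(n - burst_length + 1L)) {
    run <- presses[i:(i + burst_length - 1L)]
    if (all(diff(run) <= threshold) && run[1L] >= min_start) {
      return(run[1L])
    }
  }
  NA_real_
}

# brute-force oracle for online change-point detection: evaluates every
# (prefix, split) pair directly from the marginal-likelihood definition
brute_force_first_change <- function(presses, cfg, min_start = 5) {
  ipis <- diff(presses)
  n <- length(ipis)
  ms <- cfg$min_segment
  if (n < 2 * ms) return(list(index = NA, time = NA))
  if (is.null(cfg$prior_rate)) {
    cfg$prior_rate <- cfg$prior_scale * stats::median(ipis)
  }
  m_of <- function(x) {
    marginal_loglik_exp(x, cfg$prior_shape, cfg$prior_rate)
  }
  for (m in (2 * ms):n) {
    best_lbf <- -Inf
    best_c <- NA
    for (c in ms:(m - ms)) {
      lbf <- m_of(ipis[1:c]) + m_of(ipis[(c + 1):m]) - m_of(ipis[1:m])
      if (lbf > best_lbf) {
        best_lbf <- lbf
        best_c <- c
      }
    }
    if (exp(best_lbf) >= cfg$bf_threshold) {
      time <- presses[best_c + 1L]
      if (time >= min_start) return(list(index = best_c, time = time))
    }
  }
  list(index = NA, time = NA)
}

# random press sequence generator for oracle comparisons
random_presses <- function(n_max = 25) {
  n <- sample(3:n_max, 1)
  sort(round(runif(n, 0, 60), 3)) |> unique()
}
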