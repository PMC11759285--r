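# Press times are generated as a piecewise-constant Poisson process:
# baseline_rate from consumption_delay onward, plus high_rate from the
# sampled start time onward. Candidate gaps that would cross the rate
# change point are redrawn from the change point (exact by memorylessness).
# All times are rounded to 1 ms, the resolution floor of the event log;
# rounding never breaks strict monotonicity (a 1 ms minimum gap is kept).
generate_press_times <- function(fi, start_time, params) {
  # each homogeneous stream runs until its own first event at/after fi;
  # the merged trial then truncates at its earliest event >= fi
  baseline <- poisson_stream(params$consumption_delay,
                             params$baseline_rate, fi)
  high <- poisson_stream(start_time, params$high_rate, fi)
  presses <- round_ms(sort(c(baseline, high)))
  if (length(presses) > 1L) {
    d <- diff(presses)
    if (any(d < 0.001)) {
      # enforce the 1 ms grid: push colliding rounded presses apart
      presses <- round_ms(Reduce(function(prev, x) max(x, prev + 0.001),
                                 presses, accumulate = TRUE))
    }
  }
  # the reward rule operates on the grid the log records: the first
  # rounded press at/after the deadline ends the trial
  presses[seq_len(which(presses >= fi)[1L])]
}

# events of a homogeneous Poisson process started at `from`, up to and
# including the first event at or after `horizon`
poisson_stream <- function(from, rate, horizon) {
  if (rate <= 0) return(numeric(0))
  events <- numeric(0)
  t <- from
  chunk <- max(16L, ceiling(rate * (horizon - from) * 1.25))
  repeat {
    gaps <- rexp(chunk, rate)
    new <- t + cumsum(gaps)
    events <- c(events, new)
    t <- new[length(new)]
    if (t >= horizon) break
    chunk <- max(16L, ceiling(rate * (horizon - t) * 1.5))
  }
  events[seq_len(which(events >= horizon)[1L])]
}

#' Simulate a single fixed-interval trial
#'
#' Generates one trial of the sFI task: the agent presses at
#' `baseline_rate` from the end of the consumption pause, switches to
#' `baseline_rate + high_rate` at a start time sampled by
#' [agent_start_time()] from its current FI estimate, and the first press at
#' or after `fi` seconds is rewarded and ends the trial.
#'
#' @param fi FI duration of the trial (s), > 0.
#' @param current_estimate The agent's current FI estimate (s).
#' @param params An [agent_params()] object.
#' @return A list with `press_times` (strictly increasing, the last element
#'   being the rewarded press), `reward_time`, and the sampled
#'   `start_time`.
#' @examples
#' withr::with_seed(1, simulate_trial(36, 36, agent_params()))
#' @export
simulate_trial <- function(fi, current_estimate, params) {
  check_number(fi, "fi", min = 0, strict_min = TRUE)
  start_time <- agent_start_time(current_estimate, params)
  presses <- generate_press_times(fi, start_time, params)
  list(
    press_times = presses,
    reward_time = presses[length(presses)],
    start_time = start_time
  )
}

#' Simulate a complete sFI session
#'
#' Runs the agent through a session of the given protocol: FI durations and
#' block lengths are drawn without replacement (refreshing on exhaustion;
#' fresh lists every session), trials are generated sequentially, and after
#' every reward the agent's FI estimate is updated toward the experienced
#' trial duration (its reward time) by the delta rule. The session stops at
#' `max_rewards` rewards, or at the first trial whose start would fall at or
#' beyond `max_session_time`; a trial already in progress at timeout runs to
#' completion.
#'
#' For the `"de_novo"` variant a fresh rescaled duration list is generated
#' for the session before any drawing.
#'
#' @param protocol An [sfi_protocol()] object.
#' @param params An [agent_params()] object.
#' @param subject_id Subject label.
#' @param day Session day (1-based).
#' @param seed Optional integer seed; when given, the session is generated
#'   under [withr::with_seed()] and is exactly reproducible.
#' @return A tibble with one row per trial and columns `subject_id`, `day`,
#'   `block_index`, `trial_index_in_block`, `fi_duration`, `press_times`
#'   (list column), `reward_time`. The seed (if any) is stored in attribute
#'   `"seed"`.
#' @examples
#' s <- simulate_session(sfi_protocol(), agent_params(), seed = 1)
#' nrow(s) # <= 100 rewards
#' @export
simulate_session <- function(protocol, params, subject_id = "s01", day = 1,
                             seed = NULL) {
  stopifnot(inherits(protocol, "sfi_protocol"), inherits(params, "sfi_agent"))
  run <- function() simulate_session_impl(protocol, params, subject_id, day)
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  attr(out, "seed") <- seed
  attr(out, "protocol") <- protocol
  attr(out, "params") <- params
  out
}

simulate_session_impl <- function(protocol, params, subject_id, day) {
  durations <- protocol$base_durations
  if (protocol$variant == "de_novo") {
    durations <- scale_durations_de_novo(durations)
  }
  # without-replacement pools, refreshed independently on exhaustion
  dur_pool <- numeric(0)
  len_pool <- integer(0)
  next_duration <- function() {
    if (length(dur_pool) == 0L) {
      dur_pool <<- durations[sample.int(length(durations))]
    }
    d <- dur_pool[1L]
    dur_pool <<- dur_pool[-1L]
    d
  }
  next_length <- function() {
    if (length(len_pool) == 0L) {
      len_pool <<- protocol$block_lengths[
        sample.int(length(protocol$block_lengths))]
    }
    l <- len_pool[1L]
    len_pool <<- len_pool[-1L]
    l
  }

  estimate <- params$initial_estimate
  elapsed <- 0
  rows <- vector("list", protocol$max_rewards)
  n <- 0L
  block_index <- 0L
  trial_in_block <- 0L
  block_length <- 0L
  fi <- NA_real_

  while (n < protocol$max_rewards && elapsed < protocol$max_session_time) {
    if (trial_in_block == block_length) {
      block_index <- block_index + 1L
      trial_in_block <- 0L
      block_length <- next_length()
      fi <- next_duration()
    }
    trial_in_block <- trial_in_block + 1L
    tr <- simulate_trial(fi, estimate, params)
    n <- n + 1L
    rows[[n]] <- tibble::tibble(
      subject_id = subject_id,
      day = as.integer(day),
      block_index = block_index,
      trial_index_in_block = trial_in_block,
      fi_duration = fi,
      press_times = list(tr$press_times),
      reward_time = tr$reward_time
    )
    elapsed <- elapsed + tr$reward_time
    estimate <- agent_update_estimate(estimate, tr$reward_time,
                                      params$learning_rate)
  }
  dplyr::bind_rows(rows[seq_len(n)])
}

#' Simulate a cohort of subjects
#'
#' Convenience wrapper running [simulate_session()] for `n_subjects`
#' subjects over `n_days` days each. Per-session seeds are derived from
#' `seed` so the whole cohort is reproducible and sessions are mutually
#' independent.
#'
#' @inheritParams simulate_session
#' @param n_subjects Number of subjects.
#' @param n_days Sessions per subject.
#' @param seed Optional master seed.
#' @return A tibble of trials (all sessions row-bound).
#' @examples
#' cohort <- simulate_cohort(sfi_protocol(), agent_params(),
#'                           n_subjects = 2, seed = 1)
#' dplyr::count(cohort, subject_id)
#' @export
simulate_cohort <- function(protocol, params, n_subjects = 20, n_days = 1,
                            seed = NULL) {
  check_number(n_subjects, "n_subjects", min = 1)
  check_number(n_days, "n_days", min = 1)
  n_sessions <- n_subjects * n_days
  session_seeds <- if (is.null(seed)) {
    sample.int(2147483646L, n_sessions)
  } else {
    withr::with_seed(seed, sample.int(2147483646L, n_sessions))
  }
  grid <- expand.grid(day = seq_len(n_days), subject = seq_len(n_subjects))
  purrr::map2_dfr(grid$subject, seq_len(n_sessions), function(s, i) {
    simulate_session(
      protocol, params,
      subject_id = sprintf("s%02d", s),
      day = grid$day[i],
      seed = session_seeds[i]
    )
  })
}
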