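#' Start-time estimator settings
#'
#' Settings shared by the four single-trial start-time estimators. Because
#' every trial ends in a reward and pressing routinely continues across the
#' reward, presses earlier than `min_start_time` (default 5 s) are never
#' accepted as start times. A burst is `burst_length` presses whose
#' inter-press intervals (IPIs) all fall within the smallest
#' `burst_ipi_quantile` of the experiment's pooled IPI distribution. The
#' rate-increase estimator bins presses at `rate_bin` seconds, smooths with
#' a centred moving average of `smooth_window` bins, and detects the first
#' bin whose smoothed rate exceeds `rate_multiplier` times the
#' session-average press rate.
#'
#' @param min_start_time Earliest admissible start time (s), default 5.
#' @param burst_length Presses per burst, default 3.
#' @param burst_ipi_quantile Fraction defining "fast" IPIs, default 0.40.
#' @param rate_bin Rate histogram bin width (s), default 1.
#' @param smooth_window Moving-average width in bins; odd, default 3.
#' @param rate_multiplier Threshold multiple of the session-average rate,
#'   default 2.
#' @return An object of class `sfi_metric_config`.
#' @export
metric_config <- function(min_start_time = 5,
                          burst_length = 3,
                          burst_ipi_quantile = 0.40,
                          rate_bin = 1,
                          smooth_window = 3,
                          rate_multiplier = 2) {
  check_number(min_start_time, "min_start_time", min = 0)
  check_number(burst_length, "burst_length", min = 2)
  check_number(burst_ipi_quantile, "burst_ipi_quantile", min = 0, max = 1,
               strict_min = TRUE)
  if (burst_ipi_quantile >= 1) stop_invalid("`burst_ipi_quantile` must be < 1.")
  check_number(rate_bin, "rate_bin", min = 0, strict_min = TRUE)
  check_number(smooth_window, "smooth_window", min = 1)
  if (smooth_window %% 2 != 1) stop_invalid("`smooth_window` must be odd.")
  check_number(rate_multiplier, "rate_multiplier", min = 1, strict_min = TRUE)
  structure(
    list(
      min_start_time = min_start_time,
      burst_length = as.integer(burst_length),
      burst_ipi_quantile = burst_ipi_quantile,
      rate_bin = rate_bin,
      smooth_window = as.integer(smooth_window),
      rate_multiplier = rate_multiplier
    ),
    class = "sfi_metric_config"
  )
}

#' Pool within-trial inter-press intervals
#'
#' Collects the IPIs (successive differences of press times) of every trial
#' in `trials` into one vector. IPIs never span trials; the last press of a
#' trial is the rewarded press, so all pooled IPIs are within-trial by
#' construction.
#'
#' @param trials A trials tibble (see [simulate_session()]).
#' @return Numeric vector of IPIs in seconds.
#' @export
pool_ipis <- function(trials) {
  check_trials(trials)
  unlist(purrr::map(trials$press_times, diff), use.names = FALSE)
}

#' Fast-IPI threshold from the pooled IPI distribution
#'
#' Nearest-rank (type 1) empirical quantile of the pooled IPIs; an IPI
#' counts as "fast" when it is less than or equal to this threshold. The
#' pooling scope is the whole experiment (all trials of all subjects), so
#' the burst definition accounts for overall differences in pressing vigour
#' between cohorts.
#'
#' @param ipis Pooled IPIs (s), non-empty.
#' @param quantile Fraction, default 0.40.
#' @return The threshold in seconds.
#' @examples
#' ipi_threshold(c(0.2, 0.4, 0.6, 0.8, 1.0)) # 0.4
#' @export
ipi_threshold <- function(ipis, quantile = 0.40) {
  if (length(ipis) == 0L) stop_invalid("`ipis` must be non-empty.")
  check_number(quantile, "quantile", min = 0, max = 1, strict_min = TRUE)
  unname(stats::quantile(ipis, probs = quantile, type = 1, names = FALSE))
}

#' First press at or after the censoring time
#'
#' @param press_times Press times of one trial (s).
#' @param min_start_time Censoring time (s), default 5.
#' @return Time of the first admissible press, or `NA` if none.
#' @examples
#' first_press_time(c(2.1, 7.3, 9.0)) # 7.3
#' @export
first_press_time <- function(press_times, min_start_time = 5) {
  ok <- press_times[press_times >= min_start_time]
  if (length(ok)) ok[1L] else NA_real_
}

#' First burst of fast pressing
#'
#' Scans consecutive runs of `burst_length` presses; a run is a burst when
#' all of its IPIs are at or below `threshold` (see [ipi_threshold()]). The
#' burst's time is the first press of the run; the earliest burst whose
#' first press is at or after `min_start_time` is reported.
#'
#' @param press_times Press times of one trial (s).
#' @param threshold Fast-IPI threshold (s), > 0.
#' @param min_start_time Censoring time (s), default 5.
#' @param burst_length Presses per burst, default 3.
#' @return Burst onset time, or `NA` if the trial has no admissible burst.
#' @examples
#' first_burst_time(c(6.0, 8.0, 8.1, 8.2), threshold = 0.3) # 8.0
#' @export
first_burst_time <- function(press_times, threshold, min_start_time = 5,
                             burst_length = 3) {
  check_number(threshold, "threshold", min = 0, strict_min = TRUE)
  k <- burst_length - 1L # IPIs per burst
  ipis <- diff(press_times)
  if (length(ipis) < k) return(NA_real_)
  fast <- ipis <= threshold
  n_starts <- length(ipis) - k + 1L
  ok <- rep(TRUE, n_starts)
  for (j in seq_len(k)) {
    ok <- ok & fast[seq_len(n_starts) + j - 1L]
  }
  starts <- which(ok & press_times[seq_len(n_starts)] >= min_start_time)
  if (length(starts)) press_times[starts[1L]] else NA_real_
}

#' Smoothed per-bin press-rate series of a trial
#'
#' Counts presses in consecutive `[t, t + rate_bin)` bins spanning the trial
#' and applies a centred moving average of `smooth_window` bins, truncating
#' the window at the edges (the average is taken over the bins available).
#'
#' @param press_times Press times of one trial (s).
#' @param duration Trial duration (s); normally the reward time.
#' @param rate_bin Bin width (s), default 1.
#' @param smooth_window Odd moving-average width in bins, default 3.
#' @return A tibble with `bin_start`, `rate`, `smoothed` (presses/s).
#' @export
smoothed_rate_series <- function(press_times, duration, rate_bin = 1,
                                 smooth_window = 3) {
  check_number(duration, "duration", min = 0, strict_min = TRUE)
  n_bins <- max(1L, as.integer(ceiling(duration / rate_bin - 1e-9)))
  idx <- pmin(floor(press_times / rate_bin) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  rate <- counts / rate_bin
  half <- (smooth_window - 1L) %/% 2L
  smoothed <- vapply(seq_len(n_bins), function(i) {
    mean(rate[max(1L, i - half):min(n_bins, i + half)])
  }, numeric(1))
  tibble::tibble(
    bin_start = (seq_len(n_bins) - 1) * rate_bin,
    rate = rate,
    smoothed = smoothed
  )
}

#' Session-average press rate
#'
#' Total presses divided by total trial time, per session (subject x day).
#' This is the baseline against which the rate-increase estimator sets its
#' doubling threshold, computed across the entire session (all blocks).
#'
#' @param trials A trials tibble.
#' @return A tibble with `subject_id`, `day`, `baseline_rate` (presses/s).
#' @export
session_baseline_rate <- function(trials) {
  check_trials(trials)
  if (nrow(trials) == 0L) stop_invalid("`trials` must contain trials.")
  trials |>
    dplyr::group_by(.data$subject_id, .data$day) |>
    dplyr::summarise(
      baseline_rate = sum(lengths(.data$press_times)) / sum(.data$reward_time),
      .groups = "drop"
    )
}

#' Time the smoothed press rate doubles over the session average
#'
#' Returns the left edge of the earliest bin whose smoothed rate is
#' strictly greater than `rate_multiplier` times `baseline_rate` and whose
#' bin start is at or after `min_start_time`; `NA` if no crossing.
#'
#' @param press_times Press times of one trial (s).
#' @param duration Trial duration (s).
#' @param baseline_rate Session-average press rate (presses/s), > 0.
#' @param min_start_time Censoring time (s), default 5.
#' @inheritParams smoothed_rate_series
#' @param rate_multiplier Threshold multiple, default 2.
#' @return Crossing time (s) or `NA`.
#' @export
rate_increase_time <- function(press_times, duration, baseline_rate,
                               min_start_time = 5, rate_bin = 1,
                               smooth_window = 3, rate_multiplier = 2) {
  check_number(baseline_rate, "baseline_rate", min = 0, strict_min = TRUE)
  series <- smoothed_rate_series(press_times, duration, rate_bin,
                                 smooth_window)
  hit <- which(series$smoothed > rate_multiplier * baseline_rate &
                 series$bin_start >= min_start_time)
  if (length(hit)) series$bin_start[hit[1L]] else NA_real_
}

#' Compute all four start-time estimates per trial
#'
#' Builds the per-trial start-time table: the analysis unit for everything
#' downstream. Each trial of the first `max_blocks` blocks (default 5 —
#' responding wanes in later blocks) gets four independently computed
#' estimates:
#' \describe{
#'   \item{`first_press`}{first press at/after the censoring time.}
#'   \item{`first_burst`}{onset of the first run of `burst_length` presses
#'     with all IPIs within the experiment's fastest 40%.}
#'   \item{`rate_increase`}{first time the 3-s-smoothed per-second press
#'     rate exceeds twice the session-average rate.}
#'   \item{`change_point`}{first Bayesian change point of the trial's IPI
#'     sequence at Bayes factor >= 10 (see [first_change_point()]).}
#' }
#' The fast-IPI threshold and the change-point prior scale are fixed once
#' from the IPIs pooled across the entire input (the "experiment"), before
#' any per-trial analysis. Estimates undefined on a trial are `NA` and are
#' excluded pairwise downstream, never imputed.
#'
#' @param trials A trials tibble covering one experiment.
#' @param cfg A [metric_config()].
#' @param cprl A [cprl_config()]; its `prior_rate`, when `NULL`, is set to
#'   `prior_scale` times the median pooled IPI.
#' @param max_blocks Blocks retained per session, default 5.
#' @return A tibble (one row per analysed trial): `subject_id`, `day`,
#'   `block_index`, `trial_index_in_block`, `fi_duration`, `first_press`,
#'   `first_burst`, `rate_increase`, `change_point`.
#' @examples
#' trials <- simulate_session(sfi_protocol(), agent_params(), seed = 1)
#' head(estimate_start_times(trials))
#' @export
estimate_start_times <- function(trials, cfg = metric_config(),
                                 cprl = cprl_config(), max_blocks = 5) {
  check_trials(trials)
  if (nrow(trials) == 0L) stop_invalid("`trials` must contain trials.")
  pooled <- pool_ipis(trials)
  if (length(pooled) == 0L) {
    stop_invalid("no inter-press intervals in `trials`.")
  }
  threshold <- ipi_threshold(pooled, cfg$burst_ipi_quantile)
  cprl <- resolve_cprl_prior(cprl, pooled)
  baselines <- session_baseline_rate(trials)

  kept <- trials |>
    dplyr::filter(.data$block_index <= max_blocks) |>
    dplyr::left_join(baselines, by = c("subject_id", "day"))

  kept |>
    dplyr::mutate(
      first_press = purrr::map_dbl(
        .data$press_times, first_press_time,
        min_start_time = cfg$min_start_time
      ),
      first_burst = purrr::map_dbl(
        .data$press_times, first_burst_time,
        threshold = threshold,
        min_start_time = cfg$min_start_time,
        burst_length = cfg$burst_length
      ),
      rate_increase = purrr::pmap_dbl(
        list(.data$press_times, .data$reward_time, .data$baseline_rate),
        function(p, d, b) {
          rate_increase_time(
            p, d, b,
            min_start_time = cfg$min_start_time,
            rate_bin = cfg$rate_bin,
            smooth_window = cfg$smooth_window,
            rate_multiplier = cfg$rate_multiplier
          )
        }
      ),
      change_point = purrr::map_dbl(
        .data$press_times,
        function(p) {
          first_change_point(p, cprl,
                             min_start_time = cfg$min_start_time)$change_time
        }
      )
    ) |>
    dplyr::select(
      "subject_id", "day", "block_index", "trial_index_in_block",
      "fi_duration", "first_press", "first_burst", "rate_increase",
      "change_point"
    )
}

start_metric_names <- function() {
  c("first_press", "first_burst", "rate_increase", "change_point")
}
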