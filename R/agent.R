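#' Parameters of the scalar-timing pressing agent
#'
#' The simulated presser is a reduced scalar-timing agent. It holds a
#' running estimate of the current FI duration and, on each trial, switches
#' from a low-rate baseline Poisson pressing state to a high-rate state at a
#' start time drawn from a truncated normal whose mean is
#' `threshold_fraction` times the current estimate and whose standard
#' deviation is proportional to that mean (`weber_cv`, the scalar-timing
#' property: constant coefficient of variation). After every reward the
#' estimate moves toward the experienced trial duration by a delta rule with
#' `learning_rate`; `learning_rate = 1` is one-shot updating, small values
#' give gradual updating.
#'
#' `threshold_fraction = 0.5` matches the empirical observation that rodent
#' start times scale linearly with FI duration with a slope around 0.5 — in
#' drift-diffusion terms, responding begins when the accumulator reaches
#' about half its maximum height.
#'
#' @param preset `"fast"` (one-shot updating, `learning_rate = 1`, the
#'   default) or `"slow"` (`learning_rate = 0.2`). Explicit arguments
#'   override the preset.
#' @param baseline_rate Low-state Poisson press rate, presses/s.
#' @param high_rate Additional press rate of the timed high state,
#'   presses/s; must exceed `2 * baseline_rate` so the rate-doubling
#'   estimator has a detectable step.
#' @param threshold_fraction Start-time mean as a fraction of the current
#'   FI estimate, in (0, 1].
#' @param weber_cv Coefficient of variation of the start time (SD = cv
#'   times mean); 0 gives a deterministic start.
#' @param learning_rate Delta-rule learning rate in \[0, 1\].
#' @param consumption_delay Seconds after trial start with no pressing
#'   (reward consumption). A long delay (e.g. 8 s) reproduces the sparse
#'   pressing seen on the shortest intervals when eating time eats most of
#'   the trial.
#' @param initial_estimate Initial FI estimate in seconds.
#'
#' @return An object of class `sfi_agent`.
#' @seealso [simulate_session()], [agent_update_estimate()]
#' @examples
#' agent_params()
#' agent_params("slow", weber_cv = 0.1)
#' @export
agent_params <- function(preset = c("fast", "slow"),
                         baseline_rate = 0.1,
                         high_rate = 2,
                         threshold_fraction = 0.5,
                         weber_cv = 0.2,
                         learning_rate = NULL,
                         consumption_delay = 1,
                         initial_estimate = 36) {
  preset <- match.arg(preset)
  if (is.null(learning_rate)) {
    learning_rate <- switch(preset, fast = 1, slow = 0.2)
  }
  check_number(baseline_rate, "baseline_rate", min = 0)
  check_number(high_rate, "high_rate", min = 0, strict_min = TRUE)
  if (high_rate <= 2 * baseline_rate) {
    stop_invalid("`high_rate` must exceed 2 * `baseline_rate`.")
  }
  check_number(threshold_fraction, "threshold_fraction", min = 0, max = 1,
               strict_min = TRUE)
  check_number(weber_cv, "weber_cv", min = 0)
  check_number(learning_rate, "learning_rate", min = 0, max = 1)
  check_number(consumption_delay, "consumption_delay", min = 0)
  check_number(initial_estimate, "initial_estimate", min = 0,
               strict_min = TRUE)
  structure(
    list(
      preset = preset,
      baseline_rate = baseline_rate,
      high_rate = high_rate,
      threshold_fraction = threshold_fraction,
      weber_cv = weber_cv,
      learning_rate = learning_rate,
      consumption_delay = consumption_delay,
      initial_estimate = initial_estimate
    ),
    class = "sfi_agent"
  )
}

#' @export
print.sfi_agent <- function(x, ...) {
  cat("<sfi_agent>", x$preset, "preset\n")
  cat(sprintf("  rates: baseline %.3g + high %.3g presses/s\n",
              x$baseline_rate, x$high_rate))
  cat(sprintf("  start ~ %.2g x estimate, CV %.2g, floor %.3g s\n",
              x$threshold_fraction, x$weber_cv, x$consumption_delay))
  cat(sprintf("  learning rate %.2g, initial estimate %.3g s\n",
              x$learning_rate, x$initial_estimate))
  invisible(x)
}

#' Sample a high-state start time for one trial
#'
#' Draws from Normal(mean = `threshold_fraction * current_estimate`,
#' sd = `weber_cv` * mean), truncated below at `consumption_delay`, using
#' inverse-CDF sampling from the current RNG. With `weber_cv = 0` the draw
#' is deterministic: `max(mean, consumption_delay)`.
#'
#' @param current_estimate The agent's current FI estimate (s), > 0.
#' @param params An [agent_params()] object.
#' @return Start time in seconds.
#' @export
agent_start_time <- function(current_estimate, params) {
  check_number(current_estimate, "current_estimate", min = 0,
               strict_min = TRUE)
  mu <- params$threshold_fraction * current_estimate
  sd <- params$weber_cv * mu
  lo <- params$consumption_delay
  if (sd == 0) {
    return(max(mu, lo))
  }
  p_lo <- pnorm(lo, mean = mu, sd = sd)
  u <- runif(1, min = p_lo, max = 1)
  qnorm(u, mean = mu, sd = sd)
}

#' Delta-rule update of the agent's FI estimate
#'
#' `new = old + learning_rate * (experienced - old)`. The experienced
#' interval is the trial's reward time — the only duration feedback the
#' task delivers, since nothing but the pellet signals the end of a trial.
#' With `learning_rate = 1` the estimate snaps to the experienced interval
#' after a single exposure (one-shot updating).
#'
#' @param old_estimate Current estimate (s), > 0.
#' @param experienced_interval Experienced trial duration (s), > 0.
#' @param learning_rate Learning rate in \[0, 1\].
#' @return Updated estimate (s). Vectorised over its first two arguments.
#' @examples
#' agent_update_estimate(36, 60, 1) # one-shot: 60
#' agent_update_estimate(36, 60, 0.25) # 42
#' @export
agent_update_estimate <- function(old_estimate, experienced_interval,
                                  learning_rate) {
  if (any(old_estimate <= 0) || any(experienced_interval <= 0)) {
    stop_invalid("estimates and experienced intervals must be positive.")
  }
  check_number(learning_rate, "learning_rate", min = 0, max = 1)
  old_estimate + learning_rate * (experienced_interval - old_estimate)
}
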