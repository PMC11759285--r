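#' Define a serial fixed-interval protocol
#'
#' A serial fixed-interval (sFI) session presents fixed-interval (FI) trials
#' in blocks; at the end of each block the FI duration changes without any
#' cue. Durations and block lengths are each drawn without replacement from
#' their lists, the lists being refreshed on exhaustion and at the start of
#' every session. A session ends once `max_rewards` rewards have been earned
#' or `max_session_time` seconds have elapsed, whichever comes first.
#'
#' Three variants are supported:
#' * `"fixed"` — the standard task: FI durations 12, 24, 36, 48, 60 s in
#'   blocks of 13, 15, 17, 19 or 21 trials.
#' * `"novel"` — same structure with durations 13, 15, 31, 45, 57 s, used to
#'   probe transfer to intervals never trained on.
#' * `"de_novo"` — each session rescales the base durations by an
#'   independent uniform factor in \[0.8, 1.2\] so no exact duration repeats
#'   across days (see [scale_durations_de_novo()]).
#'
#' @param variant Protocol variant, one of `"fixed"`, `"novel"`, `"de_novo"`.
#' @param base_durations Ordered FI durations in seconds. Defaults to
#'   `c(12, 24, 36, 48, 60)` (`c(13, 15, 31, 45, 57)` for `"novel"`).
#' @param block_lengths Candidate block lengths (trials per block).
#' @param max_rewards Session ends after this many rewards (default 100).
#' @param max_session_time Session time limit in seconds (default 5400,
#'   i.e. 90 min).
#'
#' @return An object of class `sfi_protocol`.
#' @seealso [simulate_session()], [agent_params()]
#' @examples
#' sfi_protocol()
#' sfi_protocol("novel")
#' @export
sfi_protocol <- function(variant = c("fixed", "novel", "de_novo"),
                         base_durations = NULL,
                         block_lengths = c(13, 15, 17, 19, 21),
                         max_rewards = 100,
                         max_session_time = 5400) {
  variant <- match.arg(variant)
  if (is.null(base_durations)) {
    base_durations <- if (variant == "novel") {
      c(13, 15, 31, 45, 57)
    } else {
      c(12, 24, 36, 48, 60)
    }
  }
  if (!is.numeric(base_durations) || length(base_durations) < 1L ||
      any(base_durations <= 0)) {
    stop_invalid("`base_durations` must be positive numbers.")
  }
  if (is.unsorted(base_durations, strictly = TRUE)) {
    stop_invalid("`base_durations` must be strictly increasing.")
  }
  if (!is.numeric(block_lengths) || length(block_lengths) < 1L ||
      any(block_lengths < 1)) {
    stop_invalid("`block_lengths` must all be >= 1.")
  }
  check_number(max_rewards, "max_rewards", min = 1)
  check_number(max_session_time, "max_session_time", min = 0, strict_min = TRUE)
  structure(
    list(
      variant = variant,
      base_durations = as.numeric(base_durations),
      block_lengths = as.integer(block_lengths),
      max_rewards = as.integer(max_rewards),
      max_session_time = as.numeric(max_session_time)
    ),
    class = "sfi_protocol"
  )
}

#' @export
print.sfi_protocol <- function(x, ...) {
  cat("<sfi_protocol>", x$variant, "\n")
  cat("  FI durations (s):", paste(x$base_durations, collapse = ", "), "\n")
  cat("  block lengths:   ", paste(x$block_lengths, collapse = ", "), "\n")
  cat("  stops at", x$max_rewards, "rewards or", x$max_session_time, "s\n")
  invisible(x)
}

#' Draw a sequence of values without replacement, with refresh
#'
#' Values are drawn without replacement from `values`; once every value has
#' been used the list refreshes and drawing starts over, so every aligned
#' window of `length(values)` draws is a permutation of the list. This is
#' how both the FI-duration list and the block-length list are consumed
#' within an sFI session. Lists never carry over between sessions.
#'
#' Uses the current R random number generator; seed the caller (e.g. with
#' [withr::with_seed()]) for reproducibility.
#'
#' @param values Non-empty vector to draw from.
#' @param n_items Number of draws to return.
#' @return A vector of `n_items` draws.
#' @examples
#' withr::with_seed(1, draw_without_replacement(c(12, 24, 36, 48, 60), 7))
#' @export
draw_without_replacement <- function(values, n_items) {
  if (length(values) == 0L) stop_invalid("`values` must be non-empty.")
  check_number(n_items, "n_items", min = 1)
  n_items <- as.integer(n_items)
  k <- length(values)
  n_windows <- ceiling(n_items / k)
  out <- unlist(lapply(seq_len(n_windows), function(i) {
    values[sample.int(k)]
  }), use.names = FALSE)
  out[seq_len(n_items)]
}

#' Rescale base FI durations for a de-novo session
#'
#' Each base duration d is multiplied by an independent factor
#' `0.8 + 0.4 * X` with X uniform on \[0, 1\], giving a session-specific
#' list within 80--120% of the base values. Durations are rounded to 1 ms.
#'
#' @param base_durations Positive base durations in seconds.
#' @param x Optional vector of uniform variates in \[0, 1\] (recycled to the
#'   length of `base_durations`); drawn from the current RNG when `NULL`.
#'   Supplying `x` makes the scaling deterministic, e.g. for testing bounds.
#' @return Rescaled durations, same length as `base_durations`.
#' @examples
#' scale_durations_de_novo(c(12, 24, 36, 48, 60), x = rep(0.5, 5))
#' @export
scale_durations_de_novo <- function(base_durations, x = NULL) {
  if (!is.numeric(base_durations) || length(base_durations) < 1L ||
      any(base_durations <= 0)) {
    stop_invalid("`base_durations` must be positive numbers.")
  }
  if (is.null(x)) {
    x <- runif(length(base_durations))
  } else {
    if (!is.numeric(x) || any(x < 0 | x > 1)) {
      stop_invalid("`x` must lie in [0, 1].")
    }
    x <- rep_len(x, length(base_durations))
  }
  round_ms(base_durations * (0.8 + 0.4 * x))
}

#' Check novel durations against percentage bounds of the base list
#'
#' Positionally compares a novel duration list against the base list and
#' reports each ratio as a percentage, flagging whether all ratios fall
#' inside `[low, high]`. The standard check for candidate novel-interval
#' lists requires every ratio within 60--140% of the original value.
#'
#' @param base,novel Positionally matched duration vectors (seconds).
#' @param low,high Bounds in percent (defaults 60 and 140).
#' @return A tibble with columns `base`, `novel`, `ratio_pct`, `within`,
#'   of class `sfi_ratio_check`; `glance()` returns the overall pass flag
#'   and ratio range.
#' @examples
#' chk <- validate_duration_ratios(c(12, 24, 36, 48, 60), c(13, 15, 31, 45, 57))
#' glance(chk)
#' @export
validate_duration_ratios <- function(base, novel, low = 60, high = 140) {
  if (length(base) != length(novel)) {
    stop_invalid("`base` and `novel` must have the same length.")
  }
  if (any(base <= 0) || any(novel <= 0)) {
    stop_invalid("durations must be positive.")
  }
  out <- tibble::tibble(
    base = as.numeric(base),
    novel = as.numeric(novel),
    ratio_pct = 100 * novel / base
  )
  out$within <- out$ratio_pct >= low & out$ratio_pct <= high
  structure(out, bounds = c(low = low, high = high),
            class = c("sfi_ratio_check", class(out)))
}

#' @exportS3Method generics::glance
glance.sfi_ratio_check <- function(x, ...) {
  bounds <- attr(x, "bounds")
  tibble::tibble(
    n = nrow(x),
    min_ratio_pct = min(x$ratio_pct),
    max_ratio_pct = max(x$ratio_pct),
    low = bounds[["low"]],
    high = bounds[["high"]],
    pass = all(x$within)
  )
}
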