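#' Blockwise means of the start-time estimates
#'
#' Mean of each estimator over the non-missing trials of every block
#' (pairwise deletion); a block whose trials are all missing gets `NA`.
#'
#' @param start_times A start-time table from [estimate_start_times()].
#' @return A tibble with one row per (subject, day, block) and a mean per
#'   estimator.
#' @export
blockwise_means <- function(start_times) {
  if (nrow(start_times) == 0L) stop_invalid("`start_times` is empty.")
  start_times |>
    dplyr::group_by(.data$subject_id, .data$day, .data$block_index,
                    .data$fi_duration) |>
    dplyr::summarise(
      dplyr::across(
        dplyr::any_of(start_metric_names()),
        ~ ifelse(all(is.na(.x)), NA_real_, mean(.x, na.rm = TRUE))
      ),
      .groups = "drop"
    )
}

#' Classify a block transition by direction and magnitude
#'
#' Direction follows the sign of the FI change. Magnitude uses the rank gap
#' g within the session's ordered duration list: adjacent durations
#' (g = 1) are `"small"`; durations separated by at least two intervening
#' list values (g >= 3) are `"large"`; the g = 2 case is labelled
#' `"intermediate"` and excluded from small/large contrasts, since the two
#' standard definitions do not cover it.
#'
#' @param prev_fi,next_fi FI durations (s) before and after the transition;
#'   vectorised, must both be members of `duration_list` and differ.
#' @param duration_list The session's FI duration list.
#' @return A tibble with `direction` (`"increase"`/`"decrease"`) and
#'   `magnitude` (`"small"`/`"intermediate"`/`"large"`).
#' @examples
#' classify_transition(36, 48, c(12, 24, 36, 48, 60)) # increase, small
#' classify_transition(60, 24, c(12, 24, 36, 48, 60)) # decrease, large
#' @export
classify_transition <- function(prev_fi, next_fi, duration_list) {
  ranks <- sort(unique(duration_list))
  r_prev <- match(prev_fi, ranks)
  r_next <- match(next_fi, ranks)
  if (anyNA(r_prev) || anyNA(r_next)) {
    stop_invalid("transition FI durations must belong to `duration_list`.")
  }
  if (any(prev_fi == next_fi)) {
    stop_invalid("`prev_fi` and `next_fi` must differ.")
  }
  gap <- abs(r_next - r_prev)
  tibble::tibble(
    direction = ifelse(next_fi > prev_fi, "increase", "decrease"),
    magnitude = dplyr::case_when(
      gap == 1 ~ "small",
      gap >= 3 ~ "large",
      .default = "intermediate"
    )
  )
}

#' Build per-transition adaptation records for one estimator
#'
#' For every boundary between consecutive analysed blocks of each session,
#' records the previous block's mean value of `metric`, the transition's
#' direction and magnitude class, and the estimator's values on the first
#' `t_post` trials of the new block, normalised as a percentage of the
#' previous-block mean (100% = no change).
#'
#' For the burst, rate-increase and change-point estimators, transitions to
#' or from the session's shortest duration class are dropped (pressing on
#' the shortest trials is too sparse for these estimators); the first-press
#' estimator keeps all transitions. The exclusion keys on the rank of the
#' duration in the session's own list, so it carries over to novel and
#' rescaled duration sets. Records whose previous-block mean is undefined
#' are dropped.
#'
#' @param start_times A start-time table from [estimate_start_times()].
#' @param metric One of `"first_press"`, `"first_burst"`,
#'   `"rate_increase"`, `"change_point"`.
#' @param t_post Post-transition trials retained, default 10.
#' @param exclude_shortest Drop transitions to/from the shortest duration.
#'   Default `NULL` means `TRUE` for all estimators except `first_press`.
#' @return A long tibble of class `sfi_transition_records`: one row per
#'   (transition, post-trial), columns `subject_id`, `day`, `metric`,
#'   `transition_index`, `prev_fi`, `next_fi`, `direction`, `magnitude`,
#'   `prev_block_mean`, `post_trial`, `value`, `normalized_pct`.
#' @export
build_transition_records <- function(start_times, metric = "first_press",
                                     t_post = 10, exclude_shortest = NULL) {
  metric <- match.arg(metric, start_metric_names())
  check_number(t_post, "t_post", min = 1)
  t_post <- as.integer(t_post)
  if (is.null(exclude_shortest)) {
    exclude_shortest <- metric != "first_press"
  }

  per_session <- function(df) {
    durations <- sort(unique(df$fi_duration))
    shortest <- durations[1L]
    blocks <- sort(unique(df$block_index))
    recs <- purrr::map_dfr(blocks[-length(blocks)], function(b) {
      if (!((b + 1L) %in% blocks)) return(NULL)
      prev <- df[df$block_index == b, ]
      nxt <- df[df$block_index == b + 1L, ]
      prev_fi <- prev$fi_duration[1L]
      next_fi <- nxt$fi_duration[1L]
      if (prev_fi == next_fi) return(NULL)
      if (exclude_shortest && (prev_fi == shortest || next_fi == shortest)) {
        return(NULL)
      }
      pb_mean <- mean(prev[[metric]], na.rm = TRUE)
      if (is.nan(pb_mean)) return(NULL)
      cls <- classify_transition(prev_fi, next_fi, durations)
      post <- nxt[[metric]][match(seq_len(t_post), nxt$trial_index_in_block)]
      tibble::tibble(
        transition_index = b,
        prev_fi = prev_fi,
        next_fi = next_fi,
        direction = cls$direction,
        magnitude = cls$magnitude,
        prev_block_mean = pb_mean,
        post_trial = seq_len(t_post),
        value = post,
        normalized_pct = 100 * (post / pb_mean)
      )
    })
    recs
  }

  out <- start_times |>
    dplyr::group_by(.data$subject_id, .data$day) |>
    dplyr::group_modify(~ per_session(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(metric = metric, .after = "day")
  class(out) <- c("sfi_transition_records", class(out))
  out
}

#' Normalised adaptation curves after block transitions
#'
#' Aggregates transition records by direction and post-transition trial:
#' mean, SD, SEM and n of the previous-block-normalised values (pairwise
#' deletion of missing trials). A flat curve at 100% means no adaptation;
#' a one-shot learner jumps to `next_fi / prev_fi` x 100% on the second
#' post-transition trial.
#'
#' @param records Records from [build_transition_records()] (several
#'   estimators may be row-bound).
#' @return A tibble of class `sfi_adaptation_curves` with columns `metric`,
#'   `direction`, `post_trial`, `mean_pct`, `sd_pct`, `sem_pct`, `n`.
#'   Plot with [autoplot()].
#' @export
adaptation_curves <- function(records) {
  if (nrow(records) == 0L) stop_invalid("`records` is empty.")
  out <- records |>
    dplyr::group_by(.data$metric, .data$direction, .data$post_trial) |>
    dplyr::summarise(
      mean_pct = mean(.data$normalized_pct, na.rm = TRUE),
      sd_pct = stats::sd(.data$normalized_pct, na.rm = TRUE),
      n = sum(!is.na(.data$normalized_pct)),
      .groups = "drop"
    ) |>
    dplyr::mutate(sem_pct = .data$sd_pct / sqrt(pmax(.data$n, 1L)))
  class(out) <- c("sfi_adaptation_curves", class(out))
  out
}

#' Adaptation latency: first post-transition trial differing from baseline
#'
#' For each estimator and direction, tests every post-transition trial's
#' record-level normalised values against 100% (two-sided one-sample
#' t-test) with Holm correction across the `t_post` trials, and reports the
#' smallest trial index with adjusted p < `alpha`. Trial 1 is the first
#' trial experienced under the new FI; an agent that has not yet been
#' rewarded under the new interval cannot deviate on trial 1, so a latency
#' of 2 is the fastest adaptation observable by construction.
#'
#' @param records Records from [build_transition_records()].
#' @param alpha Significance level, default 0.05.
#' @return An object of class `sfi_latency`. `tidy()` gives the per-trial
#'   test table (`metric`, `direction`, `post_trial`, `n`, `mean_pct`,
#'   `statistic`, `p_value`, `p_adjusted`); `glance()` gives one row per
#'   (metric, direction) with the `latency` (`NA` when no trial differs).
#' @export
adaptation_latency <- function(records, alpha = 0.05) {
  if (nrow(records) == 0L) stop_invalid("`records` is empty.")
  check_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  tests <- records |>
    dplyr::group_by(.data$metric, .data$direction, .data$post_trial) |>
    dplyr::summarise(
      n = sum(!is.na(.data$normalized_pct)),
      mean_pct = mean(.data$normalized_pct, na.rm = TRUE),
      statistic = one_sample_t(.data$normalized_pct, 100)["statistic"],
      p_value = one_sample_t(.data$normalized_pct, 100)["p"],
      .groups = "drop_last"
    ) |>
    dplyr::mutate(p_adjusted = p.adjust(.data$p_value, method = "holm")) |>
    dplyr::ungroup()
  latency <- tests |>
    dplyr::group_by(.data$metric, .data$direction) |>
    dplyr::summarise(
      latency = first_or_na(.data$post_trial[!is.na(.data$p_adjusted) &
                                               .data$p_adjusted < alpha]),
      .groups = "drop"
    )
  structure(list(tests = tests, latency = latency, alpha = alpha),
            class = "sfi_latency")
}

one_sample_t <- function(x, mu) {
  x <- x[!is.na(x)]
  if (length(x) < 3L || stats::sd(x) == 0) {
    return(c(statistic = NA_real_, p = NA_real_))
  }
  tt <- t.test(x, mu = mu)
  c(statistic = unname(tt$statistic), p = tt$p.value)
}

first_or_na <- function(x) if (length(x)) x[1L] else NA_integer_

#' @export
print.sfi_latency <- function(x, ...) {
  cat("<sfi_latency> first post-transition trial deviating from 100%",
      sprintf("(Holm-adjusted p < %g)\n", x$alpha))
  print(x$latency)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sfi_latency <- function(x, ...) x$tests

#' @exportS3Method generics::glance
glance.sfi_latency <- function(x, ...) x$latency

#' Correlation of start time with FI duration at fixed post-transition trials
#'
#' Pools (FI duration, estimate) pairs at a given trial-within-block index
#' across blocks 2--5 and subjects (the first block has no preceding
#' transition and is excluded) and computes the Pearson correlation with a
#' two-sided t-based p-value. On the first post-transition trial the animal
#' has no information about the new FI, so r is expected near 0; the speed
#' with which r (and R^2) rises over trials 2--4 measures adaptation.
#'
#' @param start_times A start-time table from [estimate_start_times()].
#' @param trial_indices Trial-within-block indices to assess, default 1:4.
#' @param metrics Estimators to assess, default all four.
#' @param blocks Block indices pooled, default 2:5.
#' @param min_pairs Minimum complete pairs, default 3; below it (or with a
#'   degenerate FI spread) the row is `NA`.
#' @return A tibble of class `sfi_correlations`: `metric`, `post_trial`,
#'   `n`, `r`, `r_squared`, `p_value`. Plot with [autoplot()].
#' @export
post_transition_correlations <- function(start_times, trial_indices = 1:4,
                                         metrics = start_metric_names(),
                                         blocks = 2:5, min_pairs = 3) {
  metrics <- match.arg(metrics, start_metric_names(), several.ok = TRUE)
  grid <- tidyr::expand_grid(metric = metrics, post_trial = trial_indices)
  out <- purrr::pmap_dfr(grid, function(metric, post_trial) {
    df <- start_times[start_times$block_index %in% blocks &
                        start_times$trial_index_in_block == post_trial, ]
    x <- df$fi_duration
    y <- df[[metric]]
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]
    y <- y[keep]
    if (length(x) < min_pairs || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble::tibble(metric = metric, post_trial = post_trial,
                            n = length(x), r = NA_real_,
                            r_squared = NA_real_, p_value = NA_real_))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble::tibble(
      metric = metric, post_trial = post_trial, n = length(x),
      r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
      p_value = ct$p.value
    )
  })
  class(out) <- c("sfi_correlations", class(out))
  out
}

#' Blockwise scaling of start times with FI duration
#'
#' Regresses the blockwise mean of each estimator on FI duration across all
#' blocks and sessions (ordinary least squares). Start times on this task
#' scale linearly with the interval with a slope of about 0.5 — the
#' signature of a response threshold at roughly half the timed interval.
#'
#' @param start_times A start-time table from [estimate_start_times()].
#' @param metrics Estimators to fit, default all four.
#' @return An object of class `sfi_scaling` holding one `lm` fit per
#'   estimator. `tidy()` returns per-term coefficients; `glance()` returns
#'   one row per estimator with `slope`, `intercept`, `r_squared`, `n`.
#' @export
blockwise_scaling <- function(start_times, metrics = start_metric_names()) {
  metrics <- match.arg(metrics, start_metric_names(), several.ok = TRUE)
  bw <- blockwise_means(start_times)
  fits <- purrr::map(rlang::set_names(metrics), function(m) {
    df <- bw[!is.na(bw[[m]]), c("fi_duration", m)]
    names(df) <- c("fi_duration", "value")
    if (nrow(df) < 3L) return(NULL)
    lm(value ~ fi_duration, data = df)
  })
  structure(list(fits = fits, blockwise = bw), class = "sfi_scaling")
}

#' @export
print.sfi_scaling <- function(x, ...) {
  cat("<sfi_scaling> blockwise mean start time ~ FI duration\n")
  print(glance(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sfi_scaling <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(fit, m) {
    if (is.null(fit)) return(NULL)
    s <- summary(fit)$coefficients
    tibble::tibble(
      metric = m,
      term = rownames(s),
      estimate = s[, "Estimate"],
      std_error = s[, "Std. Error"],
      statistic = s[, "t value"],
      p_value = s[, "Pr(>|t|)"]
    )
  })
}

#' @exportS3Method generics::glance
glance.sfi_scaling <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(fit, m) {
    if (is.null(fit)) {
      return(tibble::tibble(metric = m, slope = NA_real_,
                            intercept = NA_real_, r_squared = NA_real_,
                            n = 0L))
    }
    tibble::tibble(
      metric = m,
      slope = unname(coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]),
      r_squared = summary(fit)$r.squared,
      n = length(fit$residuals)
    )
  })
}
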