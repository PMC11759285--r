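#' Write a session or cohort of trials to an event-log CSV
#'
#' Serialises trials as a long event log: one `press` row per press and one
#' `reward` row per trial (the rewarded press appears as both). Columns are
#' `subject_id`, `day`, `block_index`, `trial_index_in_block`,
#' `fi_duration`, `event_type`, `event_time`; times are trial-relative
#' seconds at 1 ms resolution, indices 1-based.
#'
#' @param trials A trials tibble (see [simulate_session()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_event_log()]
#' @export
write_event_log <- function(trials, path) {
  check_trials(trials)
  log <- trials |>
    dplyr::mutate(.trial = dplyr::row_number()) |>
    tidyr::unnest_longer("press_times", values_to = "event_time") |>
    dplyr::mutate(event_type = "press")
  rewards <- trials |>
    dplyr::mutate(.trial = dplyr::row_number(),
                  event_type = "reward",
                  event_time = .data$reward_time)
  out <- dplyr::bind_rows(log, rewards) |>
    dplyr::arrange(.data$.trial, .data$event_time,
                   .data$event_type) |> # "press" < "reward": reward row last
    dplyr::mutate(
      fi_duration = round(.data$fi_duration, 3),
      event_time = round(.data$event_time, 3)
    ) |>
    dplyr::select(
      "subject_id", "day", "block_index", "trial_index_in_block",
      "fi_duration", "event_type", "event_time"
    )
  readr::write_csv(out, path)
  invisible(path)
}

abort_parse <- function(msg, row) {
  abort(sprintf("event log invalid at data row %d: %s", row, msg),
        class = "sfiadapt_parse_error")
}

#' Read an event-log CSV back into a trials tibble
#'
#' Inverse of [write_event_log()]. Every trial's invariants are validated —
#' event times sorted and strictly increasing across presses, exactly one
#' reward per trial, reward at or after the FI deadline and coincident with
#' the final press — and the first violation is reported with its data row
#' number.
#'
#' @param path Event-log CSV path.
#' @return A trials tibble; zero rows for a header-only file.
#' @export
read_event_log <- function(path) {
  log <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      day = readr::col_integer(),
      block_index = readr::col_integer(),
      trial_index_in_block = readr::col_integer(),
      fi_duration = readr::col_double(),
      event_type = readr::col_character(),
      event_time = readr::col_double()
    )
  )
  required <- c("subject_id", "day", "block_index", "trial_index_in_block",
                "fi_duration", "event_type", "event_time")
  if (!all(required %in% names(log))) {
    abort("event log must have the EventLogRow header.",
          class = "sfiadapt_parse_error")
  }
  if (nrow(log) == 0L) {
    return(tibble::tibble(
      subject_id = character(0), day = integer(0), block_index = integer(0),
      trial_index_in_block = integer(0), fi_duration = numeric(0),
      press_times = list(), reward_time = numeric(0)
    ))
  }
  if (any(log$event_time < 0)) {
    abort_parse("negative event time", which(log$event_time < 0)[1L])
  }
  if (!all(log$event_type %in% c("press", "reward"))) {
    abort_parse("unknown event_type",
                which(!log$event_type %in% c("press", "reward"))[1L])
  }
  log$.row <- seq_len(nrow(log))
  tol <- 5e-4 # half the 1 ms serialisation grain

  log |>
    dplyr::group_by(.data$subject_id, .data$day, .data$block_index,
                    .data$trial_index_in_block, .data$fi_duration) |>
    dplyr::group_modify(function(df, key) {
      if (is.unsorted(df$event_time)) {
        bad <- which(diff(df$event_time) < 0)[1L] + 1L
        abort_parse("event times out of order", df$.row[bad])
      }
      presses <- df$event_time[df$event_type == "press"]
      reward_rows <- which(df$event_type == "reward")
      if (length(reward_rows) != 1L) {
        abort_parse(
          sprintf("expected exactly one reward row, found %d",
                  length(reward_rows)),
          df$.row[1L]
        )
      }
      reward <- df$event_time[reward_rows]
      if (length(presses) && any(diff(presses) <= 0)) {
        bad <- which(diff(presses) <= 0)[1L] + 1L
        abort_parse("press times not strictly increasing",
                    df$.row[df$event_type == "press"][bad])
      }
      if (reward < key$fi_duration - tol) {
        abort_parse("reward before the FI deadline", df$.row[reward_rows])
      }
      if (!length(presses) || abs(presses[length(presses)] - reward) > tol) {
        abort_parse("reward does not coincide with the final press",
                    df$.row[reward_rows])
      }
      tibble::tibble(press_times = list(presses), reward_time = reward)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$subject_id, .data$day, .data$block_index,
                   .data$trial_index_in_block) |>
    dplyr::select(
      "subject_id", "day", "block_index", "trial_index_in_block",
      "fi_duration", "press_times", "reward_time"
    )
}

#' Assemble a run configuration
#'
#' A run configuration binds everything one reproducible pipeline run
#' needs: protocol, agent, estimator and change-point settings, transition
#' settings, cohort size and the master seed. It round-trips losslessly
#' through YAML ([write_run_config()] / [read_run_config()]).
#'
#' @param protocol An [sfi_protocol()].
#' @param agent An [agent_params()].
#' @param metric A [metric_config()].
#' @param cprl A [cprl_config()].
#' @param n_subjects,n_days Cohort size, defaults 20 subjects x 1 day.
#' @param t_post Post-transition trials analysed, default 10.
#' @param seed Master seed, default 1.
#' @return An object of class `sfi_run_config`.
#' @export
run_config <- function(protocol = sfi_protocol(),
                       agent = agent_params(),
                       metric = metric_config(),
                       cprl = cprl_config(),
                       n_subjects = 20, n_days = 1, t_post = 10, seed = 1) {
  stopifnot(inherits(protocol, "sfi_protocol"), inherits(agent, "sfi_agent"),
            inherits(metric, "sfi_metric_config"),
            inherits(cprl, "sfi_cprl_config"))
  check_number(n_subjects, "n_subjects", min = 1)
  check_number(n_days, "n_days", min = 1)
  check_number(t_post, "t_post", min = 1)
  check_number(seed, "seed")
  structure(
    list(protocol = protocol, agent = agent, metric = metric, cprl = cprl,
         n_subjects = as.integer(n_subjects), n_days = as.integer(n_days),
         t_post = as.integer(t_post), seed = as.integer(seed)),
    class = "sfi_run_config"
  )
}

#' @rdname run_config
#' @param config An `sfi_run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "sfi_run_config"))
  plain <- lapply(config, function(x) {
    if (is.list(x)) unclass(x) else x
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  protocol <- do.call(sfi_protocol, raw$protocol)
  agent <- do.call(agent_params, raw$agent)
  metric <- do.call(metric_config, raw$metric)
  cprl_args <- raw$cprl
  cprl_args$prior_rate <- cprl_args$prior_rate %||% NULL
  cprl <- do.call(cprl_config, cprl_args)
  run_config(
    protocol = protocol, agent = agent, metric = metric, cprl = cprl,
    n_subjects = raw$n_subjects, n_days = raw$n_days,
    t_post = raw$t_post, seed = raw$seed
  )
}
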