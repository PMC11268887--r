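# Within-session reward-history stratification of responding.

backward_run_length <- function(rewarded) {
  n <- length(rewarded)
  out <- rep(NA_integer_, n)
  if (n >= 2) {
    out[2] <- 1L
    for (i in seq_len(n)[-(1:2)]) {
      out[i] <- if (rewarded[i - 1] == rewarded[i - 2]) out[i - 1] + 1L
        else 1L
    }
  }
  out
}

#' Label trials by within-session reward history
#'
#' For every non-first trial of each session, records whether the
#' immediately preceding trial (same session, regardless of context phase)
#' was actually rewarded (`prior_outcome` `"R"`/`"NR"`, based on delivered
#' rewards, not the contingency) and the length of the run of identical
#' prior outcomes immediately preceding the trial. The first trial of each
#' session carries `NA` labels and is excluded from history analyses, so a
#' block of 10 sessions of 80 trials yields 790 labeled trials.
#'
#' @param trials Trial table (e.g. [trial_metrics()] output, possibly for
#'   many sessions/subjects) with columns `trial`, `rewarded` and, when
#'   present, grouping columns `subject_id` and `session_index`.
#' @return The input with `prior_outcome` and `run_length` columns added.
#' @export
label_history <- function(trials) {
  stopifnot(all(c("trial", "rewarded") %in% names(trials)))
  keys <- intersect(c("subject_id", "session_index"), names(trials))
  trials |>
    group_by(across(all_of(keys))) |>
    arrange(.data$trial, .by_group = TRUE) |>
    mutate(
      prior_outcome = ifelse(dplyr::lag(.data$rewarded), "R", "NR"),
      run_length = backward_run_length(.data$rewarded)) |>
    ungroup()
}

#' Reward-history effects on responding
#'
#' Stratifies time in port and response probability on current rewarded and
#' non-rewarded trials by the prior trial's outcome (and by the run length
#' of consecutive identical prior outcomes), and computes per-subject
#' difference scores `(after prior R) - (after prior NR)`. Group-level
#' hypothesis tests are delegated to [prior_reward_anova()].
#'
#' @param labeled [label_history()] output that also carries
#'   `time_in_port_pct` and `responded`, plus `subject_id` and the `by`
#'   column.
#' @param by Grouping column for the summaries, default `"sex"`.
#' @return List of tibbles: `strata` (per subject x current type x prior
#'   outcome means), `diff_scores` (per subject x current type x measure),
#'   `run_length` (per group x current type x prior outcome x run length,
#'   with n), `group` (per group x current type x prior outcome means).
#' @export
history_effects <- function(labeled, by = "sex") {
  needed <- c("subject_id", by, "rewarded", "prior_outcome",
              "time_in_port_pct", "responded")
  stopifnot(all(needed %in% names(labeled)))
  lab <- labeled |>
    filter(!is.na(.data$prior_outcome)) |>
    mutate(current_type = ifelse(.data$rewarded, "rewarded",
                                 "non-rewarded"))

  strata <- lab |>
    group_by(.data$subject_id, .data[[by]], .data$current_type,
             .data$prior_outcome) |>
    summarize(time_in_port_pct = mean(.data$time_in_port_pct),
              p_response = mean(.data$responded),
              n_trials = dplyr::n(), .groups = "drop")

  diff_scores <- strata |>
    tidyr::pivot_wider(
      id_cols = all_of(c("subject_id", by, "current_type")),
      names_from = "prior_outcome",
      values_from = c("time_in_port_pct", "p_response")) |>
    mutate(
      diff_time_in_port = .data$time_in_port_pct_R -
        .data$time_in_port_pct_NR,
      diff_p_response = .data$p_response_R - .data$p_response_NR) |>
    select(all_of(c("subject_id", by, "current_type")),
           "diff_time_in_port", "diff_p_response")

  run_length <- lab |>
    group_by(.data[[by]], .data$current_type, .data$prior_outcome,
             .data$run_length) |>
    summarize(time_in_port_pct = mean(.data$time_in_port_pct),
              p_response = mean(.data$responded),
              n_trials = dplyr::n(), .groups = "drop")

  group <- strata |>
    group_by(.data[[by]], .data$current_type, .data$prior_outcome) |>
    summarize(
      time_in_port_pct = mean(.data$time_in_port_pct),
      p_response = mean(.data$p_response),
      n_subjects = dplyr::n(), .groups = "drop")

  list(strata = strata, diff_scores = diff_scores,
       run_length = run_length, group = group)
}
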