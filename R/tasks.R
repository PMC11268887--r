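# Task contingencies for the four discrimination conditions.

TASK_NAMES <- c("ctx_dep_o1", "simple", "no_discr", "ctx_dep_o1o2")
CONTEXTS <- c("LIGHT", "DARK")
CUES <- c("X", "Y")

#' Define a discrimination task
#'
#' Builds the reward-contingency table for one of the four training
#' conditions. Contexts are the 2-min visual background states (`LIGHT` =
#' flashing houselight, `DARK` = houselight off); cues are the two 10-s
#' auditory stimuli `X` and `Y`.
#'
#' * `ctx_dep_o1` -- bidirectional occasion setting with a single outcome:
#'   X is rewarded only in LIGHT, Y only in DARK, all rewards are `O1`.
#' * `simple` -- simple discrimination: X always rewarded, Y never.
#' * `no_discr` -- both cues probabilistically rewarded in both contexts
#'   (p = 0.5 under the standard schedule, p = 0.25 under the equalized
#'   `reduced` schedule).
#' * `ctx_dep_o1o2` -- same reward cells as `ctx_dep_o1` but with
#'   differential outcomes: LIGHT:X pays `O1`, DARK:Y pays `O2`.
#'
#' The `schedule_phase` also fixes the per-session trial-type counts used by
#' [generate_schedule()]: 20 per (context, cue) combination under
#' `"standard"`; under `"reduced"` the rewarded trial types drop to 10 and
#' the non-rewarded rise to 30 (context tasks), or the rewarded cue X drops
#' to 10 per context (simple), so that rewarded trials are 1/4 of all trials.
#'
#' @param task_name One of `"ctx_dep_o1"`, `"simple"`, `"no_discr"`,
#'   `"ctx_dep_o1o2"`.
#' @param schedule_phase `"standard"` (equal trial-type proportions) or
#'   `"reduced"` (rewarded trials are 1/4 of all trials).
#' @return A `task_spec` object: list with `task_name`, `schedule_phase`, a
#'   `contingency` tibble (`context`, `cue`, `reward_probability`,
#'   `outcome_id`) and a `trial_counts` tibble (`context`, `cue`, `n`,
#'   summing to 80).
#' @examples
#' make_task("ctx_dep_o1")
#' make_task("simple", "reduced")$trial_counts
#' @export
make_task <- function(task_name, schedule_phase = c("standard", "reduced")) {
  if (length(task_name) != 1 || !task_name %in% TASK_NAMES) {
    stop("unknown task_name: ", paste(task_name, collapse = ", "),
         "; must be one of ", paste(TASK_NAMES, collapse = ", "))
  }
  schedule_phase <- match.arg(schedule_phase)

  cells <- tidyr::expand_grid(context = CONTEXTS, cue = CUES)
  cont <- switch(task_name,
    ctx_dep_o1 = cells |>
      mutate(
        reward_probability = as.numeric(
          (.data$context == "LIGHT" & .data$cue == "X") |
            (.data$context == "DARK" & .data$cue == "Y")),
        outcome_id = ifelse(.data$reward_probability > 0, "O1", "none")),
    ctx_dep_o1o2 = cells |>
      mutate(
        reward_probability = as.numeric(
          (.data$context == "LIGHT" & .data$cue == "X") |
            (.data$context == "DARK" & .data$cue == "Y")),
        outcome_id = dplyr::case_when(
          .data$context == "LIGHT" & .data$cue == "X" ~ "O1",
          .data$context == "DARK" & .data$cue == "Y" ~ "O2",
          TRUE ~ "none")),
    simple = cells |>
      mutate(
        reward_probability = as.numeric(.data$cue == "X"),
        outcome_id = ifelse(.data$cue == "X", "O1", "none")),
    no_discr = cells |>
      mutate(
        reward_probability = if (schedule_phase == "reduced") 0.25 else 0.5,
        outcome_id = "O1")
  )

  counts <- cells
  counts$n <- if (schedule_phase == "standard") {
    rep(20L, 4)
  } else {
    switch(task_name,
      # rewarded trial types at 10, non-rewarded at 30
      ctx_dep_o1 = ,
      ctx_dep_o1o2 = ifelse(cont$reward_probability > 0, 10L, 30L),
      simple = ifelse(cells$cue == "X", 10L, 30L),
      no_discr = rep(20L, 4))
  }

  structure(
    list(task_name = task_name, schedule_phase = schedule_phase,
         contingency = cont, trial_counts = counts),
    class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat("<task_spec> ", x$task_name, " [", x$schedule_phase, " schedule]\n",
      sep = "")
  print(dplyr::left_join(x$contingency, x$trial_counts,
                         by = c("context", "cue")))
  invisible(x)
}
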