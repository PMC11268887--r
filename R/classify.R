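# Discriminator criterion, sessions to criterion, group proportions.

# earliest index s (>= window) with >= needed passes in sessions
# (s-window+1)..s; NA sessions count as failures.
rolling_criterion <- function(pass, window = 5L, needed = 4L) {
  pass[is.na(pass)] <- FALSE
  n <- length(pass)
  if (n < window) return(NA_integer_)
  cs <- cumsum(pass)
  hits <- cs[window:n] - c(0, cs)[1:(n - window + 1)]
  idx <- which(hits >= needed)
  if (!length(idx)) NA_integer_ else as.integer(idx[1] + window - 1L)
}

# per-cue pass rule: rewarded-cell mean >= threshold * non-rewarded-cell
# mean, with some responding required (0 vs 0 does not pass).
cue_pass <- function(t_rew, t_nonrew, threshold) {
  ok <- !is.na(t_rew) & !is.na(t_nonrew) & (t_rew + t_nonrew) > 0
  ok & (t_rew >= threshold * t_nonrew)
}

#' Classify one subject as discriminator or non-discriminator
#'
#' A session "passes" when time in port on rewarded trials is at least
#' `threshold` (1.5) times the time on non-rewarded trials -- equivalent to
#' a discrimination ratio >= 0.6 whenever there is any responding. For the
#' context-dependent tasks the rule is evaluated per cue
#' (`tip_light_x >= 1.5 * tip_dark_x` and `tip_dark_y >= 1.5 *
#' tip_light_y`) and both cues must pass; for `simple` the single
#' rewarded-vs-non-rewarded contrast (`t_rew` vs `t_nonrew`) is used. The
#' criterion is met when at least `needed` of any `window` consecutive
#' sessions pass; `criterion_session` is the last session of the earliest
#' qualifying window.
#'
#' @param timeline Tibble of session summaries for one subject (columns as
#'   produced by [session_summary()]), ordered by `session_index` with at
#'   least `window` sessions.
#' @param task Task name; `"no_discr"` is rejected (discrimination between
#'   rewarded and non-rewarded trials is impossible by design).
#' @param threshold Pass multiplier, default 1.5.
#' @param window,needed The `needed`-of-`window` consecutive-session rule
#'   (default 4 of 5).
#' @param joint_windows If `TRUE` (default), both cues must pass within the
#'   same session windows (the stricter reading); if `FALSE`, each cue
#'   meets the rule in its own window and `criterion_session` is the later
#'   of the two.
#' @return One-row tibble: `is_discriminator`, `criterion_session` (`NA`
#'   for non-discriminators).
#' @examples
#' tl <- tibble::tibble(
#'   session_index = 1:6,
#'   tip_light_x = c(30, 30, 10, 30, 30, 30), tip_dark_x = 10,
#'   tip_dark_y = c(30, 30, 10, 30, 30, 30), tip_light_y = 10)
#' classify_subject(tl, "ctx_dep_o1")  # criterion at session 5
#' @export
classify_subject <- function(timeline, task, threshold = 1.5, window = 5L,
                             needed = 4L, joint_windows = TRUE) {
  if (task == "no_discr") {
    stop("classification is not applicable to the no_discr task")
  }
  stopifnot(task %in% TASK_NAMES, nrow(timeline) >= window)
  timeline <- arrange(timeline, .data$session_index)
  if (task %in% c("ctx_dep_o1", "ctx_dep_o1o2")) {
    pass_x <- cue_pass(timeline$tip_light_x, timeline$tip_dark_x, threshold)
    pass_y <- cue_pass(timeline$tip_dark_y, timeline$tip_light_y, threshold)
    if (joint_windows) {
      crit <- rolling_criterion(pass_x & pass_y, window, needed)
    } else {
      cx <- rolling_criterion(pass_x, window, needed)
      cy <- rolling_criterion(pass_y, window, needed)
      crit <- if (is.na(cx) || is.na(cy)) NA_integer_ else max(cx, cy)
    }
  } else {
    crit <- rolling_criterion(
      cue_pass(timeline$t_rew, timeline$t_nonrew, threshold),
      window, needed)
  }
  if (!is.na(crit)) crit <- timeline$session_index[crit]
  tibble(is_discriminator = !is.na(crit),
         criterion_session = as.integer(crit))
}

#' Classify every subject of a cohort
#'
#' @param summaries Session summaries for several subjects: columns
#'   `subject_id`, `sex`, `task` plus those of [session_summary()].
#' @param ... Passed to [classify_subject()].
#' @return Tibble with one row per subject: `subject_id`, `sex`, `task`,
#'   `is_discriminator`, `criterion_session`.
#' @export
classify_cohort <- function(summaries, ...) {
  dots <- list(...)
  summaries |>
    group_by(.data$subject_id, .data$sex, .data$task) |>
    group_modify(function(d, key) {
      do.call(classify_subject, c(list(d, task = key$task), dots))
    }) |>
    ungroup()
}

#' Sessions to criterion, by group
#'
#' Excludes non-discriminators, reports per-group medians and a rank-based
#' omnibus comparison (Kruskal-Wallis) with Bonferroni-corrected pairwise
#' rank follow-ups.
#'
#' @param results Classification results (rows per subject) with columns
#'   `is_discriminator`, `criterion_session` and the grouping column.
#' @param group Name of the grouping column, e.g. `"task"` or `"sex"`.
#' @return List: `summary` (per-group n, median, mean, sem; groups empty
#'   after exclusion are flagged), `omnibus` (`htest` or `NULL` when fewer
#'   than two non-empty groups), `pairwise` (`pairwise.htest` or `NULL`).
#' @export
sessions_to_criterion <- function(results, group = "task") {
  stopifnot(group %in% names(results))
  disc <- filter(results, .data$is_discriminator)
  summary <- results |>
    group_by(group = .data[[group]]) |>
    summarize(
      n_discriminators = sum(.data$is_discriminator),
      n_excluded = sum(!.data$is_discriminator),
      median_sessions = median(.data$criterion_session[.data$is_discriminator]),
      mean_sessions = mean(.data$criterion_session[.data$is_discriminator]),
      sem_sessions = sd(.data$criterion_session[.data$is_discriminator]) /
        sqrt(pmax(1, sum(.data$is_discriminator))),
      empty = sum(.data$is_discriminator) == 0,
      .groups = "drop")
  groups <- factor(disc[[group]])
  omnibus <- pairwise <- NULL
  if (nlevels(droplevels(groups)) >= 2) {
    omnibus <- kruskal.test(disc$criterion_session, droplevels(groups))
    pairwise <- suppressWarnings(pairwise.wilcox.test(
      disc$criterion_session, droplevels(groups),
      p.adjust.method = "bonferroni"))
  }
  list(summary = summary, omnibus = omnibus, pairwise = pairwise)
}

#' Discriminator proportions by sex
#'
#' Builds the sex-by-outcome 2x2 contingency table and a Pearson
#' chi-square test (without Yates continuity correction by default, toggle
#' with `correct`).
#'
#' @param results Classification results with columns `sex`,
#'   `is_discriminator`.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return List: `table` (2x2 counts), `test` (`htest`), `proportions`
#'   (per-sex discriminator proportion).
#' @export
discriminator_proportions <- function(results, correct = FALSE) {
  stopifnot(all(c("sex", "is_discriminator") %in% names(results)))
  if (nrow(results) == 0) stop("empty results table")
  tab <- table(
    sex = factor(results$sex, levels = c("M", "F")),
    discriminator = factor(results$is_discriminator,
                           levels = c(TRUE, FALSE)))
  if (sum(tab) == 0) stop("zero-total contingency table")
  test <- suppressWarnings(chisq.test(tab, correct = correct))
  if (is.nan(test$statistic)) {
    # degenerate margin (e.g. everyone a discriminator): no association
    test$statistic[] <- 0
    test$p.value <- 1
  }
  props <- prop.table(tab, margin = 1)[, "TRUE"]
  list(table = tab, test = test, proportions = props)
}
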