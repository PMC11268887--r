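# Per-trial and per-session behavioral measures.

# cumulative occupancy time in [0, t) for sorted non-overlapping intervals
occupied_before <- function(intervals, t) {
  if (nrow(intervals) == 0) return(numeric(length(t)))
  ent <- intervals$entry_s
  dur <- intervals$exit_s - ent
  cs <- c(0, cumsum(dur))
  i <- findInterval(t, ent)
  ifelse(i == 0, 0,
         cs[pmax(i, 1)] + pmin(pmax(t - ent[pmax(i, 1)], 0),
                               dur[pmax(i, 1)]))
}

# Total overlap of sorted non-overlapping intervals with [start, end),
# vectorized over windows; returns a fraction of window length.
overlap_fraction <- function(intervals, start, end) {
  stopifnot(length(start) == length(end))
  if (any(end <= start)) stop("window length must be > 0")
  (occupied_before(intervals, end) - occupied_before(intervals, start)) /
    (end - start)
}

#' Fraction of a time window spent in the reward port
#'
#' Reconstructs occupancy from alternating port entry/exit events (an open
#' interval at session end is closed at the final timestamp) and returns
#' the total overlap with the window divided by the window length.
#'
#' @param log An `event_log`.
#' @param window Numeric length-2 vector `c(start_s, end_s)`, end > start.
#' @return A fraction in \[0, 1\].
#' @examples
#' sch <- generate_schedule(make_task("simple"), seed = 1)
#' log <- render_events(sch, tibble::tibble(entry_s = 106, exit_s = 108.5))
#' time_in_port(log, c(105, 110))  # 0.5
#' @export
time_in_port <- function(log, window) {
  stopifnot(length(window) == 2)
  if (diff(window) <= 0) stop("window length must be > 0")
  occ <- occupancy_from_events(log)
  overlap_fraction(occ, window[1], window[2])
}

#' Did the subject respond on a trial?
#'
#' A response is a port entry during the 10-s cue window
#' `[onset, onset + 10)`, or (by default) already being in the port at cue
#' onset, which captures sustained anticipatory occupancy.
#'
#' @param log An `event_log`.
#' @param onset_s Cue onset time(s); vectorized.
#' @param include_onset_occupancy If `TRUE` (default), being in port at
#'   onset counts as a response; set `FALSE` for entry-events-only scoring.
#' @return Logical vector.
#' @export
response_probability <- function(log, onset_s,
                                 include_onset_occupancy = TRUE) {
  occ <- occupancy_from_events(log)
  if (nrow(occ) == 0) return(rep(FALSE, length(onset_s)))
  eps <- 1e-9
  entered <- findInterval(onset_s + CUE_S - eps, occ$entry_s) >
    findInterval(onset_s - eps, occ$entry_s)
  if (include_onset_occupancy) {
    i <- findInterval(onset_s, occ$entry_s)
    covered <- i > 0 & occ$exit_s[pmax(i, 1)] > onset_s
    entered | covered
  } else {
    entered
  }
}

#' Discrimination ratio
#'
#' `t_rew / (t_rew + t_nonrew)`: 0.5 means equal responding on rewarded and
#' non-rewarded trials (no discrimination), 1 means responding exclusively
#' on rewarded trials. Undefined (`NA`) when both inputs are zero; such
#' sessions propagate as missing, not as 0.5.
#'
#' @param t_rew,t_nonrew Non-negative mean time in port on rewarded /
#'   non-rewarded trials (any common scale); vectorized.
#' @return Numeric vector of ratios in \[0, 1\], `NA` where undefined.
#' @examples
#' discrimination_ratio(1.5, 1.0)  # 0.6, the criterion boundary
#' discrimination_ratio(2, 2)      # 0.5
#' @export
discrimination_ratio <- function(t_rew, t_nonrew) {
  if (any(t_rew < 0, na.rm = TRUE) || any(t_nonrew < 0, na.rm = TRUE)) {
    stop("time in port must be non-negative")
  }
  total <- t_rew + t_nonrew
  ifelse(total > 0, t_rew / total, NA_real_)
}

#' Per-trial behavioral metrics
#'
#' For every trial of a log: percentage of the last `last_s` seconds of the
#' cue spent in the port (the primary measure), percentage of the `pre_s`
#' seconds before onset (shown but not analyzed), and the response flag
#' from [response_probability()].
#'
#' @param log An `event_log`.
#' @param trials Optional trial table; reconstructed from the events via
#'   [trials_from_events()] when `NULL`.
#' @param last_s Scoring window at the end of the cue, default 5 s.
#' @param pre_s Pre-cue window, default 5 s.
#' @param include_onset_occupancy Passed to [response_probability()].
#' @return The trial table plus `time_in_port_pct`, `pre_cue_pct`,
#'   `responded`.
#' @export
trial_metrics <- function(log, trials = NULL, last_s = 5, pre_s = 5,
                          include_onset_occupancy = TRUE) {
  stopifnot(inherits(log, "event_log"))
  if (is.null(trials)) trials <- trials_from_events(log)
  occ <- occupancy_from_events(log)
  offset <- trials$onset_s + trials$duration_s
  trials$time_in_port_pct <-
    100 * overlap_fraction(occ, offset - last_s, offset)
  trials$pre_cue_pct <-
    100 * overlap_fraction(occ, trials$onset_s - pre_s, trials$onset_s)
  trials$responded <- response_probability(
    log, trials$onset_s, include_onset_occupancy = include_onset_occupancy)
  trials
}

#' Summarize one session
#'
#' Aggregates [trial_metrics()] output: mean time in port per
#' (context, cue) trial type, mean over rewarded (`t_rew`) and non-rewarded
#' (`t_nonrew`) trials -- rewarded by actual reward delivery, which
#' coincides with the trial type for deterministic tasks -- the
#' discrimination ratio, and response probabilities.
#'
#' @param tm Output of [trial_metrics()].
#' @param session_index Session number attached to the row.
#' @return One-row tibble: `session_index`, `tip_light_x`, `tip_dark_x`,
#'   `tip_light_y`, `tip_dark_y`, `t_rew`, `t_nonrew`,
#'   `discrimination_ratio`, `p_resp_rew`, `p_resp_nonrew`, `n_trials`.
#' @export
session_summary <- function(tm, session_index = 1L) {
  cell_name <- paste0("tip_", tolower(tm$context), "_", tolower(tm$cue))
  cells <- as_tibble(as.list(tapply(tm$time_in_port_pct, cell_name, mean)))
  t_rew <- if (any(tm$rewarded)) {
    mean(tm$time_in_port_pct[tm$rewarded])
  } else NA_real_
  t_nonrew <- if (any(!tm$rewarded)) {
    mean(tm$time_in_port_pct[!tm$rewarded])
  } else NA_real_
  ratio <- if (is.na(t_rew) || is.na(t_nonrew)) {
    NA_real_
  } else {
    discrimination_ratio(t_rew, t_nonrew)
  }
  bind_cols(
    tibble(session_index = as.integer(session_index)),
    cells,
    tibble(
      t_rew = t_rew, t_nonrew = t_nonrew, discrimination_ratio = ratio,
      p_resp_rew = if (any(tm$rewarded)) mean(tm$responded[tm$rewarded])
        else NA_real_,
      p_resp_nonrew = if (any(!tm$rewarded)) mean(tm$responded[!tm$rewarded])
        else NA_real_,
      n_trials = nrow(tm)))
}

#' Aggregate a session timeline into consecutive bins
#'
#' Non-overlapping bins of `bin_size` consecutive sessions (default 4, the
#' convention for acquisition curves); numeric measures are averaged within
#' bins, a trailing partial bin is averaged and flagged. If grouping
#' columns (`subject_id`, `sex`, `task`) are present, binning is done
#' within groups.
#'
#' @param timeline Tibble of session summaries ordered by `session_index`.
#' @param bin_size Sessions per bin, >= 1.
#' @return Tibble with `bin`, `first_session`, `last_session`,
#'   `n_sessions`, `partial`, and binned means of the numeric measures.
#' @export
bin_sessions <- function(timeline, bin_size = 4) {
  stopifnot(bin_size >= 1)
  if (nrow(timeline) == 0) return(timeline[0, 0])
  keys <- intersect(c("subject_id", "sex", "task"), names(timeline))
  measure_cols <- setdiff(
    names(timeline)[vapply(timeline, is.numeric, logical(1))],
    c("session_index", "n_trials"))
  timeline |>
    group_by(across(all_of(keys))) |>
    arrange(.data$session_index, .by_group = TRUE) |>
    mutate(bin = (row_number() - 1L) %/% as.integer(bin_size) + 1L) |>
    group_by(.data$bin, .add = TRUE) |>
    summarize(
      first_session = min(.data$session_index),
      last_session = max(.data$session_index),
      n_sessions = dplyr::n(),
      partial = dplyr::n() < bin_size,
      across(all_of(measure_cols), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop")
}
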