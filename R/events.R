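# Event logs: timestamped streams in the style of chamber acquisition
# software (context transitions, cue on/off, rewards, port entries/exits).

EVENT_KINDS <- c("context_on", "cue_on", "cue_off", "reward",
                 "port_entry", "port_exit")

validate_occupancy <- function(occupancy) {
  if (is.null(occupancy) || nrow(occupancy) == 0) {
    return(tibble(entry_s = numeric(0), exit_s = numeric(0)))
  }
  stopifnot(all(c("entry_s", "exit_s") %in% names(occupancy)))
  occupancy <- as_tibble(occupancy[c("entry_s", "exit_s")])
  if (any(occupancy$exit_s <= occupancy$entry_s)) {
    stop("occupancy intervals must have entry_s < exit_s")
  }
  if (is.unsorted(occupancy$entry_s, strictly = TRUE)) {
    stop("occupancy intervals must be sorted by entry time")
  }
  n <- nrow(occupancy)
  if (n > 1 && any(occupancy$entry_s[-1] < occupancy$exit_s[-n])) {
    stop("occupancy intervals must not overlap")
  }
  # merge touching intervals so port entries/exits strictly alternate
  if (n > 1) {
    new_run <- c(TRUE, occupancy$entry_s[-1] > occupancy$exit_s[-n])
    grp <- cumsum(new_run)
    occupancy <- tibble(
      entry_s = as.numeric(tapply(occupancy$entry_s, grp, min)),
      exit_s = as.numeric(tapply(occupancy$exit_s, grp, max)))
  }
  occupancy
}

#' Render a session schedule into an event log
#'
#' Merges schedule-driven events (a `context_on` at each phase start,
#' `cue_on`/`cue_off` around each 10-s trial, a single `reward` event at
#' cue offset on rewarded trials) with port-occupancy intervals
#' (`port_entry`/`port_exit` pairs).
#'
#' @param schedule A `session_schedule` from [generate_schedule()].
#' @param occupancy Data frame with columns `entry_s`, `exit_s`: sorted,
#'   non-overlapping port-occupancy intervals. `NULL` for no port events.
#' @param subject_id,sex Subject metadata (`sex` is `"M"` or `"F"`).
#' @return An `event_log`: list with subject metadata and an `events`
#'   tibble (`time_s`, `kind`, `payload`) sorted by time.
#' @examples
#' sch <- generate_schedule(make_task("simple"), seed = 1)
#' log <- render_events(sch, tibble::tibble(entry_s = 100, exit_s = 130))
#' table(log$events$kind)
#' @export
render_events <- function(schedule, occupancy = NULL, subject_id = "subj01",
                          sex = c("M", "F")) {
  stopifnot(inherits(schedule, "session_schedule"))
  sex <- match.arg(sex)
  occupancy <- validate_occupancy(occupancy)

  tr <- schedule$trials
  ev <- bind_rows(
    tibble(time_s = schedule$phases$start_s, kind = "context_on",
           payload = schedule$phases$context),
    tibble(time_s = tr$onset_s, kind = "cue_on", payload = tr$cue),
    tibble(time_s = tr$onset_s + tr$duration_s, kind = "cue_off",
           payload = tr$cue),
    tibble(time_s = tr$onset_s[tr$rewarded] + tr$duration_s[tr$rewarded],
           kind = "reward", payload = tr$outcome_id[tr$rewarded]),
    tibble(time_s = occupancy$entry_s, kind = "port_entry", payload = ""),
    tibble(time_s = occupancy$exit_s, kind = "port_exit", payload = ""))
  ev <- ev[order(ev$time_s, match(ev$kind, EVENT_KINDS)), ]

  structure(
    list(subject_id = subject_id, sex = sex,
         task_name = schedule$task_name,
         schedule_phase = schedule$schedule_phase,
         session_index = schedule$session_index,
         events = as_tibble(ev)),
    class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat("<event_log> subject ", x$subject_id, " (", x$sex, "), task ",
      x$task_name, ", session ", x$session_index, ": ",
      nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' Reconstruct port-occupancy intervals from an event log
#'
#' Pairs alternating `port_entry`/`port_exit` events. An interval left open
#' at the end of the session is closed at the final event timestamp.
#'
#' @param log An `event_log`.
#' @return Tibble with `entry_s`, `exit_s`.
#' @export
occupancy_from_events <- function(log) {
  stopifnot(inherits(log, "event_log"))
  ev <- log$events
  port <- ev[ev$kind %in% c("port_entry", "port_exit"), ]
  if (nrow(port) == 0) {
    return(tibble(entry_s = numeric(0), exit_s = numeric(0)))
  }
  kinds <- port$kind
  expect <- rep(c("port_entry", "port_exit"), length.out = nrow(port))
  if (!all(kinds == expect)) {
    stop("port_entry/port_exit events do not strictly alternate")
  }
  entries <- port$time_s[kinds == "port_entry"]
  exits <- port$time_s[kinds == "port_exit"]
  if (length(exits) < length(entries)) {
    exits <- c(exits, max(ev$time_s))  # open interval closed at last event
  }
  tibble(entry_s = entries, exit_s = exits)
}

#' Reconstruct the trial table from an event log
#'
#' Derives per-trial context (most recent `context_on`), cue identity,
#' onset, delivered-reward flag and outcome from the event stream alone, so
#' analyses can run on logs without the generating schedule.
#'
#' @param log An `event_log`.
#' @return Tibble with `trial`, `phase`, `context`, `cue`, `onset_s`,
#'   `duration_s`, `rewarded`, `outcome_id`.
#' @export
trials_from_events <- function(log) {
  stopifnot(inherits(log, "event_log"))
  ev <- log$events
  ctx <- ev[ev$kind == "context_on", ]
  cue_on <- ev[ev$kind == "cue_on", ]
  rew <- ev[ev$kind == "reward", ]
  if (nrow(cue_on) == 0) {
    return(tibble(trial = integer(0), phase = integer(0),
                  context = character(0), cue = character(0),
                  onset_s = numeric(0), duration_s = numeric(0),
                  rewarded = logical(0), outcome_id = character(0)))
  }
  ph <- findInterval(cue_on$time_s, ctx$time_s)
  offset <- cue_on$time_s + CUE_S
  j <- findInterval(offset + 1e-6, rew$time_s)
  hit <- ifelse(j > 0 & abs(rew$time_s[pmax(j, 1)] - offset) < 1e-6,
                j, NA_integer_)
  tibble(
    trial = seq_len(nrow(cue_on)),
    phase = ph,
    context = ctx$payload[ph],
    cue = cue_on$payload,
    onset_s = cue_on$time_s,
    duration_s = CUE_S,
    rewarded = !is.na(hit),
    outcome_id = ifelse(is.na(hit), "none", rew$payload[hit]))
}

#' Write / read event logs
#'
#' One CSV per subject-session (`time_s`, `kind`, `payload`) plus a JSON
#' sidecar with subject metadata, named `<subject>_s<session>.csv/.json`.
#'
#' @param log An `event_log`.
#' @param dir Output directory (created if missing).
#' @return `write_event_log()` returns the CSV path invisibly;
#'   `read_event_log()` returns the `event_log`.
#' @export
write_event_log <- function(log, dir) {
  stopifnot(inherits(log, "event_log"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, sprintf("%s_s%03d", log$subject_id,
                                 log$session_index))
  readr::write_csv(log$events, paste0(base, ".csv"))
  meta <- log[c("subject_id", "sex", "task_name", "schedule_phase",
                "session_index")]
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(base, ".csv"))
}

#' @param path Path to an event-log CSV written by [write_event_log()]
#'   (the `.json` sidecar must sit next to it).
#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  events <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(), kind = readr::col_character(),
    payload = readr::col_character()))
  events$payload[is.na(events$payload)] <- ""
  structure(
    list(subject_id = meta$subject_id, sex = meta$sex,
         task_name = meta$task_name, schedule_phase = meta$schedule_phase,
         session_index = as.integer(meta$session_index),
         events = as_tibble(events)),
    class = "event_log")
}
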