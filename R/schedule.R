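# Session schedules: 40 alternating 2-min context phases, 80 cue trials.

SESSION_S <- 4800     # 80 min
PHASE_S <- 120        # 2 min
N_PHASES <- 40L
N_TRIALS <- 80L
CUE_S <- 10           # cue duration

#' Draw intertrial intervals
#'
#' ITIs (cue offset to next cue onset) follow a rectangular (uniform)
#' distribution with mean 50 s and half-width 20 s, i.e. uniform on
#' \[30, 70\] s. [generate_schedule()] draws from this distribution and
#' resamples (bounded) or truncates at context-phase boundaries so that cue
#' windows never straddle a context transition.
#'
#' @param n Number of draws.
#' @param seed Optional integer seed (local to the call).
#' @return Numeric vector of `n` intervals in seconds.
#' @examples
#' mean(draw_iti(1e4, seed = 1))
#' @export
draw_iti <- function(n, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  runif(n, min = 30, max = 70)
}

# Assign cue identities to the two slots of each phase of one context.
#
# When the context has balanced counts (n_x == n_phases, a multiple of 4),
# exactly n/4 phases each receive the pairs XX, XY, YX, YY, randomly
# assigned to phases: trial-type counts are exact and the second slot's cue
# is exactly independent of the first. Otherwise (e.g. the reduced 10/30
# split) slots are dealt from a shuffled pool of labels, which keeps counts
# exact with slot identities exchangeable.
assign_phase_cues <- function(n_phases, n_x) {
  n_slots <- 2L * n_phases
  stopifnot(n_x >= 0, n_x <= n_slots)
  if (n_x * 2L == n_slots && n_phases %% 4L == 0L) {
    q <- n_phases %/% 4L
    pairs <- c(rep("XX", q), rep("XY", q), rep("YX", q), rep("YY", q))
    pairs <- pairs[sample.int(n_phases)]
    matrix(c(substr(pairs, 1, 1), substr(pairs, 2, 2)), ncol = 2)
  } else {
    pool <- sample(rep(CUES, c(n_x, n_slots - n_x)))
    matrix(pool, ncol = 2, byrow = TRUE)
  }
}

#' Generate a session schedule
#'
#' Lays out one 80-min session: 40 context phases of 120 s strictly
#' alternating LIGHT/DARK, two 10-s cue trials per phase (80 trials), with
#' trial-type counts fixed by the task's schedule phase (see [make_task()])
#' and ITIs drawn from the rectangular distribution of [draw_iti()]. Cue
#' windows always lie entirely within their phase: onsets are resampled a
#' bounded number of times and then placed by a truncated draw if the
#' phase boundary leaves no room for a fresh ITI draw.
#'
#' Reward flags are deterministic for cells with probability 0 or 1 and
#' Bernoulli draws otherwise (the `no_discr` task).
#'
#' @param task A `task_spec` from [make_task()].
#' @param session_index Positive session number (metadata only).
#' @param seed Optional integer seed (local to the call).
#' @param start_context Context of the first phase, `"LIGHT"` by default.
#' @return A `session_schedule`: list with `task_name`, `schedule_phase`,
#'   `session_index`, a `phases` tibble (`phase`, `context`, `start_s`,
#'   `end_s`) and a `trials` tibble (`trial`, `phase`, `context`, `cue`,
#'   `onset_s`, `duration_s`, `rewarded`, `outcome_id`).
#' @examples
#' sch <- generate_schedule(make_task("ctx_dep_o1"), seed = 1)
#' table(sch$trials$context, sch$trials$cue)
#' @export
generate_schedule <- function(task, session_index = 1L, seed = NULL,
                              start_context = c("LIGHT", "DARK")) {
  stopifnot(inherits(task, "task_spec"))
  if (session_index < 1) stop("session_index must be >= 1")
  start_context <- match.arg(start_context)
  if (!is.null(seed)) withr::local_seed(seed)

  ctx_seq <- rep(c(start_context, setdiff(CONTEXTS, start_context)),
                 length.out = N_PHASES)
  phases <- tibble(
    phase = seq_len(N_PHASES), context = ctx_seq,
    start_s = (seq_len(N_PHASES) - 1) * PHASE_S,
    end_s = seq_len(N_PHASES) * PHASE_S)

  # cue identities, per context
  cue_mat <- matrix(NA_character_, nrow = N_PHASES, ncol = 2)
  for (ctx in CONTEXTS) {
    idx <- which(ctx_seq == ctx)
    n_x <- task$trial_counts$n[task$trial_counts$context == ctx &
                                 task$trial_counts$cue == "X"]
    cue_mat[idx, ] <- assign_phase_cues(length(idx), n_x)
  }

  # onset times: walk trials in order, ITI measured offset -> next onset.
  # The first slot of a phase is capped at phase_start + 70 so the second
  # slot can still fit (min ITI 30 + 10 s cue before phase end).
  onset <- numeric(N_TRIALS)
  prev_off <- 0
  for (j in seq_len(N_TRIALS)) {
    p <- (j + 1L) %/% 2L
    ps <- (p - 1) * PHASE_S
    slack <- if (j %% 2L == 1L) 70 else PHASE_S - CUE_S
    lower <- max(ps, prev_off + 30)
    upper <- min(ps + slack, prev_off + 70)
    if (upper < lower) upper <- lower
    o <- NA_real_
    for (try in 1:50) {
      cand <- prev_off + draw_iti(1)
      if (cand >= lower && cand <= upper) { o <- cand; break }
    }
    if (is.na(o)) o <- if (upper > lower) runif(1, lower, upper) else lower
    onset[j] <- o
    prev_off <- o + CUE_S
  }

  trials <- tibble(
    trial = seq_len(N_TRIALS),
    phase = rep(seq_len(N_PHASES), each = 2),
    context = rep(ctx_seq, each = 2),
    cue = as.vector(t(cue_mat)),
    onset_s = onset,
    duration_s = CUE_S) |>
    left_join(task$contingency, by = c("context", "cue"))
  p_rew <- trials$reward_probability
  trials$rewarded <- ifelse(p_rew %in% c(0, 1), p_rew == 1,
                            runif(N_TRIALS) < p_rew)
  trials$outcome_id <- ifelse(trials$rewarded, trials$outcome_id, "none")
  trials$reward_probability <- NULL

  structure(
    list(task_name = task$task_name, schedule_phase = task$schedule_phase,
         session_index = as.integer(session_index),
         phases = phases, trials = trials),
    class = "session_schedule")
}

#' @export
print.session_schedule <- function(x, ...) {
  cat("<session_schedule> task ", x$task_name, " (", x$schedule_phase,
      "), session ", x$session_index, ": ", nrow(x$phases), " phases, ",
      nrow(x$trials), " trials, ", sum(x$trials$rewarded), " rewarded\n",
      sep = "")
  invisible(x)
}
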