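# Parametric responder: generates realistic event logs with sex-dependent
# acquisition, prior-reward history effects, and acute-stress decrements.

#' Responder parameters
#'
#' The responder is parametrized on the scales the analyses report. The
#' expected discrimination ratio follows a logistic acquisition curve
#' `r(s) = 0.5 + (r_max - 0.5) * plogis(disc_rate * (s - midpoint))` with a
#' sex-specific midpoint (for `ctx_dep_o1` the female midpoint is later
#' than the male, emulating slower female acquisition; other tasks have
#' equal midpoints and `no_discr` never discriminates). Responding on
#' rewarded trials rises quickly to `rew_asymptote` for both sexes; the
#' expected non-rewarded occupancy is derived from the ratio. Per trial,
#' the subject responds with probability `occupancy / occupancy_mean` and,
#' when responding, occupies a Beta-distributed fraction (mean
#' `occupancy_mean`, concentration `occupancy_conc`) of the last 5 s of
#' the cue, so expected time in port matches the programmed occupancy.
#'
#' Two structured perturbations are programmed on those same scales:
#' `prior_reward_bump` is added to the response probability (and hence
#' proportionally to time in port) on non-rewarded trials that follow a
#' rewarded trial -- positive for males, zero for females in `ctx_dep_o1`;
#' `stress_drop` is subtracted from the expected ratio on the designated
#' stress session (male-only in `ctx_dep_o1`, sex-equal in the simple and
#' dual-outcome tasks, absent in `no_discr`).
#'
#' @param task Task name; fixes the task-dependent defaults.
#' @param r_max Asymptotic discrimination ratio.
#' @param disc_rate Logistic rate of the discrimination curve (per
#'   session).
#' @param disc_midpoint Named vector `c(M=, F=)` of logistic midpoints in
#'   sessions (`Inf` disables discrimination).
#' @param midpoint_sd Between-subject SD of the midpoint (sessions).
#' @param rew_asymptote,rew_rate,rew_midpoint Logistic parameters of the
#'   rewarded-trial occupancy curve (shared by sexes).
#' @param prior_reward_bump Named vector `c(M=, F=)`: additive bump on the
#'   non-rewarded-trial response probability after a rewarded trial.
#' @param stress_drop Named vector `c(M=, F=)`: drop in expected ratio on
#'   the stress session.
#' @param occupancy_mean,occupancy_conc Beta parameters of the occupied
#'   fraction given a response.
#' @param precue_prob Probability of a brief exploratory port visit in the
#'   5 s before a cue (visible in the pre-cue measure only).
#' @param reduced_from First session run under the `reduced` schedule
#'   (default 36 for `ctx_dep_o1`, `Inf` otherwise).
#' @return A `responder_params` list.
#' @export
responder_params <- function(task = "ctx_dep_o1",
                             r_max = 0.85,
                             disc_rate = NULL,
                             disc_midpoint = NULL,
                             midpoint_sd = 6,
                             rew_asymptote = 0.85,
                             rew_rate = 0.6,
                             rew_midpoint = 3,
                             prior_reward_bump = NULL,
                             stress_drop = NULL,
                             occupancy_mean = 0.9,
                             occupancy_conc = 30,
                             precue_prob = 0.15,
                             reduced_from = NULL) {
  stopifnot(task %in% TASK_NAMES)
  if (is.null(disc_rate)) {
    disc_rate <- switch(task, ctx_dep_o1 = 0.15, simple = 0.6,
                        no_discr = 0.15, ctx_dep_o1o2 = 0.35)
  }
  if (is.null(disc_midpoint)) {
    disc_midpoint <- switch(task,
      ctx_dep_o1 = c(M = 30, F = 45),
      simple = c(M = 10, F = 10),
      no_discr = c(M = Inf, F = Inf),
      ctx_dep_o1o2 = c(M = 17, F = 17))
  }
  if (is.null(prior_reward_bump)) {
    prior_reward_bump <- if (task == "ctx_dep_o1") c(M = 0.10, F = 0)
      else c(M = 0, F = 0)
  }
  if (is.null(stress_drop)) {
    stress_drop <- switch(task,
      ctx_dep_o1 = c(M = 0.15, F = 0),
      simple = c(M = 0.08, F = 0.08),
      no_discr = c(M = 0, F = 0),
      ctx_dep_o1o2 = c(M = 0.08, F = 0.08))
  }
  if (is.null(reduced_from)) {
    reduced_from <- if (task == "ctx_dep_o1") 36 else Inf
  }
  structure(
    list(task = task, r_max = r_max, disc_rate = disc_rate,
         disc_midpoint = disc_midpoint, midpoint_sd = midpoint_sd,
         rew_asymptote = rew_asymptote, rew_rate = rew_rate,
         rew_midpoint = rew_midpoint,
         prior_reward_bump = prior_reward_bump, stress_drop = stress_drop,
         occupancy_mean = occupancy_mean, occupancy_conc = occupancy_conc,
         precue_prob = precue_prob, reduced_from = reduced_from),
    class = "responder_params")
}

#' Expected discrimination ratio of the responder
#'
#' @param params A `responder_params`.
#' @param sex `"M"` or `"F"`.
#' @param session Session index (vectorized).
#' @param midpoint Subject-specific midpoint; defaults to the sex's
#'   population midpoint.
#' @param stressed Logical: apply the stress drop to these sessions.
#' @return Expected ratio, clamped to \[0.05, 0.95\].
#' @export
responder_ratio <- function(params, sex, session,
                            midpoint = params$disc_midpoint[[sex]],
                            stressed = FALSE) {
  d <- if (is.infinite(midpoint)) 0 * session
    else plogis(params$disc_rate * (session - midpoint))
  r <- 0.5 + (params$r_max - 0.5) * d
  r <- r - ifelse(stressed, params$stress_drop[[sex]], 0)
  pmin(0.95, pmax(0.05, r))
}

# simulate one subject-session into an event log
simulate_session <- function(task_std, task_red, params, subject_id, sex,
                             session, midpoint, stress_session) {
  task <- if (session >= params$reduced_from) task_red else task_std
  sch <- generate_schedule(task, session_index = session)
  tr <- sch$trials
  n <- nrow(tr)

  stressed <- !is.na(stress_session) && session == stress_session
  r <- responder_ratio(params, sex, session, midpoint, stressed)
  o_rew <- params$rew_asymptote *
    plogis(params$rew_rate * (session - params$rew_midpoint))
  o_non <- o_rew * (1 - r) / r

  prior_rew <- c(FALSE, tr$rewarded[-n])
  bump <- params$prior_reward_bump[[sex]] * (!tr$rewarded & prior_rew)
  o_trial <- ifelse(tr$rewarded, o_rew, o_non)
  p_resp <- clip01(o_trial / params$occupancy_mean + bump)

  responded <- runif(n) < p_resp
  m <- params$occupancy_mean
  shape1 <- m * params$occupancy_conc
  shape2 <- (1 - m) * params$occupancy_conc
  frac <- ifelse(responded, rbeta(n, shape1, shape2), 0)

  offset <- tr$onset_s + tr$duration_s
  entry <- offset - 5 * frac
  occ <- tibble(entry_s = entry[responded], exit_s = offset[responded])

  # brief exploratory visits shortly before some cues (pre-cue measure)
  pre <- runif(n) < params$precue_prob
  if (any(pre)) {
    pe <- tr$onset_s[pre] - 5 + runif(sum(pre), 0, 2)
    px <- pe + runif(sum(pre), 0.3, 2.5)
    px <- pmin(px, tr$onset_s[pre] - 0.05)
    occ <- bind_rows(occ, tibble(entry_s = pe, exit_s = px))
  }
  occ <- arrange(occ[occ$exit_s > occ$entry_s, ], .data$entry_s)
  render_events(sch, occ, subject_id = subject_id, sex = sex)
}

#' Simulate a synthetic cohort
#'
#' Generates one event log per subject-session through the full protocol
#' (schedules, responder behavior, port events). Deterministic given
#' `seed`: two runs with the same arguments produce identical logs.
#'
#' @param task Task name.
#' @param n_male,n_female Number of subjects per sex (>= 0).
#' @param sessions Integer vector of session indices to simulate, e.g.
#'   `1:72`.
#' @param params A [responder_params()] (defaults to the task's defaults).
#' @param stress_session Session index run immediately after acute
#'   restraint stress, or `NA` for none.
#' @param seed Optional integer seed (local to the call).
#' @return A `cohort`: list with `subjects` (tibble: `subject_id`, `sex`,
#'   `task`, `midpoint`) and `logs` (list of `event_log`, one per
#'   subject-session).
#' @examples
#' coh <- simulate_cohort("simple", 2, 2, sessions = 1:6, seed = 1)
#' length(coh$logs)  # 4 subjects x 6 sessions
#' @export
simulate_cohort <- function(task, n_male, n_female, sessions = 1:72,
                            params = responder_params(task),
                            stress_session = NA, seed = NULL) {
  stopifnot(task %in% TASK_NAMES, n_male >= 0, n_female >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  task_std <- make_task(task, "standard")
  task_red <- make_task(task, "reduced")

  subjects <- tibble(
    subject_id = sprintf("%s%02d", rep(c("m", "f"), c(n_male, n_female)),
                         c(seq_len(n_male), seq_len(n_female))),
    sex = rep(c("M", "F"), c(n_male, n_female)),
    task = task)
  subjects$midpoint <- params$disc_midpoint[subjects$sex] +
    ifelse(is.infinite(params$disc_midpoint[subjects$sex]), 0,
           rnorm(nrow(subjects), 0, params$midpoint_sd))

  logs <- vector("list", nrow(subjects) * length(sessions))
  k <- 0
  for (i in seq_len(nrow(subjects))) {
    for (s in sessions) {
      k <- k + 1
      logs[[k]] <- simulate_session(
        task_std, task_red, params, subjects$subject_id[i],
        subjects$sex[i], s, subjects$midpoint[i], stress_session)
    }
  }
  structure(list(subjects = subjects, logs = logs,
                 sessions = as.integer(sessions), params = params,
                 stress_session = stress_session),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> task ", x$subjects$task[1], ": ",
      sum(x$subjects$sex == "M"), "M + ", sum(x$subjects$sex == "F"),
      "F, sessions ", min(x$sessions), "-", max(x$sessions), " (",
      length(x$logs), " logs)\n", sep = "")
  invisible(x)
}

#' Per-session summaries for a cohort
#'
#' Runs every log through [trial_metrics()] and [session_summary()].
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @return Tibble: `subject_id`, `sex`, `task` plus [session_summary()]
#'   columns, one row per subject-session.
#' @export
cohort_session_summaries <- function(cohort) {
  bind_rows(lapply(cohort$logs, function(log) {
    ss <- session_summary(trial_metrics(log), log$session_index)
    bind_cols(tibble(subject_id = log$subject_id, sex = log$sex,
                     task = log$task_name), ss)
  }))
}

#' Per-trial metrics for a cohort
#'
#' @param cohort A `cohort`.
#' @return Tibble of [trial_metrics()] rows with `subject_id`, `sex`,
#'   `task`, `session_index` prepended.
#' @export
cohort_trial_metrics <- function(cohort) {
  bind_rows(lapply(cohort$logs, function(log) {
    bind_cols(tibble(subject_id = log$subject_id, sex = log$sex,
                     task = log$task_name,
                     session_index = log$session_index),
              trial_metrics(log))
  }))
}
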