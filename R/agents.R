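# Delta-rule learning agents embodying the two candidate associative
# architectures: elemental summation (cue + context weights) and
# hierarchical gating (context selects the active cue->outcome weight).

clip01 <- function(x) pmin(1, pmax(0, x))

task_outcomes <- function(task) {
  out <- unique(task$contingency$outcome_id[
    task$contingency$reward_probability > 0])
  if (!length(out)) "O1" else out
}

# cells with trial-frequency weights and per-outcome expected rewards
agent_cells <- function(task) {
  task$contingency |>
    left_join(task$trial_counts, by = c("context", "cue")) |>
    mutate(w = .data$n / sum(.data$n))
}

elemental_features <- function(context, cue, elements) {
  feats <- character(0)
  if ("cue" %in% elements) feats <- c(feats, paste0("cue_", cue))
  if ("context" %in% elements) feats <- c(feats, paste0("ctx_", context))
  feats
}

# expected-ratio over the contingency table given per-cell occupancy:
# each cell contributes its reward probability's worth of rewarded trials
# and the complement of non-rewarded trials, at its trial frequency.
expected_table_ratio <- function(cells, occupancy) {
  p <- cells$reward_probability
  w <- cells$w
  t_rew <- sum(w * p * occupancy) / sum(w * p)
  t_non <- sum(w * (1 - p) * occupancy) / sum(w * (1 - p))
  discrimination_ratio(t_rew, t_non)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]")
  }
}

agent_result <- function(mode, weights, cells, ratio, trace = NULL) {
  structure(list(mode = mode, weights = weights, cells = cells,
                 ratio = ratio, trace = trace),
            class = "agent_fit")
}

#' @export
print.agent_fit <- function(x, ...) {
  cat("<agent_fit> ", x$mode, " run; asymptotic discrimination ratio ",
      format(round(x$ratio, 4)), "\n", sep = "")
  invisible(x)
}

run_agent <- function(task, alpha, n_sessions, seed, mode, tol, max_iter,
                      gain, feature_fun) {
  check_alpha(alpha)
  cells <- agent_cells(task)
  outcomes <- task_outcomes(task)
  feats <- lapply(seq_len(nrow(cells)),
                  function(i) feature_fun(cells$context[i], cells$cue[i]))
  all_feats <- unique(unlist(feats))
  weights <- lapply(setNames(outcomes, outcomes),
                    function(o) setNames(numeric(length(all_feats)),
                                         all_feats))
  predict_cells <- function(weights) {
    sapply(setNames(outcomes, outcomes), function(o) {
      vapply(feats, function(f) sum(weights[[o]][f]), numeric(1))
    })
  }

  if (mode == "expected") {
    targets <- sapply(setNames(outcomes, outcomes), function(o) {
      ifelse(cells$outcome_id == o, cells$reward_probability, 0)
    })
    for (it in seq_len(max_iter)) {
      max_step <- 0
      for (o in outcomes) {
        pred <- vapply(feats, function(f) sum(weights[[o]][f]), numeric(1))
        delta <- targets[, o] - pred
        grad <- setNames(numeric(length(all_feats)), all_feats)
        for (i in seq_len(nrow(cells))) {
          grad[feats[[i]]] <- grad[feats[[i]]] + cells$w[i] * delta[i]
        }
        step <- alpha * grad
        weights[[o]] <- weights[[o]] + step
        max_step <- max(max_step, max(abs(step)))
      }
      if (max_step < tol) break
    }
    pred <- predict_cells(weights)
    combined <- apply(as.matrix(pred), 1, max)  # strongest outcome drives
    occ <- clip01(gain * combined)
    cells$prediction <- combined
    cells$occupancy <- occ
    return(agent_result(mode, weights, cells,
                        expected_table_ratio(cells, occ)))
  }

  # sampled: trial-by-trial learning over generated schedules
  if (!is.null(seed)) withr::local_seed(seed)
  trace <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    sch <- generate_schedule(task, session_index = s)
    tr <- sch$trials
    pred_out <- numeric(nrow(tr))
    occ_out <- numeric(nrow(tr))
    for (i in seq_len(nrow(tr))) {
      f <- feature_fun(tr$context[i], tr$cue[i])
      preds <- vapply(outcomes, function(o) sum(weights[[o]][f]),
                      numeric(1))
      combined <- max(preds)
      pred_out[i] <- combined
      occ_out[i] <- clip01(gain * combined)
      for (o in outcomes) {
        r <- as.numeric(tr$rewarded[i] && tr$outcome_id[i] == o)
        weights[[o]][f] <- weights[[o]][f] + alpha * (r - preds[[o]])
      }
    }
    trace[[s]] <- tibble(session_index = s, trial = tr$trial,
                         context = tr$context, cue = tr$cue,
                         rewarded = tr$rewarded, prediction = pred_out,
                         occupancy = occ_out)
  }
  trace <- bind_rows(trace)
  cells$prediction <- NA_real_
  cells$occupancy <- NA_real_
  agent_result(mode, weights, cells, trace_ratio(trace), trace)
}

#' Discrimination ratio of an agent trace
#'
#' Computed from the generated occupancy fractions over the last
#' `last_sessions` sessions, splitting trials by actual reward delivery.
#'
#' @param trace The `trace` tibble of a sampled agent run.
#' @param last_sessions Number of final sessions to aggregate (default 2).
#' @return A discrimination ratio, `NA` if undefined.
#' @export
trace_ratio <- function(trace, last_sessions = 2) {
  keep <- trace$session_index >
    max(trace$session_index) - last_sessions
  tr <- trace[keep, ]
  discrimination_ratio(mean(tr$occupancy[tr$rewarded]),
                       mean(tr$occupancy[!tr$rewarded]))
}

#' Elemental (summation) delta-rule agent
#'
#' Implements the pure associative-summation architecture: the prediction
#' on a trial is the sum of independent cue and context weights (no
#' configural terms), updated by the delta rule (learning rate `alpha`
#' times prediction error, applied to the active elements). With
#' differential outcomes each outcome has its own weight vector and
#' behavior follows the most strongly predicted outcome. Predictions map
#' to occupancy of the last-5-s scoring window by a clipped linear gain.
#'
#' Because a sum of cue and context weights cannot represent the
#' XOR-structured `ctx_dep_o1` contingency, this agent converges to a
#' discrimination ratio of 0.5 there (no discrimination), while it solves
#' `simple` perfectly.
#'
#' @param task A `task_spec`.
#' @param alpha Learning rate in \[0, 1\] (0 is the no-update limit).
#' @param n_sessions Number of training sessions (sampled mode).
#' @param seed Optional seed (sampled mode, local to the call).
#' @param mode `"sampled"` (trial-by-trial over generated schedules) or
#'   `"expected"` (noise-free batch updates over the contingency table,
#'   iterated to convergence).
#' @param tol,max_iter Convergence control for `"expected"` mode: stop
#'   when the largest weight change falls below `tol`.
#' @param elements Which elements carry weights; default cue and context.
#' @param gain Linear gain of the prediction-to-occupancy mapping.
#' @return An `agent_fit`: `weights` (per outcome), `cells` (per-cell
#'   predictions and occupancy in expected mode), `ratio` (asymptotic
#'   discrimination ratio), `trace` (sampled mode).
#' @examples
#' run_elemental(make_task("ctx_dep_o1"), mode = "expected")$ratio  # 0.5
#' @export
run_elemental <- function(task, alpha = 0.1, n_sessions = 10, seed = NULL,
                          mode = c("sampled", "expected"), tol = 1e-8,
                          max_iter = 1e5, elements = c("cue", "context"),
                          gain = 1) {
  mode <- match.arg(mode)
  run_agent(task, alpha, n_sessions, seed, mode, tol, max_iter, gain,
            function(context, cue) elemental_features(context, cue,
                                                      elements))
}

#' Hierarchical (context-gated) delta-rule agent
#'
#' The context selects which cue weight drives the prediction: one weight
#' per (context, cue) configuration, updated by the delta rule for the
#' active configuration only. Because every configuration of the
#' deterministic tasks has a fixed outcome, the gated weights converge to
#' the cell reward probabilities and the agent solves the XOR-structured
#' `ctx_dep_o1` task (ratio near 1).
#'
#' @inheritParams run_elemental
#' @param gating If `FALSE`, the context is ignored and weights attach to
#'   the cue alone; the agent then reduces to [run_elemental()] with
#'   `elements = "cue"`.
#' @return An `agent_fit`; see [run_elemental()].
#' @examples
#' run_hierarchical(make_task("ctx_dep_o1"), mode = "expected")$ratio  # 1
#' @export
run_hierarchical <- function(task, alpha = 0.1, n_sessions = 10,
                             seed = NULL, mode = c("sampled", "expected"),
                             tol = 1e-8, max_iter = 1e5, gating = TRUE,
                             gain = 1) {
  mode <- match.arg(mode)
  feature_fun <- if (gating) {
    function(context, cue) paste0("w_", context, ":", cue)
  } else {
    function(context, cue) paste0("w_", cue)
  }
  run_agent(task, alpha, n_sessions, seed, mode, tol, max_iter, gain,
            feature_fun)
}
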