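make_trial_block <- function(rewarded_by_session, subject_id = "s1") {
  dplyr::bind_rows(lapply(seq_along(rewarded_by_session), function(s) {
    rew <- rewarded_by_session[[s]]
    tibble::tibble(subject_id = subject_id, session_index = s,
                   trial = seq_along(rew), rewarded = rew)
  }))
}

test_that("labeling drops first trials: 10 x 80 gives 790 labeled", {
  set.seed(1)
  blocks <- make_trial_block(replicate(10, runif(80) < 0.25,
                                       simplify = FALSE))
  lab <- label_history(blocks)
  expect_equal(sum(!is.na(lab$prior_outcome)), 790)
  expect_true(all(is.na(lab$prior_outcome[lab$trial == 1])))
  # conservation across strata
  counts <- table(lab$prior_outcome, useNA = "no")
  expect_equal(sum(counts), 790)
})

test_that("prior outcome and run length follow the outcome sequence", {
  lab <- label_history(make_trial_block(list(c(TRUE, FALSE, FALSE))))
  expect_equal(lab$prior_outcome, c(NA, "R", "NR"))
  expect_equal(lab$run_length, c(NA, 1L, 1L))
  lab2 <- label_history(make_trial_block(list(
    c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))))
  expect_equal(lab2$prior_outcome, c(NA, "R", "R", "R", "NR", "NR"))
  expect_equal(lab2$run_length, c(NA, 1L, 2L, 3L, 1L, 2L))
})

test_that("labels are a pure function of the outcome sequence", {
  set.seed(2)
  seqs <- replicate(4, runif(80) < 0.5, simplify = FALSE)
  lab_a <- label_history(make_trial_block(seqs))
  lab_b <- label_history(make_trial_block(seqs[c(3, 1, 4, 2)]))
  for (i in seq_along(seqs)) {
    j <- c(3, 1, 4, 2)[i]
    expect_equal(
      lab_a$prior_outcome[lab_a$session_index == j],
      lab_b$prior_outcome[lab_b$session_index == i])
    expect_equal(
      lab_a$run_length[lab_a$session_index == j],
      lab_b$run_length[lab_b$session_index == i])
  }
})

test_that("collapsing run-length strata reproduces the binary means", {
  coh <- simulate_cohort("ctx_dep_o1", 2, 2, sessions = 71:74, seed = 44)
  lab <- label_history(cohort_trial_metrics(coh))
  lab <- lab[!is.na(lab$prior_outcome), ]
  lab$current_type <- ifelse(lab$rewarded, "rewarded", "non-rewarded")
  eff <- history_effects(label_history(cohort_trial_metrics(coh)))
  rl <- eff$run_length
  for (ct in unique(rl$current_type)) {
    for (po in unique(rl$prior_outcome)) {
      sub <- rl[rl$current_type == ct & rl$prior_outcome == po, ]
      pooled <- sum(sub$time_in_port_pct * sub$n_trials) /
        sum(sub$n_trials)
      direct <- mean(lab$time_in_port_pct[lab$current_type == ct &
                                            lab$prior_outcome == po])
      expect_equal(pooled, direct, tolerance = 1e-9)
    }
  }
})

test_that("a null responder shows no history effect", {
  p <- responder_params("ctx_dep_o1", prior_reward_bump = c(M = 0, F = 0),
                        midpoint_sd = 0)
  coh <- simulate_cohort("ctx_dep_o1", 6, 0, sessions = 71:80, params = p,
                         seed = 55)
  eff <- history_effects(label_history(cohort_trial_metrics(coh)))
  ds <- eff$diff_scores[eff$diff_scores$current_type == "non-rewarded", ]
  expect_lt(abs(mean(ds$diff_p_response)), 0.03)
})
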