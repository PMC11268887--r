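test_that("4-of-5 consecutive sessions rule anchors on the window end", {
  # pass pattern P,P,N,P,P in sessions 1-5 -> discriminator at session 5
  tl <- manual_timeline(light_x = c(30, 30, 10, 30, 30),
                        dark_x = rep(10, 5),
                        dark_y = c(30, 30, 10, 30, 30),
                        light_y = rep(10, 5))
  res <- classify_subject(tl, "ctx_dep_o1")
  expect_true(res$is_discriminator)
  expect_equal(res$criterion_session, 5L)
})

test_that("context tasks require the criterion for both cues", {
  # cue X passes every session, cue Y never
  tl <- manual_timeline(light_x = rep(30, 8), dark_x = rep(10, 8),
                        dark_y = rep(10, 8), light_y = rep(10, 8))
  expect_false(classify_subject(tl, "ctx_dep_o1")$is_discriminator)
  # flat performance at ratio 0.5 never qualifies
  flat <- manual_timeline(rep(20, 8), rep(20, 8), rep(20, 8), rep(20, 8))
  expect_false(classify_subject(flat, "ctx_dep_o1")$is_discriminator)
  # zero responding everywhere does not pass either
  zero <- manual_timeline(rep(0, 8), rep(0, 8), rep(0, 8), rep(0, 8))
  expect_false(classify_subject(zero, "ctx_dep_o1")$is_discriminator)
  expect_error(classify_subject(tl, "no_discr"), "not applicable")
})

test_that("joint and per-cue windows differ only when passes are disjoint", {
  # X passes sessions 1-5, Y passes sessions 6-10: separate windows
  # qualify, the joint (default, stricter) reading does not
  tl <- manual_timeline(
    light_x = c(rep(30, 5), rep(10, 5)), dark_x = rep(10, 10),
    dark_y = c(rep(10, 5), rep(30, 5)), light_y = rep(10, 10))
  expect_false(classify_subject(tl, "ctx_dep_o1")$is_discriminator)
  sep <- classify_subject(tl, "ctx_dep_o1", joint_windows = FALSE)
  expect_true(sep$is_discriminator)
  # Y first qualifies over sessions 5-9 (4 passes of that window)
  expect_equal(sep$criterion_session, 9L)
})

test_that("the 1.5x rule and the ratio >= 0.6 rule classify identically", {
  grid <- expand.grid(t_rew = seq(0, 3, by = 0.05),
                      t_nonrew = seq(0, 3, by = 0.05))
  grid <- grid[grid$t_rew + grid$t_nonrew > 0, ]
  rule_15 <- grid$t_rew - 1.5 * grid$t_nonrew >= -1e-9
  rule_60 <- discrimination_ratio(grid$t_rew, grid$t_nonrew) - 0.6 >=
    -1e-9
  expect_equal(rule_15, rule_60)
})

test_that("raising rewarded responding never hurts classification", {
  set.seed(42)
  n_disc <- 0
  for (i in 1:30) {
    n <- 12
    # rewarded cells biased high so both outcomes occur across draws
    tl <- manual_timeline(light_x = runif(n, 10, 45),
                          dark_x = runif(n, 0, 30),
                          dark_y = runif(n, 10, 45),
                          light_y = runif(n, 0, 30))
    base <- classify_subject(tl, "ctx_dep_o1")
    up <- tl
    up$tip_light_x <- up$tip_light_x + runif(n, 0, 15)
    up$tip_dark_y <- up$tip_dark_y + runif(n, 0, 15)
    improved <- classify_subject(up, "ctx_dep_o1")
    expect_true(!base$is_discriminator || improved$is_discriminator)
    if (base$is_discriminator) {
      n_disc <- n_disc + 1
      expect_lte(improved$criterion_session, base$criterion_session)
    }
  }
  expect_gt(n_disc, 0)  # the property was exercised on both outcomes
  expect_lt(n_disc, 30)
})

test_that("sessions to criterion excludes non-discriminators", {
  res <- tibble::tibble(
    subject_id = sprintf("s%d", 1:7),
    sex = c("M", "M", "M", "F", "F", "F", "F"),
    task = "ctx_dep_o1",
    is_discriminator = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    criterion_session = c(10L, 12L, 14L, 30L, 40L, NA, NA))
  out <- sessions_to_criterion(res, group = "sex")
  s <- out$summary
  expect_equal(s$median_sessions[s$group == "M"], 12)
  expect_equal(s$median_sessions[s$group == "F"], 35)
  expect_equal(s$n_excluded[s$group == "F"], 2)
  expect_s3_class(out$omnibus, "htest")
  # single-subject group: median is that subject's value, no comparison
  one <- sessions_to_criterion(res[res$subject_id == "s1", ],
                               group = "sex")
  expect_equal(one$summary$median_sessions, 10)
  expect_null(one$omnibus)
  # group empty after exclusion is flagged
  res2 <- res
  res2$is_discriminator[res2$sex == "F"] <- FALSE
  out2 <- sessions_to_criterion(res2, group = "sex")
  expect_true(out2$summary$empty[out2$summary$group == "F"])
})

test_that("discriminator proportions use Pearson chi-square", {
  even <- tibble::tibble(sex = rep(c("M", "F"), each = 10),
                         is_discriminator = rep(TRUE, 20))
  expect_equal(unname(discriminator_proportions(even)$test$statistic), 0)
  skewed <- tibble::tibble(
    sex = rep(c("M", "F"), each = 10),
    is_discriminator = c(rep(TRUE, 8), rep(FALSE, 2),
                         rep(TRUE, 2), rep(FALSE, 8)))
  out <- discriminator_proportions(skewed)
  expect_equal(unname(out$test$statistic), 7.2)  # hand-computed Pearson
  expect_gt(unname(out$test$statistic), 0)
  expect_equal(unname(out$proportions), c(0.8, 0.2))
  expect_error(discriminator_proportions(skewed[0, ]), "empty")
})
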