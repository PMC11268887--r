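test_that("task contingency tables match the four training conditions", {
  t1 <- make_task("ctx_dep_o1")
  cells <- t1$contingency
  get <- function(tbl, ctx, cue, col) tbl[[col]][tbl$context == ctx &
                                                   tbl$cue == cue]
  expect_equal(get(cells, "LIGHT", "X", "reward_probability"), 1)
  expect_equal(get(cells, "DARK", "Y", "reward_probability"), 1)
  expect_equal(get(cells, "DARK", "X", "reward_probability"), 0)
  expect_equal(get(cells, "LIGHT", "Y", "reward_probability"), 0)
  expect_true(all(cells$outcome_id[cells$reward_probability > 0] == "O1"))

  t2 <- make_task("ctx_dep_o1o2")$contingency
  expect_equal(get(t2, "LIGHT", "X", "outcome_id"), "O1")
  expect_equal(get(t2, "DARK", "Y", "outcome_id"), "O2")

  ts <- make_task("simple")$contingency
  expect_true(all(ts$reward_probability[ts$cue == "X"] == 1))
  expect_true(all(ts$reward_probability[ts$cue == "Y"] == 0))

  nd <- make_task("no_discr")$contingency
  expect_true(all(nd$reward_probability == 0.5))
  nd_red <- make_task("no_discr", "reduced")$contingency
  expect_true(all(nd_red$reward_probability == 0.25))

  expect_error(make_task("foo"), "unknown task_name")
})

test_that("schedules have exact trial-type counts under both phases", {
  for (seed in 1:3) {
    sch <- generate_schedule(make_task("ctx_dep_o1"), seed = seed)
    counts <- table(sch$trials$context, sch$trials$cue)
    expect_true(all(counts == 20))
  }
  red <- generate_schedule(make_task("ctx_dep_o1", "reduced"), seed = 4)
  tr <- red$trials
  cnt <- function(ctx, cue) sum(tr$context == ctx & tr$cue == cue)
  expect_equal(cnt("LIGHT", "X"), 10)  # rewarded
  expect_equal(cnt("DARK", "X"), 30)
  expect_equal(cnt("LIGHT", "Y"), 30)
  expect_equal(cnt("DARK", "Y"), 10)  # rewarded
  expect_equal(sum(tr$rewarded), 20)  # 1/4 of all trials

  red_s <- generate_schedule(make_task("simple", "reduced"), seed = 5)
  expect_equal(sum(red_s$trials$rewarded), 20)
})

test_that("phases alternate every 2 min and span the 80-min session", {
  sch <- generate_schedule(make_task("no_discr"), seed = 7)
  ph <- sch$phases
  expect_equal(nrow(ph), 40)
  expect_true(all(ph$end_s - ph$start_s == 120))
  expect_equal(sum(ph$end_s - ph$start_s), 4800)
  expect_true(all(ph$context[-1] != ph$context[-40]))
})

test_that("cue windows fit inside phases and ITIs stay rectangular", {
  for (task in c("ctx_dep_o1", "simple")) {
    for (phase in c("standard", "reduced")) {
      sch <- generate_schedule(make_task(task, phase),
                               seed = 11 + nchar(task))
      tr <- sch$trials
      expect_true(all(tr$onset_s >= sch$phases$start_s[tr$phase]))
      expect_true(all(tr$onset_s + tr$duration_s <=
                        sch$phases$end_s[tr$phase]))
      iti <- tr$onset_s - c(0, head(tr$onset_s + tr$duration_s, -1))
      expect_true(all(iti >= 30 - 1e-9 & iti <= 70 + 1e-9))
      expect_equal(sum(!duplicated(tr$phase)), 40)  # 2 trials/phase
    }
  }
})

test_that("ITI draws are uniform with mean 50 s", {
  x <- draw_iti(1e4, seed = 42)
  expect_true(all(x >= 30 & x <= 70))
  expect_lt(abs(mean(x) - 50), 0.5)
})

test_that("the second cue of a phase is independent of the first", {
  # balanced (standard) phases: the pair-type allocation makes the
  # conditional and marginal second-slot probabilities exactly equal
  first <- character(0); second <- character(0)
  for (s in 1:125) {
    sch <- generate_schedule(make_task("ctx_dep_o1"), seed = 1000 + s)
    cue <- sch$trials$cue
    first <- c(first, cue[seq(1, 79, 2)])
    second <- c(second, cue[seq(2, 80, 2)])
  }
  expect_gte(length(first), 5000)
  p_cond <- mean(second[first == "X"] == "X")
  p_marg <- mean(second == "X")
  expect_equal(p_cond, p_marg, tolerance = 1e-12)

  # reduced phases use pool sampling: within a context, only the small
  # finite-pool (hypergeometric) dependence remains
  first <- character(0); second <- character(0); ctx <- character(0)
  for (s in 1:50) {
    sch <- generate_schedule(make_task("ctx_dep_o1", "reduced"),
                             seed = 2000 + s)
    cue <- sch$trials$cue
    first <- c(first, cue[seq(1, 79, 2)])
    second <- c(second, cue[seq(2, 80, 2)])
    ctx <- c(ctx, sch$trials$context[seq(1, 79, 2)])
  }
  in_light <- ctx == "LIGHT"
  expect_lt(abs(mean(second[in_light & first == "X"] == "X") -
                  mean(second[in_light] == "X")), 0.05)
})

test_that("rewards follow the contingency cells", {
  sch <- generate_schedule(make_task("ctx_dep_o1"), seed = 3)
  tr <- sch$trials
  expect_true(all(tr$rewarded == ((tr$context == "LIGHT" & tr$cue == "X") |
                                    (tr$context == "DARK" & tr$cue == "Y"))))
  expect_true(all(tr$outcome_id[tr$rewarded] == "O1"))
  expect_true(all(tr$outcome_id[!tr$rewarded] == "none"))

  nd <- generate_schedule(make_task("no_discr"), seed = 3)
  expect_gt(sum(nd$trials$rewarded), 20)  # ~40 at p = 0.5
  expect_lt(sum(nd$trials$rewarded), 60)
})
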