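test_that("time in port is exact interval arithmetic", {
  log <- fixture_log(tibble::tibble(entry_s = 105, exit_s = 110))
  expect_equal(time_in_port(log, c(105, 110)), 1)        # full window
  log2 <- fixture_log(tibble::tibble(entry_s = 106, exit_s = 108.5))
  expect_equal(time_in_port(log2, c(105, 110)), 0.5)     # 2.5 / 5 s
  expect_equal(time_in_port(log2, c(200, 205)), 0)
  expect_error(time_in_port(log2, c(110, 105)), "window length")
})

test_that("time in port is invariant to splitting occupancy intervals", {
  whole <- fixture_log(tibble::tibble(entry_s = 100, exit_s = 120))
  split <- fixture_log(tibble::tibble(entry_s = c(100, 107, 113),
                                      exit_s = c(107, 113, 120)))
  for (w in list(c(99, 121), c(105, 110), c(100, 107))) {
    expect_equal(time_in_port(split, w), time_in_port(whole, w))
  }
})

test_that("interval overlap agrees with a 1-ms sampling oracle", {
  set.seed(5)
  sch <- fixture_schedule()
  for (i in 1:25) {
    starts <- sort(runif(8, 0, 4700))
    occ <- tibble::tibble(entry_s = starts,
                          exit_s = starts + runif(8, 0.05, 8))
    occ <- occ[c(TRUE, occ$entry_s[-1] > occ$exit_s[-8] + 0.01), ]
    log <- fixture_log(occ)
    w0 <- runif(1, 0, 4790)
    w <- c(w0, w0 + 5)
    expect_lt(abs(time_in_port(log, w) - grid_time_in_port(occ, w)),
              0.001)
  }
})

test_that("response detection covers entries and onset occupancy", {
  sch <- fixture_schedule()
  on <- sch$trials$onset_s[1]
  entry_during <- render_events(sch, tibble::tibble(entry_s = on + 1,
                                                    exit_s = on + 3))
  expect_true(response_probability(entry_during, on))
  no_events <- render_events(sch, NULL)
  expect_false(response_probability(no_events, on))
  # already in port at onset: counted by default, not with the toggle
  spanning <- render_events(sch, tibble::tibble(entry_s = on - 2,
                                                exit_s = on + 2))
  expect_true(response_probability(spanning, on))
  expect_false(response_probability(spanning, on,
                                    include_onset_occupancy = FALSE))
})

test_that("discrimination ratio follows its definition and edge cases", {
  expect_equal(discrimination_ratio(1.5, 1.0), 0.6)
  expect_equal(discrimination_ratio(2, 2), 0.5)
  expect_equal(discrimination_ratio(3, 0), 1.0)
  expect_true(is.na(discrimination_ratio(0, 0)))
  expect_error(discrimination_ratio(-1, 2), "non-negative")
  # scale invariance and monotonicity in non-rewarded responding
  expect_equal(discrimination_ratio(0.3 * 7, 0.2 * 7),
               discrimination_ratio(0.3, 0.2))
  r <- discrimination_ratio(rep(2, 50), seq(0.1, 5, length.out = 50))
  expect_true(all(diff(r) < 0))
})

test_that("trial metrics and session summaries aggregate correctly", {
  sch <- fixture_schedule("ctx_dep_o1", seed = 21)
  tr <- sch$trials
  # occupy the full last 5 s of every rewarded cue, nothing else
  occ <- tibble::tibble(entry_s = tr$onset_s[tr$rewarded] + 5,
                        exit_s = tr$onset_s[tr$rewarded] + 10)
  log <- render_events(sch, occ)
  tm <- trial_metrics(log)
  expect_true(all(tm$time_in_port_pct[tm$rewarded] == 100))
  expect_true(all(tm$time_in_port_pct[!tm$rewarded] == 0))
  expect_true(all(tm$time_in_port_pct >= 0 & tm$time_in_port_pct <= 100))
  ss <- session_summary(tm, 4)
  expect_equal(ss$session_index, 4L)
  expect_equal(ss$t_rew, 100)
  expect_equal(ss$t_nonrew, 0)
  expect_equal(ss$discrimination_ratio, 1)
  expect_equal(ss$tip_light_x, 100)
  expect_equal(ss$tip_dark_x, 0)
  expect_equal(ss$p_resp_rew, 1)
})

test_that("session binning uses non-overlapping four-session bins", {
  tl <- tibble::tibble(session_index = 1:72,
                       discrimination_ratio = seq(0.5, 0.85,
                                                  length.out = 72))
  b <- bin_sessions(tl)
  expect_equal(nrow(b), 18)
  expect_true(all(b$n_sessions == 4))
  expect_false(any(b$partial))
  expect_equal(b$discrimination_ratio[1],
               mean(tl$discrimination_ratio[1:4]))
  # bin size 1 is the identity; constant input gives constant bins
  b1 <- bin_sessions(tl, 1)
  expect_equal(b1$discrimination_ratio, tl$discrimination_ratio)
  const <- tibble::tibble(session_index = 1:8, discrimination_ratio = 0.7)
  expect_true(all(bin_sessions(const)$discrimination_ratio == 0.7))
  # trailing partial bin is averaged and flagged
  b2 <- bin_sessions(tl[1:10, ])
  expect_equal(nrow(b2), 3)
  expect_true(b2$partial[3])
  expect_equal(b2$n_sessions[3], 2)
})
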