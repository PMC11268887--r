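# Shared fixtures, built in code at test time.

# a small deterministic schedule/log used by the metrics tests
fixture_schedule <- function(task = "simple", phase = "standard",
                             seed = 101) {
  generate_schedule(make_task(task, phase), seed = seed)
}

fixture_log <- function(occupancy = NULL, task = "simple", seed = 101,
                        sex = "M") {
  render_events(fixture_schedule(task, seed = seed), occupancy, sex = sex)
}

# hand-built subject timeline with explicit per-cue cell means
manual_timeline <- function(light_x, dark_x, dark_y, light_y) {
  n <- length(light_x)
  tibble::tibble(
    session_index = seq_len(n),
    tip_light_x = light_x, tip_dark_x = dark_x,
    tip_dark_y = dark_y, tip_light_y = light_y,
    t_rew = (light_x + dark_y) / 2, t_nonrew = (dark_x + light_y) / 2,
    discrimination_ratio = discrimination_ratio(
      (light_x + dark_y) / 2, (dark_x + light_y) / 2))
}

# 1-ms grid-sampling oracle for time in port
grid_time_in_port <- function(occupancy, window, step = 0.001) {
  pts <- seq(window[1] + step / 2, window[2], by = step)
  inside <- rep(FALSE, length(pts))
  for (i in seq_len(nrow(occupancy))) {
    inside <- inside | (pts >= occupancy$entry_s[i] &
                          pts < occupancy$exit_s[i])
  }
  mean(inside)
}

# synthetic binned acquisition table (ratio scale) for model calibration
# checks: shared logistic curve, random subject intercepts, iid noise, and
# an optional sex-dependent slope divergence.
synth_binned <- function(n_per_sex = 15, n_bins = 8, sex_slope = 0,
                         re_sd = 0.03, noise_sd = 0.04) {
  subjects <- tibble::tibble(
    subject_id = sprintf("s%02d", seq_len(2 * n_per_sex)),
    sex = rep(c("M", "F"), each = n_per_sex),
    re = rnorm(2 * n_per_sex, 0, re_sd))
  tidyr::expand_grid(subjects, bin = seq_len(n_bins)) |>
    dplyr::mutate(
      discrimination_ratio = 0.5 +
        0.3 * stats::plogis(0.8 * (bin - n_bins / 2)) +
        sex_slope * (sex == "M") * bin / n_bins +
        re + rnorm(dplyr::n(), 0, noise_sd))
}
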