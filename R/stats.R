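# Group-level aggregation and hypothesis-test orchestration. Model fitting
# is delegated to standard routines (stats::aov, nlme::lme); all tests are
# two-tailed at alpha = 0.05 with Bonferroni-corrected follow-ups.

#' Bonferroni-corrected alpha
#'
#' @param m Number of comparisons.
#' @param alpha Familywise type I error rate, default 0.05.
#' @return `alpha / m`.
#' @export
bonferroni_alpha <- function(m, alpha = 0.05) {
  stopifnot(m >= 1)
  alpha / m
}

#' Acute-stress effect on discrimination performance
#'
#' For each subject: baseline = mean discrimination ratio over the
#' `baseline_window` sessions immediately preceding the stress session,
#' stress = the ratio on the stress session, difference = stress -
#' baseline (a stress-induced disruption appears as a negative
#' difference). Within/between tests are a repeated-measures ANOVA
#' (Stress within, Sex between, via `stats::aov`) and per-sex paired
#' t-tests with Bonferroni correction.
#'
#' @param summaries Session summaries with `subject_id`, `sex`,
#'   `session_index`, `discrimination_ratio` (one task at a time).
#' @param stress_session Index of the stress session; every subject must
#'   have it and at least `baseline_window` preceding sessions.
#' @param baseline_window Number of pre-stress sessions averaged into the
#'   baseline, default 3.
#' @return List: `table` (per-subject baseline, stress, difference),
#'   `anova` (summary of the Sex x Stress RM-ANOVA), `sex_tests` (tibble
#'   of per-sex paired t-tests, Bonferroni-adjusted).
#' @export
stress_effect <- function(summaries, stress_session, baseline_window = 3) {
  base_sessions <- stress_session - seq_len(baseline_window)
  if (any(base_sessions < 1)) stop("baseline sessions precede session 1")
  have <- summaries |>
    group_by(.data$subject_id) |>
    summarize(has_stress = any(.data$session_index == stress_session),
              has_base = all(base_sessions %in% .data$session_index),
              .groups = "drop")
  if (!all(have$has_stress)) {
    stop("missing stress session for subject(s): ",
         paste(have$subject_id[!have$has_stress], collapse = ", "))
  }
  if (!all(have$has_base)) {
    stop("missing baseline session(s) for subject(s): ",
         paste(have$subject_id[!have$has_base], collapse = ", "))
  }

  tab <- summaries |>
    group_by(.data$subject_id, .data$sex) |>
    summarize(
      baseline = mean(.data$discrimination_ratio[
        .data$session_index %in% base_sessions]),
      stress = .data$discrimination_ratio[
        .data$session_index == stress_session],
      .groups = "drop") |>
    mutate(difference = .data$stress - .data$baseline)

  long <- tab |>
    tidyr::pivot_longer(c("baseline", "stress"), names_to = "phase",
                        values_to = "ratio") |>
    mutate(phase = factor(.data$phase, levels = c("baseline", "stress")),
           sex = factor(.data$sex), subject_id = factor(.data$subject_id))
  fit <- aov(ratio ~ sex * phase + Error(subject_id / phase), data = long)

  safe_t <- function(x) {
    tryCatch(t.test(x), error = function(e) list(statistic = NA_real_,
                                                 p.value = NA_real_))
  }
  sex_tests <- tab |>
    group_by(.data$sex) |>
    summarize(
      n = dplyr::n(),
      mean_difference = mean(.data$difference),
      sem_difference = sd(.data$difference) / sqrt(dplyr::n()),
      t = unname(safe_t(.data$difference)$statistic),
      p = safe_t(.data$difference)$p.value,
      .groups = "drop") |>
    mutate(p_adj = p.adjust(.data$p, method = "bonferroni"))

  list(table = tab, anova = summary(fit), sex_tests = sex_tests)
}

# candidate within-subject covariance structures for the acquisition model
lmm_correlation <- function(structure) {
  switch(structure,
    cs = nlme::corCompSymm(form = ~ 1 | subject_id),
    ar1 = nlme::corAR1(form = ~ bin | subject_id),
    un = nlme::corSymm(form = ~ bin | subject_id),
    stop("unknown covariance structure: ", structure))
}

#' Longitudinal acquisition model
#'
#' Thin orchestration over `nlme::lme`: fits the binned acquisition data
#' with Sex, Session-bin (factor) and their interaction as fixed effects,
#' a random subject intercept, and candidate within-subject covariance
#' structures -- compound symmetry (`"cs"`), first-order autoregressive
#' (`"ar1"`), unstructured (`"un"`, `corSymm` with per-bin variances) --
#' estimated by REML and selected by the lower AIC. Structures whose fit
#' fails to converge (or is singular) are flagged and skipped.
#'
#' @param binned Binned timeline ([bin_sessions()] output) with
#'   `subject_id`, `sex`, `bin` and the response column.
#' @param response Name of the response column, default
#'   `"discrimination_ratio"`.
#' @param candidates Covariance structures to try, in order.
#' @return List: `model` (the selected `lme` fit), `structure` (its name),
#'   `aic` (named vector, `NA` for failed fits), `anova` (marginal F
#'   table), `failed` (names of structures that did not fit).
#' @export
acquisition_model <- function(binned,
                              response = "discrimination_ratio",
                              candidates = c("cs", "ar1", "un")) {
  stopifnot(all(c("subject_id", "sex", "bin", response) %in%
                  names(binned)))
  dat <- binned |>
    transmute(subject_id = factor(.data$subject_id),
              sex = factor(.data$sex),
              bin = as.integer(.data$bin),
              bin_f = factor(.data$bin),
              y = .data[[response]]) |>
    filter(!is.na(.data$y)) |>
    as.data.frame()
  if (sd(dat$y) < .Machine$double.eps^0.5) {
    warning("response has (near) zero variance; model degenerate")
  }

  fits <- list()
  aic <- setNames(rep(NA_real_, length(candidates)), candidates)
  for (cand in candidates) {
    fit <- tryCatch({
      args <- list(
        fixed = y ~ sex * bin_f, random = ~ 1 | subject_id,
        correlation = lmm_correlation(cand),
        weights = if (cand == "un") nlme::varIdent(form = ~ 1 | bin_f),
        data = dat, method = "REML",
        control = nlme::lmeControl(maxIter = 100, msMaxIter = 100,
                                   returnObject = FALSE))
      do.call(nlme::lme, args[!vapply(args, is.null, logical(1))])
    }, error = function(e) NULL)
    fits[[cand]] <- fit
    if (!is.null(fit)) aic[cand] <- AIC(fit)
  }
  if (all(is.na(aic))) stop("no candidate covariance structure converged")
  best <- names(which.min(aic))
  list(model = fits[[best]], structure = best, aic = aic,
       anova = anova(fits[[best]], type = "marginal"),
       failed = names(aic)[is.na(aic)])
}

#' Sex x prior-reward RM-ANOVA on history strata
#'
#' Group-level test for [history_effects()]: repeated-measures ANOVA with
#' prior outcome (R/NR) within subjects and sex between, on the
#' subject-level stratum means of one measure and current trial type,
#' plus Bonferroni-corrected between-sex t-tests of the difference scores.
#'
#' @param effects Output of [history_effects()].
#' @param measure `"p_response"` or `"time_in_port_pct"`.
#' @param current `"non-rewarded"` (default) or `"rewarded"`.
#' @return List: `anova` (summary of the aov fit), `sex_test` (`htest`,
#'   Welch t of the male vs female difference scores, or `NULL` when a sex
#'   is absent).
#' @export
prior_reward_anova <- function(effects,
                               measure = c("p_response",
                                           "time_in_port_pct"),
                               current = c("non-rewarded", "rewarded")) {
  measure <- match.arg(measure)
  current <- match.arg(current)
  strata <- effects$strata |>
    filter(.data$current_type == current) |>
    mutate(y = .data[[measure]], sex = factor(.data$sex),
           prior_outcome = factor(.data$prior_outcome),
           subject_id = factor(.data$subject_id))
  fit <- aov(y ~ sex * prior_outcome + Error(subject_id / prior_outcome),
             data = strata)
  diff_col <- if (measure == "p_response") "diff_p_response"
    else "diff_time_in_port"
  ds <- filter(effects$diff_scores, .data$current_type == current)
  sex_test <- if (length(unique(ds$sex)) == 2) {
    t.test(ds[[diff_col]] ~ ds$sex)
  }
  list(anova = summary(fit), sex_test = sex_test)
}
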