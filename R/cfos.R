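# c-Fos density computation and group comparison on (synthetic) counts.

FOS_REGIONS <- c("mOFC", "vOFC", "lOFC", "M1J", "S1J")

#' c-Fos density for one subject and region
#'
#' Each section contributes `count / area` (cells/mm^2); the subject value
#' is the mean over its 2-4 sections (per-section density then mean, the
#' default) or, alternatively, pooled counts over pooled area.
#'
#' @param counts c-Fos-positive cell counts per section (non-negative).
#' @param area_mm2 Section areas in mm^2 (strictly positive).
#' @param method `"per_section"` (default) or `"pooled"`.
#' @return Density in cells/mm^2.
#' @examples
#' fos_density(200, 2)          # 100
#' fos_density(c(100, 300), c(1, 1))  # 200
#' @export
fos_density <- function(counts, area_mm2,
                        method = c("per_section", "pooled")) {
  method <- match.arg(method)
  if (length(counts) != length(area_mm2)) {
    stop("counts and area_mm2 must have equal length")
  }
  if (any(area_mm2 <= 0)) stop("section areas must be > 0")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (method == "per_section") mean(counts / area_mm2)
  else sum(counts) / sum(area_mm2)
}

#' Default region x sex x task mean densities
#'
#' Synthetic effect specification emulating the structure of the c-Fos
#' comparison: behavioral testing elevates all regions far above the
#' homecage baseline, and (by default) females trained on the
#' context-dependent single-outcome task show a selective elevation in the
#' three OFC subregions relative to males, with no sex difference in the
#' jaw motor/somatosensory control regions or in any other task.
#'
#' @param base_density Named per-region baseline densities (cells/mm^2)
#'   under behavioral testing.
#' @param female_ofc_gain Multiplier applied to female OFC rows of
#'   `ofc_task` (default 1.6).
#' @param ofc_task Task carrying the female OFC elevation.
#' @param homecage_density Homecage-control density (all regions).
#' @return Tibble: `task`, `sex`, `region`, `mean_density` (includes
#'   `task = "homecage"` rows).
#' @export
default_fos_effects <- function(base_density = c(mOFC = 150, vOFC = 170,
                                                 lOFC = 190, M1J = 260,
                                                 S1J = 240),
                                female_ofc_gain = 1.6,
                                ofc_task = "ctx_dep_o1",
                                homecage_density = 25) {
  stopifnot(setequal(names(base_density), FOS_REGIONS))
  eff <- tidyr::expand_grid(task = TASK_NAMES, sex = c("M", "F"),
                            region = FOS_REGIONS) |>
    mutate(mean_density = unname(base_density[.data$region]) *
             ifelse(.data$sex == "F" & .data$task == ofc_task &
                      grepl("OFC$", .data$region), female_ofc_gain, 1))
  bind_rows(eff,
            tidyr::expand_grid(task = "homecage", sex = c("M", "F"),
                               region = FOS_REGIONS) |>
              mutate(mean_density = homecage_density))
}

#' Synthesize a c-Fos count table
#'
#' Negative-binomial section counts (overdispersion typical of cell
#' counts) around the programmed region x sex x task mean densities, with
#' 2-4 bilateral sections of variable area per animal. Deterministic given
#' `seed`.
#'
#' @param effects Effect table from [default_fos_effects()] (columns
#'   `task`, `sex`, `region`, `mean_density`).
#' @param n_per_group Animals per task x sex cell.
#' @param n_homecage Homecage-control animals (sexes alternating).
#' @param dispersion Negative-binomial size parameter (> 0).
#' @param seed Optional seed (local to the call).
#' @return Tibble: `subject_id`, `sex`, `task`, `region`, `section`,
#'   `count`, `area_mm2`.
#' @export
synth_fos_counts <- function(effects = default_fos_effects(),
                             n_per_group = 8, n_homecage = 5,
                             dispersion = 10, seed = NULL) {
  if (!is.numeric(dispersion) || dispersion <= 0) {
    stop("dispersion must be > 0")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  groups <- distinct(effects, .data$task, .data$sex)
  rows <- list()
  sid <- 0
  for (g in seq_len(nrow(groups))) {
    tk <- groups$task[g]; sx <- groups$sex[g]
    n_sub <- if (tk == "homecage") {
      if (sx == "M") ceiling(n_homecage / 2) else floor(n_homecage / 2)
    } else n_per_group
    for (i in seq_len(n_sub)) {
      sid <- sid + 1
      n_sections <- sample(2:4, 1)
      for (reg in FOS_REGIONS) {
        mu <- effects$mean_density[effects$task == tk &
                                     effects$sex == sx &
                                     effects$region == reg]
        area <- runif(n_sections, 0.7, 1.3)
        rows[[length(rows) + 1]] <- tibble(
          subject_id = sprintf("fos%03d", sid), sex = sx, task = tk,
          region = reg, section = seq_len(n_sections),
          count = rnbinom(n_sections, mu = mu * area, size = dispersion),
          area_mm2 = area)
      }
    }
  }
  bind_rows(rows)
}

#' Per-subject density table
#'
#' @param counts Count table in the layout of [synth_fos_counts()].
#' @param method Passed to [fos_density()].
#' @return Tibble: `subject_id`, `sex`, `task`, `region`, `density`.
#' @export
fos_density_table <- function(counts, method = "per_section") {
  counts |>
    group_by(.data$subject_id, .data$sex, .data$task, .data$region) |>
    summarize(density = fos_density(.data$count, .data$area_mm2,
                                    method = method),
              .groups = "drop")
}

#' RM-ANOVA and planned contrasts on c-Fos densities
#'
#' Repeated-measures ANOVA (Region within subjects; Task and Sex between)
#' on per-subject densities via `car::Anova` on a multivariate fit, which
#' reports Mauchly sphericity tests and Greenhouse-Geisser-corrected
#' p-values for the 5-level Region factor. Followed by planned
#' male-vs-female Welch t contrasts within every task x region cell,
#' Bonferroni-corrected over all contrasts. Homecage rows are shown-only
#' controls and are excluded from the analysis input before fitting.
#'
#' @param densities Output of [fos_density_table()].
#' @param alpha Familywise error rate for flagging contrasts.
#' @return List: `anova` (univariate RM-ANOVA summary with sphericity
#'   corrections), `contrasts` (tibble with per-cell means, t, raw and
#'   Bonferroni-adjusted p, `significant` flag), `n_homecage_excluded`,
#'   `data` (the analysis input).
#' @export
region_anova <- function(densities, alpha = 0.05) {
  n_home <- sum(densities$task == "homecage")
  dat <- densities |>
    filter(.data$task != "homecage") |>
    mutate(task = factor(.data$task), sex = factor(.data$sex),
           region = factor(.data$region, levels = FOS_REGIONS),
           subject_id = factor(.data$subject_id))
  complete <- dat |>
    count(.data$subject_id) |>
    filter(.data$n < length(FOS_REGIONS))
  if (nrow(complete) > 0) {
    warning("subjects with missing regions flagged and dropped: ",
            paste(complete$subject_id, collapse = ", "))
    dat <- filter(dat, !.data$subject_id %in% complete$subject_id)
  }
  wide <- tidyr::pivot_wider(dat,
                             id_cols = c("subject_id", "task", "sex"),
                             names_from = "region",
                             values_from = "density")
  resp <- as.matrix(wide[FOS_REGIONS])
  mfit <- stats::lm(resp ~ task * sex, data = wide)
  av <- car::Anova(mfit,
                   idata = data.frame(region = factor(FOS_REGIONS,
                                                      levels = FOS_REGIONS)),
                   idesign = ~ region, type = 3)
  anova_summary <- withCallingHandlers(
    summary(av, multivariate = FALSE),
    warning = function(w) {
      # Huynh-Feldt epsilon > 1 is routinely clamped to 1
      if (grepl("HF eps", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })

  contrasts <- dat |>
    group_by(.data$task, .data$region) |>
    group_modify(function(d, key) {
      tt <- t.test(density ~ sex, data = d)
      mm <- tapply(d$density, d$sex, mean)
      tibble(mean_M = mm[["M"]], mean_F = mm[["F"]],
             t = unname(tt$statistic), p = tt$p.value)
    }) |>
    ungroup() |>
    mutate(p_adj = p.adjust(.data$p, method = "bonferroni"),
           significant = .data$p_adj < alpha)

  list(anova = anova_summary, contrasts = contrasts,
       n_homecage_excluded = n_home, data = dat)
}
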