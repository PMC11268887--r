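---
title: "Context-gated discrimination: models, generators, and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-gated discrimination: models, generators, and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctxgate)
```

# The preparation

`ctxgate` models a bidirectional occasion-setting experiment in rats. Two
10-s auditory cues (X, Y) are embedded in two alternating 2-min visual
contexts (LIGHT = flashing houselight, DARK = houselight off). In the
core task, `ctx_dep_o1`, the contingencies are LIGHT:X+ / DARK:X− /
LIGHT:Y− / DARK:Y+ with a single reward outcome. Each cue and each
context is followed by reward on exactly half the trials, so no additive
combination of cue and context associative strengths can predict reward;
the context must act hierarchically, gating which cue→outcome mapping is
in force. Three comparison tasks isolate that requirement: `simple` (X
always rewarded, Y never; the context is irrelevant), `no_discr` (both
cues rewarded with probability 0.5 everywhere; discrimination is
impossible by design), and `ctx_dep_o1o2` (the same reward cells as
`ctx_dep_o1` but with different outcomes in the two contexts, which
reopens a non-hierarchical, summation-based route to context-sensitive
behavior).

A session is 80 min: 40 context phases of 120 s, strictly alternating,
with two cue trials per phase (80 trials). Under the standard schedule
each (context, cue) combination occurs 20 times per session. Under the
`reduced` schedule — used from session 36 of `ctx_dep_o1` and as the
pre-stress equalization for all tasks — rewarded trial types drop to 10
and non-rewarded rise to 30, so rewarded trials are a quarter of all
trials (for `no_discr` the cell probability drops to 0.25 instead).

# Protocol generation choices

**Cue assignment.** The two cue slots of a phase are meant to be
"semi-random": the same cue may repeat within a phase, and the first
slot's identity should carry no information about the second. With
balanced counts (20 X and 20 Y per context), drawing slots from a shared
label pool without replacement leaves a small hypergeometric footprint
(P(second = X | first = X) = 19/39, not 1/2). We instead allocate exactly
one quarter of each context's phases to each ordered pair XX, XY, YX, YY
and randomize which phase gets which pair. This yields exact trial-type
counts *and* exact pairwise independence; the test suite checks the
conditional and marginal probabilities agree to machine precision. Under
the reduced 10/30 split no integer allocation can make the slots exactly
independent, so there we fall back to the shuffled-pool scheme and accept
the small finite-pool dependence (about 0.02), which is what "exact
counts with exchangeable slots" permits.

**Intertrial intervals.** ITIs are measured from cue offset to the next
cue onset and drawn from a rectangular distribution on [30, 70] s (mean
50 s, half-width 20 s). Cue windows must lie entirely within their
context phase, and the first slot of a phase is additionally capped at
phase start + 70 s so the second slot can always fit. Draws violating
these bounds are resampled a bounded number of times, then placed by a
conditional-uniform draw on the feasible range. The raw generator
(`draw_iti()`) is exactly uniform; realized intervals are mildly
truncated near phase boundaries but always stay within [30, 70] s.

**Other conventions.** Time is seconds from session start, intervals are
half-open `[start, end)`. The reward event is placed at cue offset (the
3-s physical delivery is represented by the single event). Outcome
identities (`O1`, `O2`) are labels only; the pellet/chocolate-milk
counterbalancing has no behavioral consequence in the simulator. Trial
indices are 1-based.

# The two learning agents

No learning equations are implied by the task description itself; the
agents implement the textbook delta rule (Rescorla–Wagner) as the
simplest instantiation of each architecture:

* **Elemental (summation)**: prediction = V(cue) + V(context); both
  active elements are updated by α·(reward − prediction). With noise-free
  expected updates this is batch gradient descent on the squared error
  over the contingency table, so it converges to the additive
  least-squares fit. On the XOR-structured `ctx_dep_o1` table that fixed
  point predicts 0.5 in every cell — the agent cannot discriminate, and
  its asymptotic discrimination ratio is exactly 0.5. A test
  cross-checks the fixed point against an independent `lm()`
  least-squares fit of the additive model.
* **Hierarchical (gated)**: one weight per (context, cue) configuration;
  only the active configuration is updated. Every configuration of the
  deterministic tasks has a fixed outcome, so the gated weights converge
  to the cell reward probabilities and the agent solves `ctx_dep_o1`
  (ratio → 1). Setting `gating = FALSE` collapses the weights onto the
  cue alone, which reduces the agent to the cue-only elemental learner —
  asserted exactly, trace for trace, in the tests.

With differential outcomes (`ctx_dep_o1o2`) each outcome has its own
weight vector. Summing outcome-specific predictions is degenerate: the
raw sums are identical in all four cells (ratio 0.5) and rectified sums
land exactly on the 0.6 boundary. We therefore map behavior to the
*maximum* over outcome-specific predictions — responding is driven by the
most strongly predicted reward, and anticipation of either outcome
produces the same port approach. At the noise-free fixed point this
yields a ratio of 0.75: the summation agent benefits substantially from
differential outcomes without any hierarchical machinery, which is the
qualitative signature the task is designed to expose.

Predictions map to occupancy of the last-5-s scoring window through a
clipped linear gain (a logistic mapping would serve equally; only
monotonicity matters for the ratio).

# The parametric responder

The learning agents show *why* the tasks differ; the parametric responder
(`simulate_cohort()`) generates cohorts with the empirical structure the
analyses must recover, and is deliberately parametrized on the scales
those analyses report:

* The expected discrimination ratio follows
  r(s) = 0.5 + (r_max − 0.5)·logistic(k·(s − m)) with r_max = 0.85.
  Midpoints m are sex-specific for `ctx_dep_o1` (M = 30, F = 45
  sessions, between-subject SD 6) and sex-equal elsewhere (`simple` 10,
  `ctx_dep_o1o2` 17, `no_discr` never). The ordering and rough spacing —
  simple < dual-outcome < single-outcome context task, males earlier than
  females only in the single-outcome context task — reproduce the
  qualitative pattern of acquisition; the magnitudes are free parameters
  of the generator, not measured quantities.
* Rewarded-trial occupancy rises quickly (logistic, midpoint session 3)
  to 0.85 for both sexes; non-rewarded occupancy is derived from the
  ratio, O_nonrew = O_rew(1 − r)/r. Per trial the subject responds with
  probability O/0.9 and, when responding, occupies a Beta-distributed
  fraction (mean 0.9, concentration 30) of the last 5 s, entering the
  port accordingly; expected time in port therefore equals the
  programmed occupancy.
* **History effect**: on non-rewarded trials preceded by a rewarded
  trial, the response probability gets an additive bump — 0.10 for
  males, 0 for females in `ctx_dep_o1`, 0 elsewhere. Rewarded-trial
  responding is never perturbed. The bump acts only through the
  immediately preceding trial, so run-length strata beyond 1 carry no
  additional effect.
* **Stress**: on a designated session the expected ratio drops by 0.15
  for males and 0 for females in `ctx_dep_o1`, and by 0.08 for both
  sexes in `simple` and `ctx_dep_o1o2` (0 in `no_discr`).
* Brief exploratory port visits (probability 0.15 per trial, ending at
  least 50 ms before onset) populate the pre-cue measure without touching
  the cue-window metrics.

All generator draws run under a single seeded stream, so cohorts are
bit-reproducible. What the responder does **not** emulate: orienting
behavior, within-trial response latencies beyond the occupancy fraction,
estrous-cycle structure, motivational drift across a session, or any
coupling between a subject's history effect and its acquisition speed.
Passing recovery tests on these cohorts therefore demonstrates that the
pipeline measures what it claims on data with the programmed structure —
not that real rats have that structure.

# Measurement conventions

* The primary measure is the percentage of the **last 5 s** of the cue
  spent in the port (anticipatory behavior concentrates there); the 5 s
  before onset is computed but treated as descriptive. A full-cue window
  can be obtained through `time_in_port()` directly.
* "Responds during the cue" counts a port entry within the 10-s cue
  window *or* being in the port at onset (default), since sustained
  anticipatory occupancy is a response by any reasonable reading;
  `include_onset_occupancy = FALSE` gives the entry-events-only variant.
* The discrimination ratio uses per-session means of trial percentages
  (matching per-session acquisition curves), not pooled seconds; rewarded
  trials are defined by actual delivered reward, which coincides with the
  trial type in the deterministic tasks and keeps `no_discr` sessions
  interpretable (they hover at 0.5). A session with zero responding has
  an undefined ratio and propagates as missing, never as 0.5.
* Occupancy intervals are validated (sorted, non-overlapping); touching
  intervals are merged so port events strictly alternate, which also
  makes time-in-port exactly invariant to splitting an interval.

# Classification choices

A session passes for a cue when rewarded-cell time in port is ≥ 1.5 ×
the non-rewarded-cell time with some responding present (0 vs 0 does not
pass); this is algebraically identical to ratio ≥ 0.6 whenever total
responding is positive (tested exhaustively on a grid). The criterion is
≥ 4 of any 5 consecutive sessions. Two conventions required a decision:

* `criterion_session` is the **last session of the earliest qualifying
  window** — the first moment the evidence is complete.
* For context tasks both cues must pass **within the same windows** (the
  stricter, more literal reading of "for both cues");
  `joint_windows = FALSE` evaluates each cue in its own window and takes
  the later criterion session.

Sessions-to-criterion comparisons exclude non-discriminators, use the
Kruskal–Wallis omnibus, and follow up with Bonferroni-corrected pairwise
Wilcoxon rank-sum tests (the rank-based pairwise procedure available in
base R). Discriminator proportions use Pearson chi-square without
continuity correction by default (toggleable); a degenerate table with an
empty margin is reported as χ² = 0.

# Group statistics

Longitudinal acquisition curves are aggregated in four-session bins and
fitted with `nlme::lme` (REML): Sex × Bin fixed effects, a random subject
intercept, and candidate within-subject covariance structures — compound
symmetry, AR(1), and unstructured (general correlation with per-bin
variances) — selected by the lower AIC. Fits that fail to converge are
flagged and skipped. This operation is deliberately a thin orchestration
layer over standard mixed-model machinery.

The stress comparison takes each subject's baseline as the mean ratio
over the last three pre-stress sessions (configurable; the analysis
window is not pinned down by the protocol itself) and reports
stress − baseline difference scores (disruption is negative), a
Sex × Stress RM-ANOVA, and Bonferroni-corrected per-sex paired t-tests.
The two-level within factors (stress phase, prior outcome) satisfy
sphericity trivially; the five-level Region factor in the c-Fos analysis
is handled through `car::Anova`, which supplies Mauchly tests and
Greenhouse–Geisser-corrected p-values.

All tests are two-tailed at α = 0.05; pairwise follow-ups use Bonferroni
correction (α/m).

# c-Fos module

Densities are c-Fos-positive cells per mm², computed per section and then
averaged within subject (2–4 bilateral sections per animal); a pooled
counts-over-pooled-area variant is available. The synthetic count
generator draws negative-binomial section counts (overdispersion typical
of cell counting; dispersion configurable, default size 10) around
programmed region × sex × task mean densities, with OFC subregions around
150–190 cells/mm², jaw motor/somatosensory control regions around
240–260, homecage controls at 25, and a default 1.6× female elevation in
the OFC subregions of `ctx_dep_o1` only. Homecage rows are displayed-only
controls and are excluded from the inferential input (asserted in
tests). Planned male-vs-female contrasts run within every task × region
cell with Bonferroni correction over all 20 contrasts.

# Problem sizes and numerical notes

The test suite exercises the full pipeline at sizes chosen to make the
programmed effects statistically recoverable at desk scale: cohorts of
15 per sex over 72 sessions for acquisition-speed recovery, 10 stable
sessions (71–80) for history effects, a 5-session window around a
single stress session, 8 animals per group for c-Fos contrasts, and 200
replicates of 30-subject binned null cohorts for the type-I-error
calibration of the mixed model. Expected-update agent runs iterate to a
1e-8 weight-change tolerance (a few hundred sweeps at α = 0.1).
Floating-point boundary comparisons in the criterion rule are guarded at
1e-9.

# Known limitations

* The responder's acquisition curve is logistic by construction; real
  acquisition may be better described by gradual configural learning.
  This affects realism, not the correctness of the pipeline the package
  exists to test.
* Non-discriminators are excluded, not censored; no survival-analysis
  treatment of sessions to criterion is provided.
* The agents contain no attention, timing, or dopamine machinery and are
  not fitted to data.
* Image segmentation and counting criteria for c-Fos are out of scope;
  the module starts from count tables.
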