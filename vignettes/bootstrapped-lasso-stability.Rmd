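---
title: "Bootstrapped cross-validated LASSO stability selection for disfluency-connectivity association"
author: "fcLasso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrapped cross-validated LASSO stability selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcLasso)
```

## The problem

Adults who stutter produce three characteristic disfluency types —
repetitions of sounds or syllables, prolongations of sounds, and blocks
(stoppages of airflow or voicing). Individual symptom profiles vary
widely, and a long-standing hypothesis attributes that variation to
different weightings of two speech motor control subsystems: feedback
(FB) control, which monitors auditory/somatosensory input and issues
corrective commands, and feedforward (FF) control, which launches
pre-planned motor programs. The DIVA/GODIVA model family maps these
subsystems onto concrete cortico-subcortical circuits, which suggests a
testable question: do resting-state functional connectivity strengths
within these circuits predict how often a speaker produces each
disfluency type?

`fcLasso` implements the complete statistical pathway for that question:

1. **Behavioral rates.** Per speech sample, the rate of a disfluency
   type is `100 * count / total syllables`. A participant's rate is the
   unweighted mean of the per-sample percentages — each task
   (conversation, phone call, reading) counts equally, rather than
   pooling syllables, so a long conversation cannot drown out a short
   reading passage. Inter-rater reliability of the underlying counts is
   quantified with an intraclass correlation (below).
2. **Connectivity predictors.** For each subject and each ROI pair in a
   configurable connection list (58 pairs by default), the temporal
   Pearson correlation of the two ROI time series is Fisher-transformed
   (`z = atanh(r)`), giving a variance-stabilized subject-by-connection
   predictor matrix. A binary scanner-site code (1 = MGH, 0 = BU) is
   appended as the final predictor column.
3. **Inference engine.** For each disfluency type, subjects are
   resampled with replacement (predictor rows and outcomes jointly);
   on every resample a LASSO regression is fitted at the penalty chosen
   by K-fold cross-validation *on that resample*; raw coefficients are
   aggregated across resamples into means, SDs, normal-approximation
   confidence intervals with Bonferroni adjustment, and selection
   frequencies; and a "first drop" cutoff on the ranked frequencies
   isolates the stable set of connections.

## The model

For one outcome `y` (a disfluency percentage over `n` subjects) and the
predictor matrix `X` (`n x p`, Fisher-z connections plus the site
column), the core estimator minimizes

```
(1 / (2n)) * sum_i (y_i - b0 - x_i' b)^2  +  lambda * sum_j |b_j|
```

by cyclic coordinate descent with soft-thresholding, the standard
computation for this objective. Predictors are internally centered and
scaled to unit *population* variance (the `1/n` convention, consistent
with the `lambda_max = max_j |<x_j, y - ybar>| / n` formula that anchors
the path); coefficients are always reported on the original scale, and
the intercept is never penalized. Constant columns receive coefficient
exactly zero. The solver is implemented in C++ with warm starts along a
geometric path of `nLambda = 100` penalties from `lambda_max` down to
`lambda_max * lambdaMinRatio` (ratio `0.01` when `n < p`, else `1e-4`),
and an active-set strategy inside each penalty value.

**Cross-validation.** Folds (default 10, silently reduced to `n` when
`n < 10`, so the default cohort of 20 subjects gets 10 folds of 2) are
assigned by a seeded shuffle. The selected penalty minimizes the mean
validation MSE across folds; exact ties go to the larger penalty (the
sparser model). A fold whose training outcome is constant degenerates to
an intercept-only prediction but is still scored; only if every fold
degenerates is an error raised. Bootstrap duplicates may co-occur in
training and validation folds — no deduplication is applied, matching
the plain per-resample cross-validation the procedure describes.

**Paired bootstrap.** `B = 1000` resamples by default. Iteration `b`
derives its seed as `bitwXor(seed, b)` and uses it for both the
resampling and the fold shuffle, so any single iteration is reproducible
in isolation and the three outcome models see the *same* resampled
subjects. Degenerate resamples (constant outcome, possible under heavy
zero-inflation) contribute an all-zero coefficient row — zeros
participate in all aggregates — and are excluded from the average
optimal lambda; more than 50% degenerate draws aborts the run.

**Confidence intervals.** The interval for predictor `j` is
`mean_j ± z_{1-alpha'/2} * sd_j`, where `sd_j` is the SD of the `B` raw
coefficient draws (n−1 denominator) and `alpha' = (1 - level) / m` is
the Bonferroni-adjusted level. Because the procedure names bootstrap
*standard errors*, the normal-approximation form is the default;
percentile intervals are available via `bootstrapControl(ciType =
"percentile")`. Both `sd_j` and `sd_j / sqrt(B)` are reported, since
"SE" is ambiguous between the two conventions. A predictor is
significant when its interval excludes zero; the degenerate
never-selected predictor (mean 0, SD 0) has a zero-width interval at 0
and is not significant.

**Stability selection and the first-drop cutoff.** Predictors are
ranked by how often they were exactly nonzero across draws (ties broken
by `|mean coefficient|`, then label). Two published phrasings of the
cutoff — "first prominent drop" and "largest drop" — are reconciled as:
the cutoff index maximizes `count_i - count_{i+1}`, with ties to the
*smallest* index; the stable set is everything at or above the cutoff.
When all counts are equal there is no drop and the stable set is empty
(with a warning). A fixed selection-frequency threshold is available as
an alternative rule.

## Decisions where the procedure was underspecified

* **Bonferroni `m`**: "auto" counts the predictors within one outcome
  model — 58 connections plus the site column, `m = 59`. Whether the
  correction should instead span all three outcome models (`m = 177`) is
  not derivable from the procedure's description; a cross-model `m` can
  be supplied explicitly.
* **Site covariate**: penalized like any other predictor by default
  (`penalizeSite = TRUE`), since it enters the model as an ordinary
  column; an unpenalized option exists.
* **ICC variant**: "ICC" alone does not pin down a form. The default is
  ICC(2,1) — two-way random effects, absolute agreement, single
  measure — because multiple fixed raters scored the same items and
  systematic rater offsets should count against agreement. ICC(3,1)
  (consistency) is selectable. The estimate is computed from the two-way
  ANOVA mean squares directly.
* **Levene centering**: classic mean-centered deviations by default;
  the Brown–Forsythe median variant is selectable. The per-connection
  screen is multiplicity-unadjusted by default, mirroring its role as a
  descriptive diagnostic; its verdict is "normalization suggested" iff
  any connection is flagged after the chosen adjustment.
* **Correlation clipping**: `|r| >= 1 - 1e-7` is clipped to
  `±(1 - 1e-7)` before `atanh`, with a warning. Real BOLD series never
  reach `|r| = 1`; the clip only protects degenerate inputs.

## Numerical choices

Coordinate descent converges when the largest absolute coefficient
change in a sweep falls below `tol = 1e-7` (internal scale), bounded by
`maxIter = 1e5` sweeps; non-convergence is flagged on the fit. Solutions
satisfy the KKT conditions to well within `1e-5` and match closed-form
soft-thresholding on orthonormalized designs to `1e-8` (both are tested
properties). Warm starts along the path agree with cold starts to
`1e-6`. The two degenerate Levene branches are explicit: all deviations
zero gives statistic 0 with p = 1; zero within-group deviation spread
with differing group means gives statistic `Inf` with p = 0 (a
zero-denominator F with positive numerator — returning 0 there would
invert the test's meaning).

## What the synthetic generator emulates

`simulationControl()` encodes the study conditions the analysis assumes:
20 subjects, 58 connections in exchangeable-correlation blocks
(`rho = 0.3`, block size 6) with marginal Fisher-z mean 0.4 and SD 0.3 —
a typical resting-state scale — a 55% MGH site fraction with a +0.1
additive z-shift for MGH subjects, and outcomes
`y = max(0, mu + Z beta + eps)` with residual SD 1.0, 15% exact zeros
applied post-hoc, and target means near the observed cohort scale
(blocks ≈ 3.7%, repetitions ≈ 1.2%, prolongations ≈ 0.5%). The three
planted effects (+0.20, −0.18, +0.17 percent per z-unit, one per
correlation block) sit at the scale of published coefficient estimates.
Zero-inflation is applied as literal zeros rather than through a hurdle
model — it reproduces the observed data feature (participants with no
prolongations) without asserting a generative mechanism — and
truncation at zero keeps outcomes on the percent scale rather than
moving to a log link.

Three speech samples per subject are synthesized with syllable totals
uniform on 200–1100 and integer counts back-computed from the simulated
rates, so `aggregateRates()` reproduces the simulated outcome up to the
integer-rounding bound `100 / (2 * min total)`.

What the generator does *not* emulate: BOLD autocorrelation and
denoising residue in the time series (predictors are drawn directly at
the Fisher-z level), motion artifacts, site effects on the *outcome*,
SSI-4 scoring structure, or any dependency between disfluency types
beyond their shared connectivity signal. Passing tests on synthetic data
therefore validate the statistical machinery, not claims about real
cohorts.

An important property of these defaults is honest weakness: with
effects of ~0.2 on predictors of SD 0.3 against outcome noise of SD 1.0
(plus zero-inflation), the population correlation between the outcome
and a planted predictor is below 0.07. At `n = 20` this is far inside
the sampling noise, so the bootstrap-stability engine — correctly —
cannot reliably distinguish planted from null connections under these
conditions; the end-to-end recovery suite documents exactly that, and
the solver/CV layers are instead validated on configurations with
detectable signal. This mirrors the fundamental power limit of any
20-subject, 58-predictor design at published effect scales.

## Problem sizes used by the test and acceptance suites

Worked behavioral examples run on the bundled 20-participant cohort
table. Solver oracles use `n = 50, p = 5` orthonormalized designs and
100 random KKT instances. Cross-validation operating characteristics use
200 replicates at `n = 50, p = 10`. The bootstrap-stability recovery
suite runs 50 replicates (20 in the acceptance script) of the default
`n = 20, p = 58` conditions at `B = 200` — the same per-resample
procedure as the full `B = 1000` analysis, shortened only in the number
of draws; these sizes keep the full suite comfortably reproducible on a
single CPU. Levene rates use 2000 null and 500 alternative replicates.

## Known limitations

* The default 58-pair connection list is a plausibility reconstruction
  from the DIVA/GODIVA ROI vocabulary (the file header says so); real
  analyses should supply their own list.
* The bundled cohort table pools each participant's three samples, so
  per-task rates cannot be recovered from it; its two printing
  inconsistencies (cells whose printed percentage disagrees with the
  printed count/total by one unit in the last digit) are preserved
  as-is and documented in the acceptance suite.
* Normal-approximation CIs on LASSO coefficients are heuristic — the
  estimator's distribution has a point mass at zero, and the procedure
  provides no formal false-discovery control. The stable set should be
  read as "consistently selected under resampling", not as a tested
  hypothesis.
* Only two scanner sites are supported, by design; multi-site
  harmonization is out of scope.
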