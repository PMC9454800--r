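---
title: "Stability-tuned Lasso models of the platinum-free interval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-tuned Lasso models of the platinum-free interval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfilasso)
```

## The problem

In high-grade serous ovarian cancer, the platinum-free interval (PFI) — the
number of days between the last cycle of platinum chemotherapy and the
documented recurrence — is the strongest prognostic factor for overall
survival.  Ascites, the peritoneal fluid that accumulates in most stage
III/IV patients, is routinely drained and carries secreted proteins from
the whole tumor microenvironment, so it is an attractive liquid biopsy for
outcome prediction.  The quantitative setting is hostile, though: a
multiplexed bead-based immunoassay measures on the order of a hundred
analytes on a few dozen patients, the concentration distributions are
heavy-tailed (coefficients of variation above 100% are the norm, not the
exception), and a sizeable fraction of cells fall outside the assay's
quantifiable range.

`pfilasso` implements the full analysis chain for this setting: censored
immunoassay preprocessing, an L1-penalized (Lasso) regression of the
transformed PFI on the transformed analyte concentrations, penalty tuning
by leave-one-out cross-validation (LOOCV), and — the methodological core —
*stability tuning*: deliberately trading cross-validated accuracy for
fold-to-fold reproducibility of the selected features and their weights.

## Preprocessing model

An `assay_panel` carries concentrations (pg/mL), per-cell censoring flags,
per-analyte detection limits, top standards and dilution factors, cohort
labels (NACT, treated with neoadjuvant chemotherapy; PDS, primary
debulking surgery) and the PFI in days.  The chain, in fixed order:

1. **Detection filter.**  An analyte is kept iff it is detected (flag not
   below-limit; above-range cells count as detected, they are measurable
   signal) in at least 75% of patients.  Filtering precedes every other
   step and the retained set never changes afterwards.
2. **Censored-cell imputation.**  Below-limit cells become
   `0.5 * LOD * dilution`; above-range cells become `2 * ULOQ * dilution`.
   Imputation happens on the concentration scale, before any log — the
   half-detection-limit rule only makes sense for a concentration.  A cell
   recorded as a literal 0 with a "detected" flag is treated as
   below-limit first: a true zero concentration is an instrument artifact.
   Values exactly at a limit count as detectable (strict inequalities).
3. **log10**, then a per-analyte **Yeo-Johnson transform** fitted by
   maximum profile likelihood (λ searched on [-5, 5] by bounded scalar
   optimization, tolerance 1e-8 — bounds wide enough for any realistic
   skew and tight enough for reproducible tests), followed by
   standardization to zero mean and unit SD.  Standardization matters
   because the L1 penalty is scale-sensitive; it makes the penalty act
   uniformly across analytes.  The PFI gets its own fitted Yeo-Johnson.
   Every transform is kept so predictions can be inverted back to days.

Each step is strictly monotone, so patient rank order per analyte survives
the whole chain.  Transforms are fitted once on the full cohort: the
analyte transforms never see the outcome, and the PFI transform uses only
the marginal outcome distribution.  A strict mode
(`loocv(..., nested_transforms = TRUE)`) refits all transforms inside each
training fold for readers who want the fully nested discipline; it is off
by default and changes the estimates very little on well-behaved panels.

## Regression and tuning

The Lasso objective is fixed as

$$\frac{1}{2n}\sum_{i=1}^n\left(y_i - b - x_i^\top w\right)^2
  + \alpha\,\lVert w\rVert_1,$$

with an unpenalized intercept; any α reported by this package refers to
this 1/(2n) scaling.  The solver is cyclic coordinate descent on the
centered Gram system with active-set iteration and warm starts along
decreasing penalty paths; convergence is declared when the largest scaled
coefficient update in a sweep drops below 1e-9 (bounded by 3e5 sweeps).
Every fit satisfies the KKT conditions to 1e-6, which the test suite
checks directly — that certificate, not the solver's internals, is the
package's correctness contract.

Tuning evaluates the LOOCV RMSE, in days, at 201 log-uniformly spaced
penalties from 1e-5 to 1e5 (log spacing is the only sensible reading of a
grid spanning ten decades on standardized data).  Predictions are made on
the transformed scale and inverted to days before the error is computed,
so all reported RMSEs have clinical units:

$$\mathrm{RMSE} = \sqrt{\tfrac1n \sum_i
  (\mathrm{Observed\ PFI}_i - \mathrm{Pred\ PFI}_i)^2}.$$

The *optimal* penalty minimizes this curve; exact ties break toward the
larger (sparser) penalty.  `nested_loocv_rmse()` wraps the whole tuning in
an outer LOOCV loop and is the honest generalization estimate for the
tuned procedure; the non-nested curve is what the relaxation below
operates on.

**Numerical edge cases.**  `invert_transform()` is exact and raises when a
value falls outside the fitted transform's range (possible for λ < 0 or
λ > 2).  Model *predictions*, however, are inverted with a saturation
rule: the transformed prediction is clamped into ψ's attainable range and
the resulting days are capped at [0, 10 × the largest observed PFI].
Without this, grid tuning would abort whenever an overfit small-penalty
fold extrapolates beyond the transform's range; with it, such predictions
contribute a large but data-scaled error.  A constant analyte column
(unidentifiable λ) raises; a column constant within a training fold gets a
zero coefficient.

## Stability analysis and the error budget

For a model at penalty α, LOOCV leaves behind one coefficient vector per
fold.  Per feature, over *all* folds (zeros included):

$$\%CV = \frac{\mathrm{SD\ of\ fold\ coefficients}}
              {\lvert\mathrm{mean\ fold\ coefficient}\rvert}\times 100\%,$$

together with the inclusion count (folds with a nonzero coefficient).
The aggregate %CV averages the per-feature %CVs over features that are
nonzero in the full-cohort model and have a defined %CV (the statistic is
undefined when the fold mean is numerically zero, |mean| ≤ 1e-12, and `NA`
for an empty model).  The denominator uses the absolute mean so the
statistic is sign-free, and it is invariant to rescaling any feature's
fold coefficients.  One orientation note: the %CV is
SD/|mean| — the ratio of the fold-to-fold spread to the typical weight —
which is the only orientation under which "a high SD relative to the
average" yields a high %CV.

The error-budget relaxation formalizes "allow a tolerable error, gain
stability": given a budget (default 20 days — on the scale of clinical
forecasting horizons, and small enough that almost no patient's PFI is
shorter), `relax_alpha()` returns the **largest** grid penalty whose LOOCV
RMSE stays within the budget.  If no penalty qualifies, it falls back to
the optimal penalty and flags the budget infeasible.  `compare_models()`
then reports what the relaxation did to the support (shared, dropped,
added features), the coefficient signs on the shared support, and the
RMSE/%CV deltas.

## Cross-cohort prediction

The two treatment cohorts are modeled separately (their PFI distributions
differ systematically).  `cross_predict()` applies one cohort's model to
the other cohort's panel, preprocessing the target with the *source*
cohort's fitted transforms; model features missing from the target panel
are held at 0 in standardized space — the source-cohort mean, the
least-information default — and are listed in the output.

## The synthetic-cohort generator

The generator exists so the entire pipeline is testable without any
clinical data.  Its defaults are the package's reference study
conditions, chosen once:

* 25 patients (the NACT arm's size), 116 assayed analytes of which 59 are
  effectively undetectable (their detection limit sits at the 0.95
  quantile of their own concentration distribution, so the 75% filter
  removes them and ~57 analytes survive — the study's detected counts);
* per-analyte log-normal concentrations with natural-log mean drawn from
  [1, 6] and log-SD from [0.8, 1.5], giving raw CVs of roughly 95-330% —
  matching panels where most detected analytes exceed 100% CV;
* detection limits at the 10% quantile and top standards at the 98%
  quantile of each detectable analyte (plausible assay-QC placeholders;
  per-analyte censoring rates are rarely published), dilution factor 2;
* a sparse linear signal: 5 informative analytes with effects of
  magnitude 0.8 and random sign on the standardized log scale, residual
  noise SD 0.2;
* PFI mapped affinely to days with mean 166 and SD 40 (the NACT arm's
  mean; the map is normalized by the theoretical signal SD so the day
  scale is controlled whatever the effect/noise settings, and the
  generator raises if a draw still produces a non-positive PFI).

A PDS-arm emulation used by the acceptance script differs where the study
says the arms differ: 14 patients, PFI 447 ± 120 days, and a sparser,
stronger signal (2 informative analytes, effect 1.0, noise 0.1) —
reflecting that the study's smaller PDS cohort supported the more
predictable model.

Each cohort uses a private RNG stream seeded from its config; the caller's
RNG state is untouched and equal configs give bit-identical panels.  The
ground truth (true coefficients, pre-censoring concentrations, realized
censoring fractions) is returned alongside the panel for recovery tests.

**What the generator does not emulate:** inter-analyte correlation
(analytes are drawn independently, whereas real secreted-protein panels
are strongly co-regulated), plate and batch effects, technical replicates,
and the instrument's logistic standard curve.  Passing tests on this
generator therefore demonstrate the pipeline's statistical mechanics —
recovery of a sparse signal through censoring, imputation and transforms —
not performance on correlated real panels, where the Lasso's arbitrary
choice among correlated predictors is an additional, well-known
instability.

## What the test suite shows — and a structural limit

Property tests confirm the solver's KKT certificate and closed-form
special cases, the transform round trip across all λ branches, the exact
imputation and filter rules, determinism, and the censoring calibration of
the generator.  A 100-replicate study at the reference conditions (n = 25,
57 detectable analytes, 5 informative) confirms the package's central
claim: relaxing the penalty to a 20-day budget lowers both the median
aggregate %CV and the median model size relative to the accuracy-optimal
penalty.

The same study exposes an honest structural limit worth knowing about.
The relaxation rule by construction parks the model at the penalty where
the LOOCV RMSE touches the budget.  With five equal informative effects on
a unit-variance outcome, each true standardized coefficient is at most
1/√5 ≈ 0.45, while the budget-edge penalty is typically 0.15-0.25 —
a margin of only a couple of replicate-level standard errors.  In a
substantial minority of replicates at least one informative analyte
therefore drops out of at least one of the 125 fold fits, and occasionally
out of the relaxed model altogether; no honest configuration of noise or
censoring removes this while keeping the budget both feasible and binding.
On real panels the same mechanics apply, compounded by correlation: a
feature reported with inclusion fraction 1 and low %CV is strong evidence
of a stable signal, but a feature that drops in a few folds is not
evidence of absence.

## Problem sizes used by the tests and acceptance script

The bundled acceptance script rebuilds both emulated cohorts from a seed,
runs both models (optimal and relaxed), nested LOOCV on the NACT arm,
cross-cohort predictions in both directions and the descriptive layer,
and writes every headline number as JSON; it completes in well under a
minute.  The 100-replicate stability study in the test suite runs in a
few minutes.  Larger cohorts are generated on the fly wherever a test
needs them (e.g. n = 1000 for censoring calibration); nothing is stored.
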