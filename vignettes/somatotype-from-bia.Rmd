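---
title: "Somatotype from bioimpedance: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatotype from bioimpedance: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somatoBIA)
```

## The two measurement routes

somatoBIA computes the Heath–Carter anthropometric somatotype two ways. The
*reference* route is the full protocol: ten body dimensions (weight, stature,
four skinfolds, two girths, two bone breadths) fed into the standard
Heath–Carter constants. The *reduced* route replaces part of that set with a
50 kHz whole-body bioimpedance measurement: resistance drives an
athlete-specific fat-free mass equation, and three bundled linear equations
then estimate the components from FM%, the bioimpedance index S²/R, two
skinfolds, two girths, fat-free mass and stature. The reduced route needs no
sliding caliper (breadths), one fewer skinfold site on each of the trunk and
leg, and no reactance.

Units are fixed package-wide: stature in cm (converted internally where
metres are needed), weight in kg, skinfolds in mm, girths and breadths in cm,
impedance in ohm. All somatotype ratings are floored at 0.1, for predicted as
well as reference components, so both routes share one type; the floor is
flagged in prediction output whenever it engages, because the bundled
equations can go below it only for physiques far outside the population they
were developed on.

## Model details and conventions

**Endomorphy** uses the height-corrected cubic in the skinfold sum;
**mesomorphy** the linear form in breadths and skinfold-corrected girths;
**ectomorphy** the piecewise rule on HWR = stature/weight^(1/3) with
half-closed branches (HWR ≥ 40.75 upper line, 38.25 < HWR < 40.75 middle
line, HWR ≤ 38.25 floored). These constants are fixed in code, not
configurable: they are the published standard, and the bundled reference
group statistics reproduce their printed somatotype means to one decimal
under exactly these constants.

**Phase angle** is computed as (Xc/R)·180/π — the small-angle form the
downstream equations were developed against — rather than arctan(Xc/R). At
physiological ratios (Xc/R ≈ 0.14) the two differ by under 0.1°; the
conventional form is available via `phase_angle(..., method = "arctan")`.

**The fat-free mass equation is male-specific.** The trailing +5.462 term is
the male indicator at value 1. Rather than silently mis-applying it, every
entry point refuses records marked with another sex.

**FFM/stature** in the ectomorphy prediction equation is kg/cm. This is the
unit in which the equation reproduces the development-group mean ectomorphy;
kg/m does not.

**Thirteen-category classification** uses the half-unit convention: a
component is dominant when it exceeds both others by more than 0.5 rating
units; two components are equal when they differ by at most 0.5. One dominant
component with the other two equal gives "balanced X"; a dominant component
with an ordered remainder gives the modifier form ("ectomorphic mesomorph");
two equal leaders above the third give the hyphened hybrid
("mesomorph-ectomorph"); everything else — including exact three-way ties —
is "central". Exact boundary ties therefore fall toward the
balanced/hybrid/central labels, and the rule set partitions the whole rating
space (property-tested on a grid including the 0.5 boundaries).

**Reporting precision** follows the field: somatotype components to one
decimal, halves rounded away from zero (`round_half_up()`); concordance
statistics to 2–4 decimals; full precision everywhere internally and in JSON
output.

## Equation development and validation machinery

`stepwise_ols()` is classical forward selection with backward elimination.
The entry statistic is the partial-F p-value of the incoming predictor
(equivalently the square of its t statistic); the candidate with the smallest
p enters if p ≤ 0.05, and after each entry any member with partial p > 0.10
leaves. Entry strictly below removal prevents cycling; ties at entry break by
larger |t|, then lexicographic name, so selection is deterministic.
Perfectly collinear candidates are skipped with a warning; an empty first
step returns the intercept-only model with a warning. VIFs are 1/(1−R²) of
each retained predictor on the others, reported only when two or more
predictors remain (a single-predictor model reports VIF = 1 by convention),
with the conventional flag at 5.

Residual diagnostics test normality with a Kolmogorov–Smirnov statistic
against the normal with the residuals' own moments, and variance homogeneity
with the t-test on the slope of |residual| against fitted values. The
homogeneity test is a package choice — the convention names no specific
test — and reports are labelled accordingly. All-zero residuals (exact fits)
are reported as degenerate rather than crashing.

`cross_validate()` reports, per component: R² (squared Pearson correlation of
predicted and reference), pure error √(Σ(Ŷ−Y)²/n) (which charges bias as well
as scatter, unlike the SEE), Lin's concordance correlation coefficient with
n-denominator moments in the original formulation (the n−1 variant sits
behind a flag) and its exact decomposition ρc = ρ·C_b, and Bland–Altman bias
with 1.96·SD limits of agreement and the trend correlation of differences
against pair means. **Differences are always predicted − reference**; the
direction is stamped on every report because a negative bias then reads as
"the reduced method runs slightly below the reference", the pattern to expect
when predictions shrink toward the development mean.

## The synthetic cohort generator

No per-athlete data ship with the package; every test and demonstration runs
on synthetic cohorts. The generator draws fifteen variables (anthropometrics,
latent fat-free mass, phase angle, impedance) from a truncated multivariate
Gaussian parameterized by the bundled development-group means and SDs of an
elite male Serie A-like cohort, with two deliberate departures:

* **Stature SD is 5.0 cm**, not the printed 0.5 cm, which is implausibly
  small for over a hundred adults (likely a typo in the source statistics;
  the printed value is retained verbatim in `soccer_reference_stats()` as
  data, and the simulator default is the package's own choice).
* **The correlation matrix is hand-set**, since no covariances are published:
  weight–FFM 0.95, weight–stature 0.5, skinfold–skinfold 0.6, skinfolds
  independent of FFM, girths loading on both weight and FFM, resistance
  negatively correlated with weight and FFM. The raw hand matrix had a
  smallest eigenvalue of −0.004, so it was shrunk once by 5% toward the
  identity; the shipped file (`extdata/cohort_correlation_default.csv`) is
  the result, is editable, and is validated (symmetry, unit diagonal,
  positive definiteness) on load.

Rows violating the physiological record invariants are rejected and redrawn;
since every bound sits ≳3 SD from its mean, truncation barely moves the
moments (large-sample means land within 2% and SDs within 5% of
specification). Position labels follow the 8/50/62/56
goalkeeper/defender/midfielder/forward roster proportions by exact
largest-remainder allocation.

In **linked** mode (the default), anthropometrics are rounded to instrument
precision (0.1 unit) first, then resistance is back-solved from the latent
fat-free mass target, R = 0.327·S²/(FFM + 2.261 − 0.525·W − 5.462), and
reactance from the drawn phase angle, so `ffm_athlete()` inverts the
generator exactly (tested at 1e−9) and BIA and anthropometry are mutually
consistent. In **empirical** mode resistance and reactance are drawn directly
from their marginal moments, which is the mode to use when checking marginal
distributions rather than cross-modality structure.

What the generator does *not* emulate: skinfold skewness (everything is
truncated-Gaussian), position-specific morphology differences, seasonal or
injury-related change, measurement error correlation between sites, or any
device-specific impedance artefact. Passing tests on synthetic cohorts
therefore demonstrate the correctness and internal consistency of the
computations, not field accuracy of the bundled equations on new athletes.

## An identifiability caveat for selection studies on linked cohorts

One structural consequence of linked mode matters when the generator is used
to study *predictor selection* (rather than prediction): because resistance
is back-solved exactly, the bioimpedance index S²/R is an exact linear
combination of fat-free mass and weight among the candidate columns,
S²/R = (FFM + 2.261 − 0.525·W − 5.462)/0.327, and FFM/stature is almost
exactly linear in {FFM, stature} at realistic stature spread (CV ≈ 2.7%). A
response generated from one representation is therefore fitted equally well
by statistically equivalent predictor sets, and any selection procedure —
stepwise or otherwise — lands on one of them essentially by noise. Recovery
of the *predictor labels* on linked cohorts is consequently poor even when
the fitted function is recovered almost perfectly, and exercises that score
label recovery on this design will fail regardless of implementation. The
stepwise machinery itself recovers generating sets and coefficients reliably
on well-conditioned (identifiable) designs, which is how the unit suite
tests it.

## Numerical and degenerate-case choices

* Stratified splitting allocates the validation total (rounded `n` × fraction)
  across strata by largest remainder, so each stratum differs from exact
  proportionality by less than one athlete; 176 athletes at 1/3 always yield
  exactly 59. Single-member strata go to development with a warning.
* Saturated fits inside stepwise (residual SS numerically zero) are handled
  by treating the partial-F p as 0 when the added term still reduces RSS and
  1 otherwise, so exact relationships terminate cleanly with R² = 1, SEE = 0.
* `validate_cohort()` is total: non-finite values become violations, never
  exceptions, so one malformed row cannot abort a batch ingest.
* Zero-variance inputs to Lin's CCC are refused (the statistic is undefined);
  identical vectors in Bland–Altman report the trend as not applicable.
* Measurement-error propagation (`somatotype_measurement_error()`) is an
  optional Monte-Carlo utility at the ISAK level-1 technical errors (5%
  skinfolds, 1% girths/breadths), off by default in every pipeline.

## Problem sizes used in the test suite

Unit and property tests run on cohorts of 10–2,000 athletes (10,000 for the
moment checks), 1,000-point random-input oracle comparisons at 1e−9, 100–400
replicate simulations for diagnostic and null-selection rates, and 50-seed
selection studies at the study size (n = 117). These sizes were chosen so the
whole suite exercises every code path in well under a minute while keeping
Monte-Carlo standard errors comfortably inside the asserted bands.

## Known limitations

The bundled equations are population-, sex- and device-specific: elite male
soccer players, hand-to-foot single-frequency BIA at 50 kHz. The package
warns on other declared frequencies and refuses non-male records. Mesomorphy
is the weakest link of the reduced route — the equation carries no bone
breadth information, so its agreement with the reference is systematically
looser than endomorphy's or ectomorphy's, a trade of accuracy for speed that
is visible in every cross-validation report the package produces.
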