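---
title: "Modelling cardiomyocyte turnover: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cardiomyocyte turnover: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmturnover)
```

## The modelling problem

Estimates of cardiomyocyte (CM) renewal in the healthy adult human heart
differ by more than an order of magnitude depending on methodology.
Pulse-chase approaches read turnover out of the ¹⁴C content of CM DNA at
autopsy, using the atmospheric bomb pulse as a global tracer; they support
low, age-declining turnover. Cell-population approaches compute turnover
from histological counts of cardiac stem cells (CSCs), their cycling
fraction and CM apoptosis; they support high, age-increasing turnover.
`cmturnover` provides one cohort bookkeeping engine that both kinds of
inputs can drive, the radiocarbon forward model that converts simulated CM
age distributions into predicted ΛC14 values, and grid-search inversion for
estimating turnover dynamics from measurements.

## Cohort bookkeeping

All scenario families share a deterministic, real-valued, year-stepped
engine. Cohorts are indexed by formation offset `0..lifespan`, offset 0
being the perinatal pool. In each year of life the engine computes
formation and destruction *from the start-of-year state* and applies both
simultaneously; the cohort formed during a year first experiences
destruction the following year. Real-valued counts are the expectation of
the equivalent discrete agent process (Bernoulli deaths, Poisson births);
the test suite carries an agent-based oracle on 10⁴-agent instances and
checks agreement within Monte-Carlo error, so at physiological counts
(5×10⁸ CMs per 10 g) the continuous ledger is the right object to compute.

Evaluated annual rates are clipped to [0, 1] with a warning; the engine
refuses to produce negative cohorts; and every ledger verifies the
conservation identity

> final count = initial + Σ formed − Σ destroyed

to a relative tolerance of 1e−9 on construction.

### Within-year conventions and the linear birth/death model

For Mode-B style schedules and constant replacement, a cohort retains the
fraction `1 − d` of its members per year. This makes the constant-
replacement survivor fraction exactly `(1 − r)^L` — the closed form the
test suite uses as an oracle — and keeps full-replacement simulations
exactly count-preserving.

The four-parameter linear model (TVB-TVDR: time-varying birth rate,
time-varying death rate) required a choice among several defensible
within-year conventions, because its published description leaves the
formation basis and the depletion rule open. We selected the convention by
requiring the model, at its published best-fit parameters
(B_s = 0.10 %/yr², B_i = 2.5 %/yr, D_s = 0.5 %/yr², D_i = 1.0 %/yr, 70-year
subject), to reproduce the two published total-count checkpoints — an
adolescent peak near 130 % of the count at birth around age 20, and 87 %
of the count at birth by year 70. Scanning all coherent combinations of
formation basis (current total vs count at birth), rate indexing and
depletion rule showed:

* formation proportional to the *current* total overshoots the adolescent
  peak badly (≥ 140 % at age 20) for every depletion rule — so the default
  formation basis is the count at birth, the natural reading of a
  full-replacement bookkeeping in which rates are percentages of the
  heart's size at birth;
* binomial depletion (`1 − d`) lands at 83–86 % at year 70; treating the
  assigned annual death rate as an exponential hazard (`exp(−d)` surviving
  per year) with rates evaluated at the cohort's formation offset gives
  129.65 % and 87.06 % — essentially exact.

The TVB-TVDR default is therefore the exponential-hazard convention, while
`survival = "binomial"` and `formation_basis = "current"` remain available
as arguments. With zero slopes and equal intercepts the binomial setting
reduces the model exactly to constant replacement, which is how the
reduction property is tested. The hazard distinction only matters at the
large per-cohort rates the model assigns to late-formed cohorts
(D_i + D_s·t approaches 36 %/yr at t = 70); at the ~1 %/yr scale of the
constant-turnover analyses the two conventions agree to within rounding.

### Hierarchical (stem-cell) kinetics

Mode-A formation converts instantaneous histological quantities into
annual event counts: the number of cycling CSCs times the number of
mitosis cycles fitting into a year (8766 h divided by the 26 h mitosis
duration), amplified by `2^E` transit divisions. Destruction does the same
with the instantaneous apoptotic fraction and the 4 h apoptosis duration.
The formation formula is pluggable (`formation_fn`) because variant
hierarchies are conceivable; the default is the composition above.

The true age/sex parameter tables behind this model come from regressions
over 74 hearts that this package deliberately does not re-estimate; tables
are inputs. The bundled table (`kajstura_synthetic_params()`,
`inst/extdata/kajstura_params_synthetic.csv`) is **synthetic**: it was
calibrated once to the qualitative conditions the literature states —
young-adult male turnover near 7 %/yr rising about three-fold with age
over a slowly declining count; higher female turnover with a count that
rises, peaks in (late) middle age and ends above youthful levels; and an
expansion exponent of 5, which makes a ±20 % change in E exactly a
two-fold change in formation (2^(0.2·5) = 2), the sensitivity magnitude
reported for this parameter. Those calibration targets are study
conditions, not tuned quantities; they were fixed before the test suite
existed and are not revisited.

### Turnover definitions

`turnover_series()` implements both published definitions: newly formed
CMs divided by a *constant* reference count, or by the *adjusting*
start-of-year total from the trajectory. The difference matters: a
declining male count amplifies adjusting-denominator turnover, a growing
female count suppresses it. The adjusting definition is the default in the
sensitivity and band machinery. The initial count defaults to 5×10⁸ CMs
per 10 g of tissue; the literature also prints a 100-fold smaller figure
in one place, so `n0` is configurable everywhere, and turnover itself is
scale-invariant.

## The radiocarbon forward model

Curve units are per-mil Δ¹⁴C differentials to the 1955 pre-bomb baseline;
years before 1955 are null by definition and the loader enforces this
(strict mode errors, lenient mode zero-fills with a warning). Smoothing is
a one-year average of the monthly record; whether the historical analyses
used a centred or trailing window is not stated, so the package averages
raw samples within each calendar year (a centred 12-month window evaluated
at mid-year), which is exact on yearly data.

Each cohort starts from the smoothed atmospheric value at its formation
year minus the incorporation delay (`incorporation_policy`; 0 by default,
2 years under the solid-tissue lag hypothesis — implemented by reading the
curve earlier, equivalently shifting the bomb curve forward in time, an
equivalence the tests assert). Polyploidization then mixes later
atmospheric carbon into the cohort's DNA: for each subsequent year with
incremental polyploidizing fraction p, the value updates as
`v ← (v + atm·p)/(1 + p)`. That weighting — old value at weight 1,
atmosphere at weight p, normalised by 1 + p — is the update the source
methodology describes verbatim, and it is the default even though a
conventional convex mixture `(1 − p)·v + p·atm` might look more natural;
the latter is available as `update = "normalized"`. Both keep every cohort
value inside the range of atmospheric values encountered during life, a
property the suite checks on random fixtures.

The polyploidization fraction is a sigmoid in subject age with three
parameters (midpoint 7 y, steepness 2 y, plateau 0.8) chosen so that the
vast majority of polyploidization completes during childhood, as the
underlying ploidy literature describes; the exact published coefficients
are not reproduced in our sources, so all three are exposed, a tabulated
curve can be supplied instead, and `scale` multiplies the whole curve
(≈ 0.78 emulates the milder correction reported by an alternative ploidy
study; 0 disables the correction).

`initial_c14()` supports the smoothed value at birth or the extreme raw
reading within 12 months of birth — the min/max modes used to propagate
initial-condition uncertainty into fitted turnover bands.

## Inversion

`solve_constant()` scans predicted ΛC14 over a rate grid (default
0–50 %/yr in steps of 0.01) using closed-form cohort weights that are
bit-identical to the simulator (an equality the tests verify), then reads
solution branches off the sign changes of the residual. For subjects born
before the bomb pulse the forward map rate → ΛC14 rises to an interior
maximum and falls again — high turnover flushes out the CMs that absorbed
peak-era carbon — so beyond a threshold ΛC14 two rates explain one
measurement. The solver reports both branches, the threshold (the
prediction at the top of the rate grid, above which the high branch
becomes viable), and flags degenerate targets (constant curve) and
non-converged best-effort solutions instead of raising.

`fit_global()` is an exhaustive grid fitter (SSE over subjects on ΛC14,
which differs from end-¹⁴C SSE only by per-subject constants) for the
constant, cell-age-dependent (E2), linear birth/death (TVB-TVDR) and
age-varying full-replacement families. The TVB-TVDR evaluator exploits the
closed-form weights to vectorise the formation intercept/slope dimensions
exactly, and its default coarse-to-fine schedule (4× steps, then local
refinement at full resolution) keeps the published 17-million-point grid
tractable; `refine = "exhaustive"` disables the shortcut, and the tests
assert both return the same optimum on fixtures. Ties within 1e−9 of the
minimum are reported, with the lexicographically smallest vector as the
canonical best, for determinism.

Two published functional forms exist only as figure images in our sources
and were transcribed by their verbal descriptions: the E2 destruction
hazard is implemented as `γ₀·a^(−γ₁)` at CM age `a ≥ 1` with formation
balancing total deaths (destruction "inversely proportional to CM age"
with constant count), and the "time-dependent" family as full replacement
at a rate linear in subject age. Published numeric outputs of the E2 model
therefore cannot be targeted by this package, only its qualitative
structure. AIC uses the least-squares form `n·ln(SSE/n) + 2k` by default
with alternatives selectable; published AIC magnitudes for these analyses
match no standard convention, so cross-source AIC comparisons should use
rankings only.

## Sensitivity, bands and overlap

`sensitivity_sweep()` scales one kinetic parameter uniformly across all
ages (the published sweeps vary the age-dependent parameter by a flat
percentage, which is what a multiplier implements).
`kajstura_band()` varies the apoptotic fraction and expansion exponent
simultaneously by ±20 %: the published description does not say how the
two variations combine, so the band is the pointwise envelope over the
four corner combinations plus the central run — a conservative choice that
contains each one-at-a-time band. Trajectories are gender-composited
(default 75 % male / 25 % female, matching the composition of the
12-subject pulse-chase cohort) before enveloping. `overlap_region()`
intersects two bands pointwise and is commutative and idempotent.

## Synthetic data

`synthetic_bomb_curve()` reproduces the tracer's documented shape — null
before 1955, a monotone rise to a 1963-style peak, exponential decay — and
is the workhorse of the test suite. The bundled
`inst/extdata/bomb_curve_synthetic.csv` is a yearly synthetic
reconstruction of the Northern Hemisphere record (peak 850 per mil in
1964) for examples that want realistic magnitudes; it is labelled
synthetic because it is not a measured dataset, and quantities that depend
on the fine structure of the real atmospheric record (per-subject rate
estimates at the 0.1 %/yr scale, absolute SSE values) inherit that
approximation. `generate_subjects()` draws reproducible cohorts (births,
lifespans, sexes) under a seed and computes ground-truth ΛC14 through the
forward model under a generating scenario, enabling end-to-end
parameter-recovery tests; generation restores the caller's RNG state.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale by design: subjects
of 25–73 years, rate grids of ≤ 5001 points, fit grids of ≤ 5⁴
combinations plus one coarse-to-fine run, and 200-replicate agent
comparisons at 10⁴ agents — a few seconds in total. Full-resolution global
fits over the published TVB-TVDR ranges are supported and take minutes via
the closed-form evaluator. Tie-breaking is lexicographic; clipped rates
warn; degenerate inversions flag rather than fail; zero-count ledgers
refuse to produce an end-¹⁴C average.

## Known limitations

* The bundled bomb curve and parameter tables are synthetic
  reconstructions; analyses that need the measured atmospheric record or
  the real histology regressions must load them as CSV inputs.
* The E2 and time-dependent families implement plausible transcriptions of
  verbally described forms; their published numeric outputs are not
  reproducible from those descriptions alone.
* Within-year kinetics are annualised; individual mitosis/apoptosis events
  are not scheduled inside a year.
* Measurement error in ¹⁴C values is not modelled; observed values enter
  the SSE as given.
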