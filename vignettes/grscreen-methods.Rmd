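---
title: "Growth-rate-corrected organoid screen scoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-rate-corrected organoid screen scoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grscreen)
library(dplyr)
```

## The problem

Patient-derived organoid (PDxO) lines differ widely in how fast they grow
-- doubling times between 3 and 8 days are typical for breast cancer
organoids. In an endpoint viability screen (luminescence read once, after
a 96-hour drug exposure), a slow-growing line accumulates fewer doublings
in the assay window, so traditional endpoint metrics (IC50, GI50, EC50)
conflate *drug potency* with *growth rate*: a drug looks weaker in a slow
line even when it suppresses the same fraction of that line's growth.
Growth-rate (GR) correction removes this confound so that potencies can
be compared across lines from different patients.

## The GR transform

Let `T` be the treated endpoint reading, `T0` the day-0 seeding-control
reading (a parallel plate assayed at dosing time), and `C` the DMSO
vehicle endpoint reading. Assuming exponential growth over the exposure
window, the ratio of treated to untreated growth rates is

$$\mathrm{GR} = 2^{\log_2(T/T_0)\,/\,\log_2(C/T_0)} - 1,$$

which is 1 for uninhibited growth (`T = C`), 0 for cytostasis
(`T = T0`), and tends to −1 for complete killing (`T → 0`). It depends
only on the fold-changes `T/T0` and `C/T0`, so it is invariant to the
readout's absolute scale and -- the point of the exercise -- to the
line's doubling time. The traditional relative-growth transform kept for
comparison is `(T − T0)/(C − T0) × 100` (GI50 = dose where this crosses
50), and endpoint viability `T/C` supplies the IC50.

`normalize_screen()` aggregates `T0` as the mean of the day-0 control
wells *within the same biological replicate* (each replicate is an
independent screen run with its own parallel day-0 plate); a replicate
without day-0 wells falls back to the model's pooled day-0 mean with a
warning. Vehicle wells must grow (`C > T0`), otherwise the GR exponent is
undefined and scoring stops with an error rather than returning
nonsense.

## Curve fitting and the response metrics

For each (model, drug) pair, all replicate points -- 12 per dose in the
default design (4 technical × 3 biological) -- enter one pooled
least-squares fit of the three-parameter sigmoid

$$f(c) = \mathrm{GR}_{\inf} +
  \frac{1 - \mathrm{GR}_{\inf}}{1 + (c/\mathrm{GEC}_{50})^{h}},$$

with the top asymptote fixed at 1 (GR scale), 100 (relative growth) or 1
(endpoint viability). Bounds are conventional for 8-point series: Hill
slope in [0.1, 5], midpoint within [min dose/100, max dose×100], plateau
in [−1, 1] (GR), [−200, 100] (RV), [0, 1] (T/C). Optimization is
bounded L-BFGS-B from three deterministic starts (midpoint at the
geometric mean and the first/third log-quartiles of the tested doses), so
fits are reproducible without randomness.

A sigmoid is only accepted over the flat alternative (the mean response)
if an F-test on the residual sums of squares rejects flatness at
α = 0.05. Non-responders therefore get `fit_type = "flat"` and missing
potency parameters, which reproduces the missing-value behaviour of
GR-based scoring tools on real screens.

Threshold metrics come from the closed-form inverse of the sigmoid
(`solve_dose()`), each cross-checked in the test suite against bisection
root-finding:

* **GR50** -- dose where the fitted GR curve crosses 0.5 (`NA` if
  `GR_inf ≥ 0.5` or the fit is flat);
* **cytostatic dose** -- crossing of 0 (`NA` unless `GR_inf < 0`);
* **GI50 / IC50** -- crossings of 50 (relative growth) and 0.5 (`T/C`)
  on their own fitted curves;
* **GEC50, GR_inf, h, EC50** -- fitted parameters.

Roots further than 10× beyond the top tested dose or 10× below the
lowest are reported `NA`: an 8-point series says nothing reliable about
potencies outside its range, and this censoring matches how
non-crossing curves are reported as missing in practice. The
extrapolation factor is an argument (`extrapolation_factor`).

**GR_aoc** is the normalized area over the GR curve,

$$\mathrm{GR}_{aoc} = \frac{1}{\log_{10} c_{max} - \log_{10} c_{min}}
  \int \big(1 - \mathrm{GR}(c)\big)\, d\log_{10} c,$$

computed by the trapezoid rule on the fitted curve evaluated at 50
log-spaced points across the tested range (flat fits integrate their
constant level). Two conventions here are ours and are worth stating
explicitly, since the area-over-curve idea admits variants: integration
is on the log-dose scale, and the area is normalized by the log10 dose
span so screens with different dilution ranges are comparable. The
result is 0 for a constant GR of 1, 2 for a constant −1, and -- unlike
every threshold metric -- always defined, which is why ranking,
clustering and group comparisons run on it.

## Cross-screen statistics

* **Ranking.** Models are ordered by GR_aoc descending (most cytotoxic
  first) with stable lexicographic tie-breaks; drugs within a model get
  average ranks for ties.
* **Group comparisons** (e.g. chemotherapy GR_aoc in TNBC vs non-TNBC
  lines; drug-class rank positions between subtype groups) use the
  two-sided Mann-Whitney U test with a Hodges-Lehmann shift estimate and
  a 95% confidence interval: exact by inversion of the U distribution
  when `n·m ≤ 10,000` with no ties, otherwise the normal approximation
  with continuity and tie corrections. Pooling per-(model, drug) points
  (rather than per-model means) is the documented choice. No
  multiple-testing correction is applied across a drug panel; the tests
  are reported unadjusted.
* **GR50-GI50 concordance** uses Pearson correlation of the
  log10-transformed concentrations over complete cases (pairs where
  both metrics are defined), an OLS regression line, and a Mann-Whitney
  comparison of residuals between faster and slower growers split at the
  median doubling time.
* **Clustering** of the model × drug GR_aoc matrix is agglomerative with
  Euclidean distance and average linkage on the raw values, both axes;
  the method is a declared convention, deterministic, and its topology
  is invariant to input row order.
* **Clinical benefit ratios** divide the PFS and TTNT achieved on a
  model-informed therapy by the prior therapy's, reported to one
  decimal, against the benchmark ratio of 1.3 used by genomics-guided
  precision-oncology trials. For the worked case the computed PFS ratio
  is 138/41 = 3.4 at one decimal; we report the computed value.

## Loewe synergy

A two-drug grid is scored against Loewe additivity, the null model in
which a drug is additive with itself. The single-agent margins (the
zero-dose row and column) are Hill-fitted on the percent-of-control
viability scale; the expected response `E` of the pair `(a, b)` solves

$$\frac{a}{A(E)} + \frac{b}{B(E)} = 1,$$

where `A`, `B` invert the margin fits. The equation is solved by
bisection on `E` (80 iterations); when one drug cannot reach `E` alone
its term vanishes (inverse treated as infinite), and cells whose
expected effect falls below both plateaus are clipped to the deeper
plateau and flagged `"extrapolated"`. Synergy is
`expected − observed` (positive = more kill than additive), averaged
over nonzero-dose cells.

The standard error attached to `mean_synergy` deliberately counts two
sources: the within-cell replicate scatter, and -- because the fitted
margins are shared by every cell, making their error common-mode -- the
spread of per-biological-replicate re-analyses, each with its own margin
fits. Cell-level scatter alone understates the uncertainty by roughly
half in additive simulations.

## In vivo statistics

Tumor volumes are normalized to the volume at treatment start; arm
comparisons use the trapezoidal AUC of relative volume up to `t_max`
(trajectories linearly interpolated to `t_max`; extrapolation past the
last measurement is refused) with a pooled-variance two-sided t-test
(Welch via `var_equal = FALSE`). Growth rates are log-linear slopes.
Recurrence is compared by the standard log-rank (Mantel-Cox) statistic
with censoring. Organoid-to-xenograft concordance is a signed Spearman
correlation between GR_aoc and an in vivo endpoint (smaller = better
response), oriented so perfect concordance gives ρ = +1; being
rank-based it is invariant to monotone endpoint transformations.

## The synthetic-data generators

Every pipeline input can be generated with known ground truth.
`simulate_screen()` emulates the screen design: 384-well plates, an
8-point half-log dilution from 10 µM, 4 technical × 3 biological
replicates, 16 day-0 wells per biological replicate on a parallel
plate, 16 vehicle wells, 96-hour exposure, doubling times in [3, 8]
days. Growth is exponential over the window (organoids far from
confluence), so the vehicle fold-change is
`C/T0 = 2^(96 h / (24·DT))` and a treated well's expected endpoint is
`T = T0 · (C/T0)^{log2(GR^*(c)+1)}` -- the exact inverse of the GR
transform, which makes recovery exact in the noiseless limit and turns
every scoring step into a testable round trip.

Choices the underlying assay literature does not pin down, fixed here
once:

* **Noise**: multiplicative lognormal per well (technical CV 5%, day-0
  CV 5%) plus a lognormal per-biological-replicate scale factor
  (SD 10%). Luminescence noise is scale-proportional, and replicate-run
  effects are multiplicative; the GR transform cancels the replicate
  factor by construction, which the tests exploit.
* **Truth draws**: 30% of (line, drug) pairs inert; responsive pairs get
  `GR_inf ~ U(−1, 0.5)` (strong cytotoxicity through weak partial
  response -- "growth" is the inert category), midpoints log-uniform in
  the central tested range (screens are designed so potencies fall
  inside the series), Hill slopes `U(0.5, 3)`.
* **Dilution**: half-log (×3.16), spanning 3.5 decades from the top
  dose.

`simulate_synergy_grid()` builds combination surfaces from true margin
curves, exactly Loewe-additive unless a synergy `bonus` is applied, and
renormalizes each biological replicate to its own untreated wells as
percent-of-control data are prepared in practice. `simulate_invivo()`
couples a per-line latent sensitivity (shared with the screen truth) to
exponential tumor growth under treatment; `simulate_clinical()` draws
exponential therapy durations with stated medians.

What the generators deliberately do **not** model: plate spatial (edge)
effects, drug-penetration gradients into organoids, subclonal
heterogeneity, non-exponential (confluent or lagged) growth, and
non-lognormal readout artifacts. Passing recovery tests therefore
demonstrates correctness of the scoring arithmetic and robustness to
realistic magnitudes of multiplicative noise -- not robustness to every
failure mode of a real screen.

## Numerical choices and degenerate inputs

* Sigmoid-vs-flat selection: F(2, n−3) test at α = 0.05; a perfect
  (zero-residual) sigmoid on non-constant data is accepted directly.
* Bisection tolerances: 80 iterations for the Loewe effect solver
  (relative error < 1e−12 of the effect range); closed-form threshold
  doses agree with 300-iteration bisection to better than 1e−6 relative
  in 1,000-draw sweeps.
* Ties: model ranks break lexicographically (stable); drug ranks
  average. Mann-Whitney falls back to the tie-corrected normal
  approximation whenever ties are present; completely degenerate
  samples (all observations identical) report p = 1, shift 0, and the
  pairwise-difference range as a vacuous interval.
* Zero treated readings map to GR = −1 exactly; the generator clips
  true GR at −1 + 1e−9 when extreme parameters would underflow.
* A t-test between arms with no within-arm variability at all returns
  p = 1 when the arms are identical and p = 0 otherwise, instead of
  failing.

## Known limitations, and problem sizes used in validation

The recovery of weakly identified truths is limited by the design, not
the fitter: with an 8-point half-log series, curves with shallow Hill
slopes (< 0.8) or small amplitude (`GR_inf > 0.2`) admit many
near-equivalent (midpoint, slope) pairs, and in our 100-seed recovery
suite the joint GEC50-within-15% / GR_inf-within-0.1 rate settles near
89% -- with every miss showing a fitted RSS below the truth's RSS, i.e.
the data genuinely prefer the wrong neighborhood. A wider dilution
range or steeper truth panel would lift this, but the study conditions
are fixed.

Validation problem sizes (chosen so the full suite runs comfortably on
a laptop): 100-seed suites for doubling-time invariance (2 lines ×
4 drugs), truth recovery (2 × 3) and additive-synergy calibration
(6 × 6 grids); 200 seeds for screen-to-xenograft concordance (8 lines,
4 mice per arm); 1,000 random draws for closed-form-vs-bisection
agreement; exhaustive Mann-Whitney enumeration up to 10 + 10
observations. The in-package examples use 1-3 line mini-screens.

```{r example, eval = FALSE}
lines <- tibble::tibble(model_id = c("L1", "L2"),
                        doubling_days = c(3, 8), subtype = "TNBC")
truth <- tibble::tibble(model_id = rep(c("L1", "L2"), each = 1),
                        drug_id = "drugA", inert = FALSE,
                        gr_inf = -0.8, gec50_uM = 0.1, hill = 1.5)
sim <- simulate_screen(lines, truth, screen_config(), seed = 7)
score_screen(sim)
# identical GR50 for the 3-day and 8-day lines; IC50/GI50 differ
```
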