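---
title: "Statistical method validation for iCIEF calibrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical method validation for iCIEF calibrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iciefval)
```

## The measurement and its model

Imaged capillary isoelectric focusing (iCIEF) focuses amphoteric analytes
along a pH gradient inside a short, whole-column-imaged cartridge; the
readout is an absorbance trace over (here) 2048 detector pixels. Peptides
focus at their isoelectric point (pI), and because the acquisition software
anchors the pixel axis to exactly two co-focused pI markers, apparent pI is
obtained by linear interpolation between those anchors (`pixel_to_pi()`);
positions outside the anchor interval are extrapolated on the same line and
flagged, which is why a third marker can appear slightly off its nominal
pI.

Quantification rests on an ordinary-least-squares calibration of peak area
(or, for detection limits, peak height) against concentration,

$$y = b_0 + b_1 x \qquad\text{or}\qquad y = b_0 + b_1 x + b_2 x^2,$$

never forced through the origin. OLS is only trustworthy when its
textbook assumptions hold, so the package implements the full battery a
careful validation runs on the residuals, in the order
`validate_series()` executes them:

1. **Influence screening** (`influence_table()`, `flag_outliers()`):
   leverage, studentized deleted residuals (SDR), Cook's D, DFFITS and
   per-coefficient DFBETAS, all by the standard leave-one-out
   definitions. An observation is declared an outlier only when it
   exceeds *all* of |SDR| > 3.0, Cook's D > median F(p, n − p) (0.724 at
   n = 18, p = 2), |DFFITS| > 1 and max |DFBETAS| > 1; partial
   exceedances are reported as suspects. Leverage cut-offs (both 2p/n and
   4/n are reported) stay advisory because evenly spaced calibration
   levels make x-outliers uninformative.
2. **Normality** (`normality_suite()`): bias-corrected skewness and excess
   kurtosis with t-based intervals from the sample-size-only standard
   errors, BCa bootstrap intervals for both moments, Shapiro-Wilk and
   Lilliefors tests.
3. **Homoscedasticity** (`breusch_pagan()`): see below.
4. **Independence** (`durbin_watson_check()`): the Durbin-Watson statistic
   computed against the *chronology of injections*, classified into
   positive / inconclusive / none / inconclusive-negative / negative
   autocorrelation zones by the critical bounds.
5. **Linearity** (`mandel_test()`, `lof_test()`, `stepwise_linearity()`):
   the genuine Mandel fitting test — the extra-sum-of-squares F between
   nested first- and second-order fits with denominator SSE₂/(n − 3) —
   and the classical lack-of-fit test (lack-of-fit vs pure-error mean
   squares). When a test rejects, the highest remaining level is removed
   and the test repeated until it passes or the design floor is reached
   (five levels for the Mandel test, three for lack-of-fit, each with
   three replicates); exhausting the floor is reported as "no linear
   range found", never silently truncated further.
6. **Inter-day slope comparison** (`variance_f_test()`,
   `compare_slopes()`): homogeneity of the regression-model variances
   s²y/x by a two-sided F-test at α = 0.01, then both Welch's t-test with
   Aspin-Welch fractional degrees of freedom and the pooled t-test. Both
   use s²y/x/Sxx as the slope variance. With equal sample sizes and equal
   residual variances the two tests coincide exactly, which is why
   paired calibrations of the same design report near-identical p-values.

Detection limits come in two flavours (`estimate_noise()`, `lod_loq_sn()`,
`lod_loq_slope()`): the signal-to-noise route (3:1 and 10:1 on baseline
noise N) and the calibration-slope route (3.3·SD/slope and 10·SD/slope,
per-day values averaged).

## Defaults that matter

| Parameter | Default | Why |
|---|---|---|
| Calibration design | 6 evenly spaced levels × 3 cycles (n = 18), injected in increasing concentration per cycle | the smallest design satisfying the five-level guideline minimum with the three replicates the lack-of-fit test needs; cycling prevents drifts masquerading as non-linearity |
| Outlier rule | all four thresholds simultaneously, α = 0.01 for SDR | a single exceeded measure is a suspect, not an outlier |
| Linearity α | 0.01 for both MFT and LOF | convention for curvature screening |
| Variance-homogeneity α | 0.01; slope tests at 0.05 | the F-gate is deliberately conservative |
| BCa bootstrap | n_boot = 1000, α = 0.05, seeded | reproducible intervals |
| Baseline window | ±100 pixels around the focused zone, linear detrend | at least five half-height widths of a typical zone |
| Core noise | 2.5th–97.5th percentile range, N = half of it | approximates 4·SD while clipping extremes, and equals the central 95% span of the noise; one convention satisfying both common descriptions |
| Peak baseline | rolling median, 201 pixels | robust to zones up to ~±10σ wide |
| Resolution | R_S = 1.18·Δapex/(w½,1 + w½,2) | the European-Pharmacopoeia half-height form; on the pixel or pI scale equivalently, since the two are affine between anchors |
| pKa set | `"ipc_protein"` | see below |

## The synthetic-data generator

`simulate_trace()` and `simulate_calibration()` generate the study
conditions every test runs under: Gaussian analyte zones on a
piecewise-linear gradient with iid Gaussian per-pixel noise and optional
broad baseline bumps; calibration responses with a known line, plus
injectable pathologies — quadratic curvature, heteroscedastic noise with
SD ∝ (c/c_max)^g, AR(1) drift along the injection order (stationary
start), and a single gross outlier at a chosen (level, cycle). The default
calibration emulates a mid-range analyte: slope 1 response unit per
µmol/L, intercept 0.5, noise SD 0.4 at the top level (about 1–2% relative,
matching the repeatability a validated iCIEF method achieves), levels
5–30 µmol/L.

What the generator does *not* emulate: carrier-ampholyte chemistry, pH
gradient dynamics during focusing, gradient compression near the
electrodes, and concentration-dependent peak shape. Passing tests
therefore demonstrate the statistics are computed correctly and behave as
designed under their own assumptions — not that any real instrument
satisfies those assumptions.

Two scenario sizes were fixed once and pinned. The injected-outlier
narrative uses an offset of −5 noise SDs at the highest level of the
middle cycle; the stepwise-elimination scenario uses a flat saturation
deficit of 3 response units (7.5 noise SDs) at the top level, a decisive
saturation. Monte-Carlo suites in the tests use 200 seeds (outlier
narrative), 500 (AR(1) power), 1000–2000 (Breusch-Pagan), 10⁴ (MFT/LOF
type-I error) and 5000 (Welch type-I error) replicates; these sizes keep
Monte-Carlo error a factor ~3 below the asserted bands.

## Numerical choices

* **Durbin-Watson bounds.** Rather than embedding the published bound
  tables, `dw_bounds()` computes d_L and d_U exactly: the bounding null
  distributions are ratios of weighted chi-squares over the extreme
  selections of the differencing-matrix eigenvalues
  4 sin²(πj/2n), and their α-quantiles are found by Imhof integration
  plus root finding. The results reproduce the published 5% table to
  three decimals (1.158/1.391 at n = 18, m = 1; 1.133/1.381 at n = 17)
  and extend to any n, m and α. A simulation oracle in the tests checks
  the same quantiles by directly sampling the bounding laws.
* **Breusch-Pagan form.** The primary statistic is the classic
  (normality-assuming) ESS/2 form of the auxiliary regression of scaled
  squared residuals on concentration; Koenker's studentized n·R² variant
  is always reported alongside. At n = 18 the classic form is noticeably
  more powerful (simulations in the test suite put its power above 50%
  against SD ∝ concentration, where the studentized form stays below),
  while both hold their nominal size.
* **BCa intervals.** z₀ from the fraction of bootstrap replicates below
  the estimate (ties split), acceleration from the jackknife, endpoints
  by type-6 quantiles. A caveat the package documents deliberately:
  nominal 95% BCa intervals for skewness at n = 18 *undercover* — about
  9 cases in 10 rather than 95%, confirmed against the reference `boot`
  implementation. The bootstrap view is reported as a complement to the
  t-based intervals, not as an exact procedure.
* **Moment estimators.** Skewness and excess kurtosis use the adjusted
  (bias-corrected) estimators common to mainstream statistics packages,
  so their sample-size-only standard errors
  √(6n(n−1)/((n−2)(n+1)(n+3))) and the paired kurtosis formula apply
  exactly.
* **Lilliefors p-values** come from the Dallal-Wilkinson approximation in
  the `nortest` package.
* **Degenerate inputs.** Exact fits (SSE at rounding-noise level),
  constant residuals, zero-variance squared residuals and
  exact-interpolation points (leverage 1) are flagged and reported rather
  than producing spurious statistics.
* **Stepwise elimination** re-estimates pure error on the reduced design
  after each removal, rather than reusing the full-range estimate.

## pKa sets and the mimotope predictions

`isoelectric_point()` bisects the Henderson-Hasselbalch net-charge
function over pH 0–14; the charge is strictly decreasing, so the root is
unique whenever the sequence carries both basic and acidic groups. Four
conventions ship: the two Isoelectric Point Calculator sets
(`ipc_protein`, `ipc_peptide`), the Bjellqvist/Expasy set with
first-residue amine overrides, and the EMBOSS textbook set.

For the CD20 mimotope pair — the linear 12-mer QDKLTQWPKWLE and its
cyclization scaffold CQDKLTQWPKWLEGC — the `ipc_protein` set (the
isoelectric.org default) is the convention that reproduces the IPC
predictions of 5.88 (cyclic scaffold, cysteines free) and 6.56 (linear),
a 0.68-unit split driven entirely by the two extra thiols:

```{r}
predict_pi_table(list(peptide_sequence("CQDKLTQWPKWLEGC", id = "Rp5-C"),
                      peptide_sequence("QDKLTQWPKWLE", id = "Rp5-L")))
```

The `ipc_peptide` set predicts higher values (6.22/6.97) — the peptide
pair sits in the regime where the two IPC calibrations disagree — and
the Bjellqvist set reproduces the near-iso-pI Expasy picture
(6.05/6.07), with the lower value belonging to the cyclic scaffold.
Treating the cysteines as free matches what sequence-based calculators
do; `cys_mode = "oxidized"` models the actual disulfide-bonded species by
removing the thiols from the ionizable set, raising the predicted charge
at every pH.

## Known limitations

* Two-anchor (affine) pixel→pI mapping only; no multi-anchor nonlinear
  gradient fitting.
* Peak integration is a transparent rolling-median/trapezoid scheme; it
  is not meant to replicate any commercial integrator numerically.
* No weighted least squares or GLS: heteroscedasticity is detected and
  HC3 standard errors offered, matching a workflow that retains OLS once
  homoscedasticity is confirmed.
* Slope comparison covers two series; multi-day ANCOVA is out of scope.
* The suitability schema supports height-ratio windows but ships no
  default values for them.
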