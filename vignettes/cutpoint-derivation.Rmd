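---
title: "Probability-based obesity cut-points from anthropometric indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probability-based obesity cut-points from anthropometric indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipocut)
library(dplyr)
```

## The problem

Dual-energy X-ray absorptiometry (DXA) measures whole-body fat percentage
(%FM) and, through android-region software, visceral adipose tissue (VAT)
mass in grams — the quantities most directly tied to cardiometabolic
risk. Screening programmes, however, work with a tape measure and scales.
This package evaluates five anthropometric indices — BMI, waist
circumference (WC), waist-to-hip ratio (WHR), waist-to-height ratio
(WHtR) and WHT.5R = WC/√height — as sex-stratified linear predictors of
the DXA outcomes, and converts the best predictor's equation into a
screening cut-point with an explicit probability interpretation.

## Models and procedure

**Regression.** Within each sex, each outcome is regressed on each index
by ordinary least squares: `y = a + b x + e`, `e ~ N(0, σ²)`. %FM is
modelled on its natural scale. VAT mass is strongly right-skewed with
multiplicative dispersion, so it is modelled as ln(VAT); its SEE is
reportable as a ×/÷ factor `exp(SEE)`, and descriptives use the geometric
mean ×/÷ factor SD (`exp(mean(ln x))`, `exp(sd(ln x))`, natural logs,
n − 1 SD). Subjects with VAT recorded as 0 g (below the software's
detection ability) cannot enter a log model and are excluded from VAT
analyses only; `exclude_undetectable_vat()` reports the count.

**Model comparison.** Candidates are compared within a stratum by AIC,
computed in the Gaussian profile form `n ln(RSS/n) + 2k` with k = 3
(slope, intercept, residual variance). Absolute AICs are defined only up
to an additive constant common to candidates fitted to the same subjects;
all inference uses differences Δ from the minimum, mapped to the usual
support scale. The printed scale overlaps at its boundaries ("<2", "2–7",
"7–14", ">14"); this package resolves it half-open — Δ < 2 equivalent,
2 ≤ Δ ≤ 7 plausible, 7 < Δ ≤ 14 weak, Δ > 14 unsupported — and tests pin
each boundary. An exact tie for the minimum is broken in the fixed order
BMI, WC, WHR, WHtR, WHT.5R so output is deterministic.

**Cut-point derivation.** Given a fit with positive slope, SEE `s` and
`n` subjects, the probability that an individual whose predicted outcome
is `ŷ` truly exceeds an obesity threshold `T` is the one-tailed
t-distribution area at `t = (ŷ − T)/s`, df = n − 2. Requiring probability
`p` (default 0.75, "likely", 3:1 odds) and solving backwards:
`ŷ_req = T + t_p · s*`, and the cut-point is `(ŷ_req − a)/b`. The SEE is
first inflated for small samples (n < 50), where the equation's own
sampling error adds to the prediction error:

`s* = s · √(1 + 1/n + 1/(n − 3))`.

The literature motivating this adjustment prints the factor without the
square root, but its own worked numbers (4.1 % fat adjusted to 4.2 % at
n = 41) are only consistent with the square-root form — the literal
product would give 4.3. The square-root form is therefore the default;
`method = "literal"` exposes the printed alternative. `paper_mode = TRUE`
additionally reproduces a printed-precision hand calculation (t to 3 dp,
SEE and required prediction to 1 dp between steps); the default keeps
full precision. Cut-points are conventionally read to 2 dp.

**Obesity thresholds.** %FM uses the standard strict thresholds
(> 25 % men, > 35 % women); BMI obesity is ≥ 30 kg/m² (inclusive, as the
criterion is written). VAT has no accepted mass threshold, so the obese
group is defined distributionally as the highest third of detectable VAT
per sex: the boundary is the empirical 2/3 quantile (quantile type 6, the
convention of mainstream commercial statistics software; the exact
interpolation rule is not identifiable from published tables, so tests
assert the membership property — about ⌈n/3⌉ subjects strictly above —
rather than one interpolant), and the VAT cut-point chain runs on the
ln-gram scale with `T = ln(boundary)`.

## The synthetic cohort generator

`simulate_cohort()` exists so that every pipeline stage is testable
without access to subject-level data. It generates what the analysis
assumes, not more: WHtR, BMI, WHR and height are drawn as independent
truncated normals per sex, and the raw measurements are back-derived
(WC = WHtR × height, HC = WC/WHR, mass = BMI × height²), which makes the
index identities hold exactly. Outcomes follow the fitted-model form:
%FM linear in WHtR with Gaussian residuals, VAT log-normal around a line
in WHtR, zeroed with probability `p_zero_vat` to emulate undetectable
records (0 g exactly, not missing — matching the exclusion rule).

Default calibration targets a published validity study of 41 men and 40
women. Index means/SDs come straight from its descriptive table (male
WHtR 0.50 (0.07), BMI 26.2 (4.1), WHR 0.91 (0.07); female WHtR
0.48 (0.08), BMI 24.8 (4.4), WHR 0.80 (0.07)); mean height is
back-derived as mean WC / mean WHtR (1.776 m men, 1.640 m women). The
male %FM line is the printed equation (slope 99.7, intercept −24.7, SEE
4.1). Where only fit statistics were printed, slopes are back-derived via
`r = √R²` with R² recovered from adjusted R² at the stratum n, slope
= r·SD(y)/SD(x), intercept through the means: female %FM (adj R² 0.60,
SD 7.8 → slope 76.2, intercept −2.56, SEE 5.0) and the ln VAT lines
(male: geometric mean 604 ×/÷ 2.9, adj R² 0.71, SEE factor 1.8; female,
detectable n = 32: 204 ×/÷ 4.9, adj R² 0.65, factor 2.6). Eight of forty
women have undetectable VAT (`p_zero_vat = 0.2`). Height SDs (0.07 /
0.065 m) and the age floor of 18 years are this package's own realistic
choices; truncation at the floor shifts the simulated age mean upward by
about five years, which is immaterial because age never enters the
models. Other truncation floors (height > 1.2 m, WHtR > 0.25, BMI > 13,
WHR > 0.4, %FM in (0, 100)) only prevent non-physical draws.

What the generator deliberately does **not** emulate: cross-index
correlations beyond those back-derivation induces (BMI and WHR are
independent of WHtR by construction, so the full published ΔAIC pattern —
where BMI carries real signal — is not reproducible on synthetic data);
DXA measurement error; ethnicity structure; any dependence of VAT
detectability on adiposity. Passing tests therefore demonstrate the
correctness of the statistical machinery under the stated model, not the
field behaviour of the indices on real cohorts.

The calibration fixes what the stand-in can reproduce. The implied female
%FM cut-point is 0.540 (published 0.54). The implied VAT cut-points are
0.58 (men) and 0.57 (women) against a published 0.59 in both sexes: the
inputs are summary statistics printed to 1–2 significant figures, and the
accumulated rounding moves the chain by roughly ±0.02 in WHtR units. The
implied large-sample male tertile boundary (~955 g) sits about 0.7
quantile-standard-errors below the published 1108 g, well inside the
sampling spread of a 41-subject tertile. These are stated here because
the acceptance checks measure exactly these quantities; none was tuned.

## Numerical choices and degenerate inputs

- SEE = √(RSS/(n − 2)); adjusted R² = 1 − (1 − R²)(n − 1)/(n − 2);
  fits need n ≥ 4 and a non-constant predictor.
- A perfect fit (RSS = 0) is kept with SEE 0 and adjusted R² 1, but AIC
  and cut-point derivation reject it explicitly rather than propagate
  infinities; as SEE → 0 the cut-point collapses continuously to
  `(T − a)/b` for every p.
- The SEE's 95 % CI is the χ² interval of the residual variance,
  condensed to one ×/÷ factor `(χ²₀.₉₇₅/χ²₀.₀₂₅)^{1/4}` (1.25 at 39 df);
  both raw bounds are exposed.
- Cut-point derivation requires slope > 0: only then does "index above
  cut-point" imply "predicted outcome above the required value".
- The Monte-Carlo calibration oracle used in testing draws prediction
  errors from `s*·t(df)` — the distribution under which the chain's
  probability statement is made — so the simulated exceedance fraction at
  the cut-point equals p exactly in expectation (a Gaussian would give
  Φ(t_p) ≈ 0.752 at p = 0.75, df = 39, a visible miscalibration at 10⁶
  draws).
- One seed drives the generator; the male stratum is drawn before the
  female stratum from a single stream, so cohorts are bit-reproducible.

Problem sizes used by the test-suite and acceptance checks, chosen to
keep Monte-Carlo error well below the assertion bands: 20 000 subjects
per sex where large-sample structure is measured, 100 replicates of
2 000/sex for parameter-recovery coverage, 300 study-size (41/40)
replicates for median cut-points and tertile boundaries, and 10⁶ draws
for probability calibration.

## Limitations

The cut-point procedure conditions on the fitted equation and its SEE; it
quantifies prediction error, not threshold-choice uncertainty, and
inherits any bias of the underlying regression. The tertile-based VAT
"obesity" definition is arbitrary by construction. Cut-points derived
from cohorts of 40–41 subjects carry sampling error of a few hundredths
in WHtR units (visible in the study-size replicate spread), and nothing
here validates transfer across populations — the synthetic stand-in is a
model of one study's structure, not of human variation.
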