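---
title: "Statistical methods behind pfasval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind pfasval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfasval)
```

## Scope and model

`pfasval` implements the statistical machinery of a bioanalytical method
validation for a targeted LC-MS/MS assay of 25 per- and polyfluoroalkyl
substances (PFAS) in 10 µL volumetric dried blood spots (DBS). All
quantitative reasoning happens on ratio axes: the response ratio
$y = A_{\text{analyte}} / A_{\text{IS}}$ is regressed on the concentration
ratio $x = c / c_{\text{IS}}$, with the internal standard at
$c_{\text{IS}} = 20$ ng/mL, so the six calibration levels 2–100 ng/mL map
to $x \in \{0.1, 0.25, 0.5, 1, 2.5, 5\}$. Reports convert back to ng/mL.

The validation design is three calibration curves per working session on
three non-consecutive days (54 analyses per analyte), QC levels at 2 / 15
/ 75 ng/mL, a 3 × 3 × 2 stability grid (temperature × time ×
concentration, 3 replicates), and a 3² full-factorial extraction
design-of-experiments.

## Weighted calibration

Replicate variance is inspected level by level. Heteroscedasticity is
declared by a one-sided F-test of the highest-level against the
lowest-level replicate variance at $\alpha = 0.05$; the criterion ("does
variance increase with concentration?") is standard, but no specific test
is canonical, so we chose the extreme-level F-test because it is exactly
calibrated and directly testable. The variance power $k$ in
$\operatorname{var}(y) \propto x^k$ is the slope of a df-weighted
regression of $\log s^2_\ell$ on $\log x_\ell$; estimates below 1.5 select
$1/x$ weighting, 1.5 and above select $1/x^2$ (nearest-integer rule around
the linear-vs-quadratic variance growth dichotomy).

Model order is decided by Mandel's fitting test at the ISO 8466
conventional $\alpha = 0.01$,
$$F = \frac{RSS_1 - RSS_2}{RSS_2 / (n-3)},$$
with weighted residual sums of squares, backed by weighted pure-error
lack-of-fit tests of both orders at $\alpha = 0.05$: the quadratic model
is adopted iff Mandel is significant, or the linear fit shows lack of fit
while the quadratic does not. Back-calculation inverts the fitted curve;
for quadratic fits the root on the ascending branch
($2 a_2 x + a_1 > 0$) inside $[0, 2 x_{\max}]$ is chosen, ties broken
toward the range midpoint. Responses with no admissible root are flagged
non-quantifiable rather than clamped.

## Detection and quantification limits

The Hubaux–Vos LOD uses the four lowest calibrators (the linear portion).
The blank decision threshold $y_c$ is the upper $(1-\alpha)$ one-sided
prediction bound of the weighted straight-line fit at $x = 0$; the LOD is
the smallest $x$ whose lower $(1-\beta)$ prediction bound reaches $y_c$,
found by root bracketing. The Currie-style weighting correction enters in
two places: the weights in the fit, and the per-observation variance term
of the prediction bound, which is extrapolated by the weighting's power
law ($\sigma^2$, $\sigma^2 x$, or $\sigma^2 x^2$). Under $1/x$ or $1/x^2$
weighting this variance extrapolates to zero at $x = 0$, so the blank
threshold is driven by calibration-parameter uncertainty alone — a
deliberate, documented convention. Defaults $\alpha = \beta = 0.05$.

Chromatographic S/N is (peak maximum − noise median) / noise standard
deviation — the RMS noise convention, which is stable for short windows —
and the S/N-based LOD extrapolates the measured ratio linearly to
S/N = 3. The LOQ is the lowest calibration level at which every bias
entry is within ±20 % (boundary passes) and every CV entry is strictly
below 20 % (boundary fails), matching the wording of the acceptance
criteria.

## Cyclic accuracy and precision

Intra-day accuracy: within each day, each curve is held out in turn, the
model is refit on the remaining curves, and the held-out levels are
back-calculated; bias % is averaged over folds. Inter-day accuracy does
the same holding out whole days. The model *form* (weighting, order) is
fixed before the cyclic procedure and not re-selected per fold, mirroring
validation practice. Precision is the CV of back-calculated
concentrations — the reporting scale — within days (intra, averaged over
days) or across all nine replicates (inter); a switch to raw response
ratios is provided because the convention is genuinely ambiguous in the
field.

## Matrix effect, recovery, process efficiency

With set 1 = blank matrix spiked after extraction, set 2 = neat solution,
set 3 = spiked before extraction:
$ME\% = 100 \cdot \bar r_1 / \bar r_2$ per level,
$ER\% = 100 \cdot \bar r_3 / \bar r_1$, and
$PE\% = ME\% \times ER\% / 100$ computed from *unrounded* components (the
printed tables of the motivating study contain rounding inconsistencies
in exactly this product). RSD is computed across the three level means,
with 85–115 % acceptability windows. Ion enhancement $IE\% = ME\% - 100$
is classified substantial above +50 %, moderate between +25 and +50 %,
suppression below −15 %. Standard addition fits an unweighted line of
response on added concentration and reports the x-intercept magnitude
$a_0/a_1$; it is scale-invariant and unbiased under multiplicative noise.

## Stability

Each (analyte, concentration) is tested with one-way ANOVA per storage
factor — temperature pooling over time, time pooling over temperature —
significant at $p < 0.05$, no multiplicity correction by default
(Bonferroni optional). A limitation worth knowing: per-factor pooling has
good power when a whole factor level degrades (e.g. everything stored at
25 °C), but a *single degraded cell* (one temperature at one time point)
inflates the within-group variance of its own factor level and can escape
detection; a two-way layout with interaction would be needed to resolve
single cells reliably.

## Extraction DoE

The 3² design (250/500/750 µL methanol × 10/20/30 min sonication) is coded
−1/0/+1 and executed in seeded random order. The runs × analytes response
matrix is autoscaled (unit column variance — standard chemometrics when
response magnitudes span orders of magnitude, as they do across a
25-analyte panel) and decomposed by PCA with a sign convention (largest
loading positive) for reproducibility. An OLS regression of PC1 scores on
the coded factors, interaction included by default, quantifies each
factor's pull on the average extraction yield; on the balanced design the
coded columns are orthogonal, so single-factor and combined analyses give
identical coefficients.

## BAGI

The Blue Applicability Grade Index sums ten practicability attributes
graded 2.5 / 5 / 7.5 / 10 (total range 25–100, practical at ≥ 60). The
shade labels map low → 2.5, medium → 7.5, high → 10: with four low, four
medium and two high attributes this is the only mapping consistent with a
total of exactly 60 at the practicality threshold (medium = 5 would give
50).

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, so
the whole pipeline is testable without instrument data:

* **Truth curves** on the ratio scale, linear
  ($y = a_1 x + a_0$, defaults $a_1 = 1$, $a_0 = 0.05$) or saturating
  quadratic. The canonical quadratic scenario uses $a_2 = -0.04$ at unit
  slope, i.e. ~20 % signal depression at the top level — a clearly
  saturating detector response. Milder printed-table curvature (~5 %) is
  statistically undetectable on 54 points at realistic noise, so a
  generator stating it would make every order-selection test vacuous.
* **Noise** is multiplicative log-normal (responses stay positive), with
  absolute sd following $\sigma(y) = \text{base\_cv} \cdot
  \text{truth}(1) \cdot x^{k/2}$, i.e. $\operatorname{var} \propto x^k$;
  $k = 2$ and base CV 8 % are the faithful defaults (quadratic variance
  growth, replicate CVs in the 3–15 % band).
* **Day effects** are a shared multiplicative log-normal factor per
  working session (default sd 4 %), reproducing the moderately higher
  inter-day CV without destroying accuracy.
* **Effect multipliers**: ion enhancement (default 1.28) and recovery
  (default 0.93) act multiplicatively on the spike sets; stability decay
  is exponential per temperature and zero in the stable scenario.
* **Seeding**: one master seed; sub-generators derive child seeds
  deterministically from a purpose label, so outputs are byte-identical
  under a fixed configuration.

What a green test does *not* establish: the generator has no carryover,
no hematocrit effects, no background contamination, no inter-curve
correlation beyond the day factor (exposed as a parameter, not fixed),
and no isotope patterns — conclusions about those belong to the wet lab,
not to this package.

## Numerical choices

Tolerances: exact identities are asserted at 1e-9–1e-12; Monte-Carlo
checks use tolerances derived from their sampling variance at the stated
replicate counts. Degenerate inputs are handled explicitly: zero
variance at all levels is homoscedastic-with-warning; identical ANOVA
observations give $F = 0$ with warning; non-positive calibration or
standard-addition slopes are errors, not silent sign flips; the LOD of a
noise-free curve is 0. Simulation sizes in the test suite are scaled to
keep the default run in tens of seconds (e.g. 60-seed LOD envelopes, 300
null ANOVA draws); the envelopes were chosen from the stated generator,
not from observed test outcomes.
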