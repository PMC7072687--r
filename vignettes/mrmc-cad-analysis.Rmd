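---
title: "Methods: MRMC analysis of CAD reader studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MRMC analysis of CAD reader studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmcad)
```

## The problem

A reader study for a computer-aided diagnosis (CAD) system asks whether
clinicians interpret images better when the software's quantified
features are shown to them. In the thyroid-ultrasound setting that
motivates this package, every reader scores the malignancy potential of
every nodule twice — once without and once with the CAD display — on a
0–100 scale, and each nodule has a pathology-proven benign/malignant
label. Because the same readers rate the same cases under both
conditions, scores are correlated across readers, cases, and
reading conditions, and a paired multi-reader multi-case (MRMC) analysis
is required: naive per-reader tests ignore the shared case sample and
overstate certainty.

`mrmcad` implements the full analysis chain for such a study: reader
operating characteristics (ROC) summaries, the Dorfman–Berbaum–Metz (DBM)
jackknife ANOVA for the modality contrast, interobserver variability of
the raw scores, a directional contour match-ratio metric for the CAD
system's automatic nodule segmentation, and a latent-variable simulator
that generates study-shaped data for calibration and power work.

## Accuracy metrics

Two AUC estimators are deliberately kept side by side:

* **Wilcoxon (trapezoidal) AUC** — the proportion of
  (benign, malignant) case pairs ranked correctly, ties counting one
  half. It is distribution-free, exactly equal to the trapezoidal area
  under the empirical ROC points, and is the metric fed to the DBM
  jackknife: its U-statistic structure makes the mean of the jackknife
  pseudovalues reproduce the full-sample value exactly, which the test
  suite checks to 1e-10.
* **Binormal maximum-likelihood fit** — the two-parameter model
  $TPF = \Phi(a + b\,\Phi^{-1}(FPF))$ fitted by the Dorfman–Alf
  categorical likelihood. The fitted curve supplies the curve-shape
  metrics: partial AUC over a false-positive-fraction interval (default
  $[0, 0.3]$, i.e. specificity 70–100%), sensitivity at 95% specificity,
  and specificity at 95% sensitivity. These quantities need a smooth
  curve; reading them off the empirical steps at a 265-case resolution
  would quantise them badly.

The conventional binormal model is used rather than the "proper"
(hook-free) variant: the conventional likelihood is fully specified by
the rating categories alone, and the two families differ materially
only where conventional fits produce non-concave hooks, which the
0–100-scale data simulated here rarely do. Extending to a proper
parameterisation is an isolated change inside `fit_binormal()`.

### Numerical choices in the binormal fit

Scores with more than `max_bins = 20` distinct values are
quantile-binned on the pooled distribution; with 0–100 integer scores
this keeps the cutpoint count manageable while using essentially all the
ranking information. The likelihood is maximised by BFGS from three
starting slopes $b_0 \in \{0.5, 1, 2\}$ (intercepts matched to the
Wilcoxon AUC), taking the best optimum; cutpoints are parameterised by
log-increments so monotonicity is structural. On degenerate data —
perfect separation, or a fit drifting to an extreme
($|a| \ge 10$, $b \le 0.02$ or $b \ge 50$) — a half-count continuity
correction is added to the extreme category cells and the model refitted;
if that also fails, the returned curve is the symmetric one ($b = 1$,
$a = \sqrt{2}\,\Phi^{-1}(\widehat{AUC})$). Either fallback is flagged
`converged = FALSE` so downstream summaries can report it.

## The DBM modality test

The modality comparison jackknifes the accuracy metric over cases:

$$Y_{ijk} = c\,\hat\theta_{ij} - (c - 1)\,\hat\theta_{ij(k)}$$

for modality $i$, reader $j$ and deleted case $k$, then decomposes the
pseudovalue cube by a fully crossed three-way ANOVA with readers and
cases random. The default test is the Hillis form: denominator
$D = MS(TR) + \max(MS(TC) - MS(TRC), 0)$, statistic $F = MS(T)/D$ on
$t-1$ and $D^2 / \left(MS(TR)^2/((t-1)(r-1))\right)$ degrees of freedom.
The truncation and the denominator degrees of freedom are what keep the
test near its nominal size; the original untruncated denominator with
$(t-1)(r-1)(c-1)$ df is available behind `hillis = FALSE` because the
two give different p-values and a reader of older literature may want
the comparison. Confidence intervals for the two-modality difference
use the same denominator and df, so interval and test always agree.

Three companion analyses reuse the machinery:

* **Per-reader tests** (the shape of a per-reader AUC table): with one
  reader, cases are the only random factor, and the paired jackknife
  reduces to a one-sample t test on per-case pseudovalue differences
  with $c-1$ df. The original study does not name its per-reader test;
  this choice is the r = 1 special case of the same framework and is
  labelled as such in output.
* **Subgroup analysis** (junior vs senior readers, threshold 10 years,
  a reader at exactly 10 years counting as senior): the full DBM
  pipeline runs within each group, and the groups are compared on
  per-reader modality improvements with a two-sample Welch t test —
  again a documented choice, since the source design reports a group
  contrast without naming a method.
* **Power**: estimated by Monte-Carlo — simulate, test, count
  rejections — rather than a noncentral-F approximation, because the
  variance components a closed form would need are exactly what a
  planning user typically does not have; the simulator stands in for a
  pilot study.

## Interobserver variability

Score spread across readers is summarised per case as the sample
standard deviation (divisor $r - 1$; with 19 readers the distinction
from the population form is well below the reporting precision, but the
convention is fixed and tested). Per-case SDs are compared between
modalities with a paired t test over cases, overall and within each
truth class; the weighted decomposition
$\overline{SD}_{all} = (n_0 \overline{SD}_{benign} + n_1
\overline{SD}_{malignant})/c$ holds exactly under this averaging order
and is asserted in the tests. Class-conditional mean scores are compared
the same way on per-case reader means. A Wilcoxon signed-rank
alternative is selectable for the SD comparison.

## Contour match ratio

Segmentation quality is measured directionally: every vertex of the
physician-adjusted contour is matched if it lies within 1 mm of the
software-defined locus, and the match ratio is the matched fraction.
The locus is interpreted as the continuous closed polyline
(point-to-segment distance); a vertex-only mode is retained because the
original implementation's convention is unknowable, and vertex-mode
distances are never smaller, a property the tests enforce. Categories:
excellent at exactly 100% (within 1e-12 — "100%" is read literally),
satisfactory at 70% or above, poor below 70%. The boundary value 0.70
itself is assigned to satisfactory; the defining phrases "above 70%" and
"below 70%" leave it unassigned, so the closed lower bound is a
documented package decision. Match ratios depend on the vertex sampling
density of the contours, so reports record vertex counts.

The benign-vs-malignant comparison of successful (excellent +
satisfactory) fractions uses a Pearson chi-square two-proportion test
without continuity correction (Yates correction selectable). On the
published category counts this test yields a much larger p-value than
the study's printed one, which was likely computed on the underlying
continuous match ratios rather than the dichotomised categories; the
package reports which test it ran and does not attempt to match that
value.

## The simulator

`simulate_ratings()` draws from a simplified Roe–Metz latent model:

$$Z_{ijk} = (\delta_i + \tau_{ij})\,s_k + C_k + RC_{jk} + \varepsilon_{ijk}$$

with truth indicator $s_k$, case effect $C_k$ and reader-case effect
$RC_{jk}$ shared across modalities (this sharing is what makes the
design paired), modality-specific noise $\varepsilon$, and a
reader-by-modality skill term $\tau_{ij} \sim N(0, \sigma^2_{\tau R})$
perturbing the class separation $\delta_i$. The within-class latent
variance is normalised to 1
($\sigma^2_C + \sigma^2_{RC} + \sigma^2_\varepsilon = 1$), giving the
closed form

$$E[\overline{AUC}_i] = \Phi\!\left(\frac{\delta_i}
{\sqrt{2 + \sigma^2_{\tau R}}}\right)$$

used as the testing oracle for the whole pipeline. A single skill term
replaces the full eight-component Roe–Metz model deliberately: the
reduction is what admits this closed form, and the extra components add
nothing that the package's tests could check. Scores reach the 0–100
scale via `clamp(round(50 + 20 Z), 0, 100)`; the rounding and clamping
mimic a bounded rating scale's floor and ceiling effects and introduce a
small upward distortion of the realised AUC (about +0.003 at the default
settings), well inside the ±0.02 recovery tolerance the acceptance
tests use.

Default configuration (`default_study_config()`): 19 readers, 165 benign
and 100 malignant cases, two modalities with separations calibrated by
inverting the closed form at AUC targets 0.728 and 0.792,
$\sigma^2_{\tau R} = 0.04$, $\sigma^2_C = 0.6$, $\sigma^2_{RC} = 0.2$,
$\sigma^2_\varepsilon = 0.2$. The variance split is a package choice —
the motivating study's components are unpublished — set so that case
variation dominates (cases differ far more than readers disagree),
reader-average AUC standard deviation across readers is a few points,
and the DBM test is exercised away from degenerate corners. These
defaults are calibration anchors for the synthetic study, not estimates
of the real one.

What the simulator does *not* emulate: unequal class variances (real
malignant-score distributions are often wider), bimodal or
floor-concentrated score usage (readers who use only the low end of the
scale), correlation between a reader's skill and experience, and any
modality effect on interobserver spread (the variance components are
modality-shared by construction, so the real study's observed SD
reduction with CAD has no synthetic counterpart — tests of that
comparison construct shrinkage explicitly instead). Passing tests
therefore certify the statistical machinery on well-specified input,
not robustness to all real-data pathologies.

Contour pairs are simulated as a reference circle versus the same circle
with radius perturbed by smoothed Gaussian noise (circular moving
average, window 3) plus a constant offset. Radial perturbation of a
star-shaped polygon with positive radii cannot self-intersect, so
validity enforcement reduces to resampling nonpositive radii. The
file-generating front end uses a mixed-offset battery (0.2, 0.8 and
1.3 mm at 0.45 mm noise) so that all three match categories occur.

## Determinism and problem sizes

Every stochastic function takes its seed from its configuration object
and restores the global RNG state (`withr::with_seed`); identical
configurations give byte-identical CSV output. The statistical test
batteries use: 1000 replicates at the full study size for the type-I
error calibration of the DBM test (band checked: rejection in
[0.037, 0.064] at $\alpha = 0.05$, plus a Kolmogorov–Smirnov uniformity
check on the p-values at the 1% level); 200 replicates for AUC
calibration recovery (±0.02); 500 replicates per design for the
full-versus-pilot power ordering; and at least 100 random instances per
brute-force oracle comparison. These sizes keep Monte-Carlo error
comfortably below the tolerances being asserted while completing in a
few minutes.

## Known limitations

* Only fully crossed designs: every reader rates every case under every
  modality; missing cells are an error, never imputed.
* One score per (reader, case, modality) — no within-session revision
  history.
* Cases are treated as independent nodules; no patient-level clustering
  term (multiple nodules from one patient are modelled as exchangeable).
* No Obuchowski–Rockette correlated-error formulation, no split-plot or
  unpaired designs, and a single random-reader covariance structure.
* Confidence bands on individual ROC curves and covariate-adjusted ROC
  regression are out of scope.
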