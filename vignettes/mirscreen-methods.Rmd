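---
title: "Methods: whole-blood miRNA biomarker discovery and validation"
author: "mirscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-blood miRNA biomarker discovery and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mirscreen)
```

`mirscreen` re-implements, end to end, the analysis design of a
microarray-based whole-blood miRNA case–control biomarker study with an
RT-qPCR validation arm. This vignette is the package's account of the
underlying models, the tunable parameters and their defaults, the numerical
choices, and the limits of what the synthetic-data tests demonstrate.

## 1. The error model and the synthetic cohort

All stages assume the multiplicative–additive intensity model that
variance-stabilizing normalization is built for. For sample (array) $i$,
feature $k$, replicate spot $r$:

$$x_{ikr} = a_i + b_i\,e^{\mu_k + \delta_k\,[\text{case}_i] + \eta_{ik}}
  + \nu_{ikr} + \text{bg}$$

* $a_i,\ b_i$ — per-array affine calibration (defaults drawn uniformly from
  $[50, 200]$ intensity units and $[0.8, 1.25]$),
* $\mu_k$ — latent log-abundance, $N(7, 2^2)$ on the natural-log scale,
* $\delta_k$ — the planted group effect of a differential feature,
* $\eta_{ik} \sim N(0, 0.25^2)$ — log-scale biological/array noise, shared
  by the replicates of a spot,
* $\nu_{ikr} \sim N(0, 20^2)$ — additive measurement noise in intensity
  units,
* bg — a constant per-array background (default 30).

`synthetic_spec()` defaults encode the discovery-study conditions: 48 cases
versus 57 controls, a panel of 1100 miRNAs and miRNA star sequences, 7
replicate intensity values per feature per array, and 59 differential
features (13 up-, 46 down-regulated in cases) whose absolute natural-log
effects are uniform on $[\ln 1.35, \ln 3.12]$ — the fold-change range of the
most deregulated reported markers. Note the array physically carries 11
replicate spots per feature in this design; 7 is the number of intensity
values actually summarized per feature, which is what matters to the
analysis, so 7 is the default and the replicate count is configurable.

The noise magnitudes and calibration ranges are not reported by any table we
reproduce; they were chosen once as values typical for two-color-free
fluorescence microarrays (relative noise ~25%, additive noise small compared
with the median signal of $e^7 \approx 1100$) and are not tuned thereafter.
The generator records the full ground truth (per-feature effect, direction,
latent baseline, per-array calibration), which is what the recovery tests
and the false-discovery measurements run against. Intensities are truncated
at zero; with the default offsets and background the truncation is a
$>4\sigma$ event and has no practical effect.

The qPCR generator (`generate_qpcr_cohort()`) emulates the validation arm:
24 age-matched case–control pairs measured in duplicate wells for target
miRNAs plus the endogenous reference miR-16. Sample-level RNA-input shifts
are shared between target and reference (they cancel in $\Delta Ct$), and
pair-level baselines are shared within a pair (they cancel in the group
$\Delta\Delta Ct$ when pairs are complete). Defaults plant the two validated
markers at their reported relative folds (miR-202 up 19.38-fold, miR-718
down 5.44-fold), with 0.1-cycle well noise and 1-cycle biological spread.

## 2. Summarization and variance-stabilizing normalization

`summarize_replicates()` takes the median of the replicate spots per feature
per array and subtracts the per-array background. Whether the original
platform's background correction was per-spot or per-array is not
documented; a per-array constant is used (and is exactly right for the
generator). The median is shift-equivariant, so the order of median and
background subtraction is immaterial.

`fit_vsn()` fits the transform family

$$h_i(x) = \operatorname{arsinh}\!\Big(\frac{x - a_i}{b_i\,\lambda}\Big),$$

an affine per-array calibration composed with a common generalized-log
scale. Under the error model, the delta method gives transformed variance
$(m^2\sigma_\eta^2 + \sigma_\nu^2)/(m^2 + b^2\lambda^2)$ for a feature of
mean signal $m$, which is constant exactly when
$\lambda = \sigma_\nu / \sigma_\eta$ (in calibrated units) — that is the
sense in which the transform stabilizes variance.

The fit proceeds as follows, all steps deterministic given the input:

1. **Initialization** by robust moment matching against the first array
   (MAD ratios for scale, medians for offset) — exact on noise-free data.
2. **Alternating robust calibration.** Given $\lambda$, each array's
   $(a_i, \log b_i)$ is refit by BFGS against the per-feature row means,
   using only the `trim_fraction` (default 0.9) of features with the
   smallest residual sums — least-trimmed-squares robustness, so a minority
   of truly differential features cannot bend the calibration.
3. **Noise decomposition.** Between sweeps, the per-feature variance versus
   mean curve of the calibrated values, $v(m) = \sigma_\eta^2 (m - c)^2 +
   \sigma_\nu^2$, is refit: $\sigma_\eta$ and the residual common offset $c$
   from a profiled grid over $c$ with median-based slope estimates, and
   $\sigma_\nu^2$ as the median excess variance of the bottom intensity
   decile. The offset $c$ is folded back into the $a_i$ and $\lambda$ is
   updated to $\sigma_\nu/\sigma_\eta$.
4. **Variance-profiling polish.** Small residual biases in the common offset
   and $\lambda$ are removed by a final two-parameter minimization of the
   spread of the median per-feature variance across the ten intensity
   deciles (medians again keep differential features from steering this).

Two design points deserve emphasis. First, the calibration parameters are
identifiable only up to a common affine change; the reference-array gauge
($a_1 = 0$, $b_1 = 1$ before the offset absorption) fixes it, and the
parameter-recovery tests state their truth in that gauge. Second, a plain
least-squares fit of all parameters is degenerate — inflating every $b_i$
shrinks every residual — so the overall scale must come from the error
model itself. We estimate it from the variance–mean relationship
(method-of-moments, in the spirit of additive-multiplicative noise
estimators for microarrays) rather than from a profile likelihood: on this
family the likelihood's scale information is weak and its optimum can run
to degenerate corners, while the moment fit is stable, interpretable, and
directly targets the property the transform is for. On exactly noise-free
input $\sigma_\nu$ is not identifiable; the stabilizer is then skipped
($\lambda = 1$, flagged in `diagnostics$stabilizer_fitted`), leaving the
exact affine calibration untouched.

Negative background-corrected intensities are permitted throughout
(arsinh is defined on all reals); nothing is clipped. For large arguments
$h_i(x) \approx \ln 2(x - a_i)/(b_i\lambda)$, so the normalized scale is
natural-log-like, which is why differential-expression fold changes are
reported as $e^{|\Delta \text{median}|}$.

Normalization is fit once on the full matrix — the discovery-study
convention — and the classifier stage therefore sees a matrix whose
calibration used all samples. `cv_config(refit_normalization = TRUE)`
switches to per-training-fold refitting with held-out arrays mapped onto the
frozen fold transform, for strictly leakage-free evaluation; the default is
off to mirror the original design. The t-test filter, by contrast, is
*always* re-run inside each training fold.

## 3. Differential-expression screen

Per feature, an unpaired two-tailed t-test compares cases with controls.
Student's pooled-variance test is the default with Welch as an option (the
original software's flavor is not documented; both are exposed).
Zero-variance features are never dropped: equal means give $t = 0, p = 1$;
unequal constant groups give $p = 0$. Benjamini–Hochberg step-up adjustment
is applied across the panel (via `stats::p.adjust`; the test suite pins it
against a brute-force implementation of the step-up formula), significance
is `p_adjusted < alpha` (default 0.05). Fold change is
$\exp(|\text{median}_{case} - \text{median}_{control}|)$ with an up/down
direction (ties count as "up"; they occur only on degenerate data). The
per-feature AUC is the Mann–Whitney statistic with ties counted half,
folded to $\max(u, 1-u)$ so that discrimination accuracy is reported in
$[0.5, 1]$ for both directions, matching how the discovery tables report
AUC for up- and down-regulated markers alike. A panel-level Shapiro–Wilk
median p-value (`shapiro_median()`) is provided as the normality
diagnostic; constant features are excluded from the median rather than
given an arbitrary p.

The screen applies to any binary partition (e.g. tumor subgroups), not just
case–control; the table carries both raw and adjusted p-values since the
original subgroup analyses do not state which they used.

## 4. Signature cross-validation

`cv_evaluate()` implements filter-embedded repeated stratified k-fold
cross-validation. Per repetition a fresh fold assignment is drawn; per fold,
features are ranked by the raw t-test p-value *on the training portion
only* and the top $s$ features train one SVM per (kernel, cost). Kernels
are the e1071 set (linear, polynomial, sigmoid, radial); the cost grid
"0.01 to 10 in decimal powers" is $\{0.01, 0.1, 1, 10\}$. Folds are
stratified by class — with a 48/57 imbalance unstratified folds are
occasionally one-class, which is also why a degenerate-fold check with
refolding (then a hard error) exists for the unstratified option. When
`n_folds` exceeds the smaller class it is reduced with a warning.

Confusion counts are pooled across the folds of a repetition (not averaged
per fold — pooling is the natural reading of "mean accuracy per subset
size" and is insensitive to unequal fold sizes); accuracy, sensitivity
(case = positive) and specificity are then averaged over repetitions.
Per-sample held-out log-odds $\ln P(\text{case})/P(\text{control})$ come
from the SVM's sigmoid-calibrated probabilities, clamped to
$[10^{-6}, 1-10^{-6}]$ before the ratio, and averaged over the repetitions
in which the sample was held out. Ties in the filter ranking and in the
best-configuration choice are broken deterministically (feature id; grid
order), and the whole procedure is reproducible from (data, config, seed).

`permutation_null()` repeats the complete evaluation on label permutations
(default 20, a runtime compromise; the count is configurable) and reports
the percentile of the observed accuracy within the null. The subset-size
default grid is 10–300 by 10 (the original sweep's exact grid is not
stated beyond the sizes 30 and 240 being discussed); tests and the
end-to-end smoke configuration use reduced grids and 10 repetitions to keep
runtimes in minutes — with 100 repetitions, four kernels and the full grid
the computation is server-scale, which is a property of the design, not of
this implementation.

## 5. Comparative-Ct qPCR quantification

Replicate wells are averaged per sample and assay (`mean_ct()`; a spread
above 1 cycle flags the sample), $\Delta Ct$ is the target mean minus the
reference mean per sample, and
$\Delta\Delta Ct = \overline{\Delta Ct}_{case} -
\overline{\Delta Ct}_{control}$ gives the relative fold change
$2^{-\Delta\Delta Ct}$. Higher $\Delta Ct$ means lower expression, so
direction is "up" when $\Delta\Delta Ct \le 0$. Because a published fold is
conventionally reported as a magnitude plus a direction (e.g. "5.44-fold,
down-regulated"), results carry both the signed fold and
$\max(f, 1/f)$ with the direction label. With complete matched pairs the
geometric mean of per-pair folds equals the group fold exactly (an
algebraic identity the tests verify numerically); the arithmetic mean is
also reported since under noise it differs (upward, by convexity) and some
studies quote it. The group comparison is a two-tailed t-test on the
per-sample $\Delta Ct$ values (Student default, Welch optional), and the
single-marker ROC/AUC uses $-\Delta Ct$ as the score so that higher
expression scores higher. No amplification-efficiency correction is
applied — quantification is pure $2^{-\Delta\Delta Ct}$.

## 6. Numerical and interface choices

* Seeds: every stochastic operation takes an explicit seed, runs in a
  private RNG stream (the caller's `.Random.seed` is untouched), and the
  pipeline writes the resolved configuration and seed next to its outputs.
* Convergence: the calibration alternation stops on a relative parameter
  change below `tol` (default $10^{-4}$) or a relative trimmed-loss change
  below $10^{-4}$, warning (with diagnostics, returning best-so-far) after
  `max_iter` sweeps.
* TSV interfaces use decimal points, 6 significant digits (fold changes
  also rounded to 2 decimals in the report column), reject duplicate
  feature ids, ragged rows and non-numeric cells with positions, and
  round-trip losslessly at the written precision.
* The pipeline log records package and R versions, seeds, and per-stage
  summaries; a MANIFEST marks complete versus partial artifact sets.

## 7. What the synthetic tests do and do not show

The generator draws independent features with Gaussian log-scale noise and
a globally constant background. Real whole-blood arrays have correlated
miRNAs (co-regulation, shared hemolysis response), spatial and batch
artifacts, probe sequence effects and heavier-tailed noise — none of which
are modeled, deliberately (they are platform-specific and would dilute the
generator's role as a ground-truth oracle). Consequently: passing the
false-discovery test shows the screen's error control is implemented
correctly under its stated assumptions, not that 5% FDR holds on any real
cohort; the classifier's near-perfect synthetic accuracy shows the CV
plumbing has no leakage, not that real blood signatures reach such
accuracy (the reported real-data figures — mid-80s accuracy at $s = 240$ —
are far below the synthetic ceiling precisely because real data are
harder). Features whose latent intensity sits in the additive-noise regime
are compressed by the glog transform, so their normalized-scale group
difference underestimates the planted $\delta_k$; the recovery tests
therefore condition on adequately expressed features (latent baseline
$\ge 5$), and the screen's slightly reduced power at the very bottom of the
intensity range is expected behavior, shared by the original method.

Problem sizes used by the test-suite and acceptance computations — 50
replicate cohorts at full study dimensions for the FDR measurement, 10
CV repetitions with reduced subset grids for classifier checks, 200
simulated validation cohorts for the $2^{-\Delta\Delta Ct}$ unbiasedness
check — were chosen to make Monte-Carlo error small relative to the margins
being tested.

## 8. Known limitations

* One endogenous reference for qPCR (no multi-reference geometric
  averaging), no efficiency correction, no amplification-curve processing.
* No quantile/loess normalization alternatives and no import of proprietary
  raw array formats; the expression interface is plain TSV.
* The permutation test reports a percentile against a configurable but
  modest default null size (20), adequate for an overtraining check, not
  for precise null p-values.
* Student-vs-Welch and pooled-vs-averaged CV metric aggregation follow the
  documented defaults; where the original analysis was ambiguous both
  options exist but only the default is exercised by the acceptance tests.
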