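---
title: "Slice-wise whole-lung emphysema scoring: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-wise whole-lung emphysema scoring: models, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scoring problem

Emphysema destroys alveolar walls and appears on unenhanced chest CT as
abnormally low-attenuation lung. The conventional quantitative metric,
LAV950, is the fraction of lung voxels below −950 HU. It is simple and
objective, but attenuation thresholding also counts air trapping,
hyperinflation and image noise, and in cross-sectional cohorts it overlaps
substantially between people with and without visually evident emphysema.

`swescore` implements an alternative: a **slice-wise whole-lung emphysema
score (SWES)**. A convolutional regression network scores each axial slice
of each lung on a continuous 0–10 severity scale, and the per-patient score
is the average of all slice-lung scores weighted by the segmented lung area
of each slice:

$$\mathrm{SWES} \;=\; \frac{\sum_{s,\ell} \hat{y}_{s,\ell}\, A_{s,\ell}}
                           {\sum_{s,\ell} A_{s,\ell}},$$

where $\hat{y}_{s,\ell} \in [0,10]$ is the predicted severity of slice $s$,
lung $\ell$, and $A_{s,\ell}$ its lung cross-sectional area in mm². Both
lungs are pooled into a single weighted mean by default; whether the
aggregation should instead average the two per-lung weighted means is
genuinely ambiguous, so `compute_swes(..., per_lung = TRUE)` provides the
alternative. The two differ only when the lungs have very unequal areas.

## Annotation refinement (4 degrees to 10)

Training labels originate as ordinal grades 0–3 ("none" to "severe")
assigned to each *centimeter* of each lung. The package reproduces the
three-step label pipeline:

1. `blocks_to_slices()` replicates each centimeter grade over its
   `ceiling(10 / z_spacing_mm)` slices (a trailing partial centimeter keeps
   its own grade).
2. `median_z_filter()` smooths the block grades with a centered median
   window, 3 blocks wide by default — the minimal spike-removing window.
   The filter is applied repeatedly until the track is a *root signal*
   (unchanged by further passes). A single median pass is not idempotent in
   general; iterating to convergence makes the operation idempotent, which
   is the property downstream consumers rely on. Window ends shrink
   symmetrically, so the outermost blocks are fixed points and the output
   stays on the 0–3 scale.
3. `refine_to_ten()` increases granularity to a continuous 0–10 scale:
   grades map to anchors $\{0, 10/3, 20/3, 10\}$ placed at each block's z
   center, interpolated piecewise-linearly across slices and clamped to
   $[0, 10]$. Refinement of ordinal grades by many-reader image comparison
   and approximate sorting is a human workflow; anchor interpolation is a
   deterministic, reader-free surrogate that preserves block order, hits
   the scale endpoints exactly (all-0 → 0, all-3 → 10), and produces the
   same granularity for training. We make no claim that it reproduces a
   reader-derived refinement on real data.

## The slice regressor

`build_model(variant = "full")` is an 18-layer residual network — the
standard four-stage basic-block configuration (widths 64/128/256/512,
bias-free 3×3 convolutions each followed by batch normalization, 1×1
projection shortcuts at each down-sampling stage) — adapted to a single
input channel and ending in a single linear output neuron that emits the
slice severity. `variant = "reduced"` keeps the same stem/stage/head
structure at widths 8/16/32 with one block per stage (~20k parameters) for
desk-scale experiments. Because no deep-learning framework is part of the
package's dependency stack, the layers, backpropagation and the Adam
optimizer are implemented in the package itself, with compiled
im2col/col2im kernels; the backward pass is verified against numerical
differentiation in the test suite.

Preprocessing at prediction time uses only segmentation, contrast
windowing, cropping and resizing (`preprocess_slice()`):

* non-lung pixels are set to the window floor;
* HU is windowed at level −500 / width 1200 (clip to $[-1100, 100]$) and
  mapped affinely onto $[0, 1]$ — the window at which emphysema is
  conventionally displayed;
* the slice is cropped to the lung side's bounding box padded by 5% and
  resized bilinearly to the network input size;
* left lungs are mirrored horizontally so both sides share one
  orientation, halving the pose variation.

Training (`train_regressor()`) uses the reference regimen by default:
75 epochs, batch size 32, learning rate 0.001 exponentially decayed with a
power of 0.95 per epoch, an L2 penalty of $10^{-6}$ (implemented as
gradient shrinkage $\lambda w$, i.e. penalty $\tfrac12\lambda\|w\|^2$),
Adam with default moments, five random seeds, and selection of the epoch
checkpoint with the lowest validation loss. The split is always by
*patient*, never by slice, so no patient contributes to both training and
validation. Label imbalance is addressed twice: `oversample()` grows each
integer label bin to at least 25% of the largest bin (the imbalance is
meant to be *partially* compensated, hence not full balancing), and
`weighted_loss()` weights each sample's $(p-y)^2 + |p-y|$ term by the
inverse proportion of its label bin in the oversampled training set.

## LAV950, patient labels, repeatability

* `compute_lav950()` counts lung voxels **strictly below** −950 HU, a
  literal reading of "below"; boundary voxels at exactly −950 are
  excluded. The value is a fraction; reports conventionally print it ×100.
* `label_patients()` applies the two clinical cutoffs as strict
  inequalities: airway obstruction is FEV1/FVC < 0.7 (GOLD) and
  significant visual emphysema is sum-visual > 2.
* `rotation_repeatability()` draws three independent angles uniform on
  ±7.5° (x–y, x–z, y–z planes simultaneously), rigidly rotates the volume
  about its center with trilinear interpolation, fills out-of-field voxels
  with −1024 HU (air — so no spurious lung can appear), re-segments,
  re-predicts and re-aggregates, and summarizes original-vs-rotated score
  pairs as Bland–Altman bias and limits of agreement. The difference sign
  convention is original − rotated.

## Lung segmentation

Segmentation is deliberately a standard densitometric stand-in, not a
contribution: threshold at −320 HU, discard connected components touching
the in-plane image border (external air), keep the two largest remaining
components, assign sides by centroid x, and close with a 2-voxel ball to
fill vessels. A fused single component is split at the per-slice midline
with a warning. Tracheal air is not removed; at phantom scale this is
irrelevant, on real data it is a small positive bias on lung volume.
Per-slice areas are exact voxel counts times in-plane pixel area, so
summed areas times slice spacing reproduce the voxel-wise lung volume
identically.

## Validation statistics

The statistics mirror how competing emphysema scores are compared in
practice:

* `pearson_r()` — product-moment correlation with the t-transform p-value.
* `meng_test()` — comparison of two *dependent* correlations sharing a
  criterion (e.g. r(SWES, FEV1/FVC) vs r(LAV950, FEV1/FVC) in the same
  patients): Fisher-z difference scaled by
  $\sqrt{(n-3)/\big(2(1-r_{xz})h\big)}$ with
  $h = (1 - f\bar r^2)/(1-\bar r^2)$,
  $f = \min\{1, (1-r_{xz})/(2(1-\bar r^2))\}$,
  $\bar r^2 = (r_{xy}^2 + r_{zy}^2)/2$. The cap $f \le 1$ prevents a
  negative $h$ at extreme correlation patterns. No installed package
  provides this test, so it is implemented here and validated two ways: a
  transcription check of the closed form and a 5,000-replicate
  trivariate-normal Monte-Carlo (the z statistic must center on the
  closed-form value with unit spread, and its type-I error at equal true
  correlations must sit in [0.035, 0.065]).
* `auc()` / `roc_curve()` — Mann–Whitney AUC (midranks, ties count ½) with
  percentile-bootstrap CIs resampled at the *subject* level. Percentile
  (rather than BCa) intervals are used because nothing more specific is
  required of the bootstrap.
* `delong_test()` — paired AUC comparison via placement-value covariance.
  Implemented in vectorized form because the calibration experiments run
  thousands of replicates; unit tests pin it against both a brute-force
  placement oracle and pROC's independent implementation, exactly.
* `bland_altman()` — bias, SD with the n−1 denominator, bias ± 1.96 SD.
* Two-sided p-values are the default everywhere; Meng's test accepts
  `alternative = "one.sided"` for the directional hypothesis.

`validate_cohort()` composes these into the standard report: three
pairwise Meng comparisons per criterion (FEV1/FVC, and DLcoPred% where at
least 10 patients have it), and ROC/DeLong analyses of the scores against
significant visual emphysema and airway obstruction. Endpoints with fewer
than two subjects in either class are skipped with a warning, since the
DeLong covariance is undefined there.

## The phantom: what it emulates, and what it does not

No real CT cohort ships with the package, so every stage is validated on
synthetic phantoms with known ground truth (`phantom_spec()`,
`generate_phantom()`, `simulate_cohort()`):

* geometry: a soft-tissue body ellipse (+40 HU) in air, holding two
  disjoint ellipsoidal lungs; the lung z-semi-axis is 38% of the volume
  height so that ±7.5° rigid rotations cannot sweep the apices out of the
  reconstructed field;
* parenchyma: Gaussian attenuation, mean −850 HU, SD 40 HU, plus additive
  acquisition noise (SD 20 HU); all HU are rounded to integers as scanners
  store them;
* emphysema: per slice and lung, a severity-dependent fraction
  $f(s) = 0.06\,s$ of lung voxels (0% at severity 0, 60% at severity 10 —
  spanning the LAV950 percentages seen across population cohorts) is
  replaced by lesion voxels at −1000 ± 25 HU, grown as clustered blobs
  around random seed centers rather than i.i.d. voxels, because emphysema
  is regional and clustering gives the network a learnable texture;
* visual scores: mean true severity over the upper/middle/lower third of
  each lung, binned at cut points [0,1), [1,4), [4,7), [7,10] into grades
  0–3 (a narrow "none" band, then roughly equal bands); their sum over six
  regions is the 0–18 sum-visual analogue, and "significant emphysema" is
  sum > 2;
* spirometry: FEV1/FVC $= 0.80 - 0.035\,\bar s + \mathcal N(0,
  \text{coupling})$, clamped to (0.2, 1.0). Severity 0 sits near a healthy
  population mean (≈0.78) and high severity falls below the 0.7
  obstruction cutoff. `coupling = 0` makes the link exactly affine
  (correlation −1), which several contracts exploit;
* diffusing capacity: DLcoPred% $= 98 - 3.5\,\bar s + \mathcal N(0, 8)$,
  clamped to (20, 140), placing severity 0 near a healthy cohort mean
  (≈93 ± 14) and severe disease near ≈77 ± 20.

`simulate_records()` is the record-level twin for cohort-scale statistical
experiments: the SWES column carries true mean severity plus small
measurement noise, while the LAV950 column carries the severity-derived
low-attenuation fraction with *additional* independent noise (SD 2 on the
severity scale). This encodes the study regime in which a learned texture
score tracks the clinical reference more faithfully than threshold
densitometry does — the regime the validation statistics are designed to
detect — without claiming the phantom reproduces real effect sizes.

What the phantom deliberately lacks: airways, vessels, fissures, lobes,
reconstruction-kernel effects, scanner-specific noise texture, and any
claim that its image statistics match real cohort CT. Passing tests
therefore demonstrate that the pipeline's machinery is correct and
well-calibrated, not that the reduced network would reach any particular
accuracy on clinical data.

## Problem sizes and numerical choices

Desk-scale validation uses deliberately small problems chosen once:

* phantom grids 40×40×18 voxels at 6 mm spacing for cohort experiments
  (24 z-slices for rotation experiments), 20×20×(8–12) for densitometry
  oracle checks;
* training cohorts of 36 phantoms (26 train / 10 held out, ≥400 training
  slice-lung samples), network input 64×64 by default and 48×48 in the
  test suite, reduced variant, 10 epochs, one seed; the phantom's severity
  signal is low-frequency, so 48–64 pixel inputs retain it comfortably;
* statistical calibrations at 2,000 replicates (type-I error bands
  [0.035, 0.065] at α = 0.05), Monte-Carlo distribution checks at 5,000,
  power experiments at 100 replicates of 400-patient record cohorts.

Numerical conventions worth knowing:

* volumes are (x, y, z) arrays; z is the slice axis, increasing cranially;
  DICOM series are ordered by geometric z position, never file name;
* HU are clamped to $[-1100, 3100]$ on container construction (air
  calibration drift below −1024 is tolerated; corrupt values are not) and
  the clamp count is retained as an attribute;
* NIfTI stores voxel spacing in single precision, so spacing survives a
  NIfTI round trip to ~1e−7 relative accuracy; MetaImage and DICOM round
  trips are exact, and voxel values round-trip exactly in all three
  formats because phantom HU are integers;
* predictions are clamped to $[0, 10]$ — scores outside the annotation
  scale are meaningless downstream;
* `bootstrap_ci()` redraws resamples on which the statistic is undefined
  (e.g. single-class ROC resamples) and records how many redraws occurred;
* all stochastic components (phantom, cohort, oversampling, training,
  rotations, bootstrap) take explicit seeds and restore the caller's RNG
  state.

## Known limitations

* The reduced network trained on phantoms shows a small systematic offset
  under rotation repeatability: trilinear resampling smooths acquisition
  noise and lesion texture, which the model reads as slightly more severe.
  Full-scale training typically mitigates this class of effect with
  training-time augmentation, which the desk-scale configuration omits; the
  repeatability harness therefore validates exactness at zero angle, seed
  reproducibility, and the reporting pipeline, not a numeric agreement
  target.
* The full 18-layer variant is validated structurally (parameter tally,
  output shape, seeded initialization) and through shared layer code with
  the reduced variant; training it at 256×256 is outside desk scale.
* Segmentation equivalence with any specific clinical tool is not claimed,
  and the SWES magnitude depends on reconstruction parameters; scores from
  different imaging settings are not directly comparable.
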