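---
title: "Karyometric classification of pancreatic lesions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Karyometric classification of pancreatic lesions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoclass)
```

## The problem

Distinguishing intraductal papillary mucinous neoplasms (IPMN) from
pancreatic carcinoma (PC) — and both from the inflammatory background of
chronic pancreatitis (CP) — is difficult on histology alone, yet drives
very different clinical decisions. Quantitative histopathology
(karyometry) approaches this objectively: nuclei are segmented from
high-resolution grayscale images of H&E-stained sections, each nucleus
is reduced to a vector of shape and chromatin-texture features, and a
statistical classifier assigns each tissue a probability of belonging to
each diagnostic class.

`karyoclass` implements this analysis end to end: feature extraction
from segmented nuclei, a penalized multinomial classifier with
cross-validated tuning, a certainty score for each call, and a seeded
synthetic-cohort generator so that the whole pipeline can be exercised
and validated without access to patient images.

## The classifier

For classes $k \in \{\mathrm{CP}, \mathrm{IPMN}, \mathrm{PC}\}$ and a
feature vector $x \in \mathbb{R}^p$ the model is multinomial logistic
regression in the symmetric (reference-free) softmax parameterization,

$$
\Pr(y = k \mid x) \;=\;
\frac{\exp(\beta_{0k} + x^\top \beta_k)}
     {\sum_{m} \exp(\beta_{0m} + x^\top \beta_m)},
$$

so the log-odds between any pair of classes is linear in the features.
Because only 6–8 of the roughly 93 available karyometric features are
expected to carry signal, estimation maximizes the penalized
log-likelihood

$$
-\frac{1}{n}\,\ell(\beta_0, \beta) \;+\; \lambda \, P(\beta),
\qquad
P(\beta) = \sum_{j,k} |\beta_{jk}| \ \text{(lasso)} \quad\text{or}\quad
\sum_{j} \lVert \beta_{j\cdot} \rVert_2 \ \text{(group lasso)} .
$$

The lasso zeroes individual class-specific coefficients; the group lasso
removes a feature for all three classes jointly, so its selected set is
feature-wise by construction. Intercepts are never penalized. The
symmetric parameterization leaves the likelihood invariant under adding
a constant vector to all classes; the penalty resolves this redundancy,
which avoids designating an arbitrary reference class.

### Numerical choices

* **Solver.** Proximal gradient with backtracking line search on the
  full multinomial objective. Backtracking guarantees a monotonically
  non-increasing objective, which doubles as a test invariant. Iteration
  stops when the relative objective change falls below `tol = 1e-7`
  *and* the maximum Karush–Kuhn–Tucker residual of the iterate falls
  below `kkt_tol = 5e-6`; the extra KKT condition guards against
  premature stops on flat stretches of the objective.
* **Path.** 100 values of $\lambda$, log-spaced over four decades down
  from $\lambda_{\max}$, the analytically computed smallest $\lambda$
  with an all-zero solution (from the null-model gradient). Fits are
  warm-started along the path.
* **Standardization.** Features are centered and scaled to unit
  population standard deviation before penalization; coefficients are
  reported on the original scale. Constant features are dropped with a
  warning.
* **Cross-validation.** Stratified 5-fold by default: with cohorts of
  ~44 tissues, 10-fold would leave folds with 1–2 members of the
  smallest class. The criterion is the mean held-out multinomial
  deviance, $-2\,\overline{\log \hat p_{y}}$, or the held-out
  misclassification rate; exact ties on the CV curve are broken toward
  the larger $\lambda$ (the sparser model). If a training fold ever
  loses a class, folds are redrawn from a derived seed (at most 10
  times).

## Classification and certainty

A lesion is assigned the class with the highest probability; exact
argmax ties (measure zero, but reproducibility requires a rule) are
broken toward the fixed order CP < IPMN < PC. The *certainty* of a call
is

$$ C = \max_k p_k - \min_k p_k \in [0, 1], $$

zero exactly at the uniform distribution (assignment by chance) and one
at a degenerate distribution (perfect assignment). Calls with certainty
below a reporting threshold (default 0.55, a `uncertain_below`
parameter rather than hard-coded logic) are flagged as uncertain in the
output.

## The two-level analysis

**Tissue level.** Nucleus features from one tissue are pooled by the
sample average; the penalized model is tuned and fit on the pooled
vectors, and per-lesion probabilities, calls, certainties, training
accuracy, and the selected features are reported
(`run_tissue_level()`).

**Nuclear level.** Individual nuclei carry no diagnosis of their own,
so nucleus labels are first imputed by applying the tissue-level model
to each nucleus's raw features; a second penalized model is then tuned
on raw nucleus features against the imputed labels
(`impute_and_run_nuclear_level()`). Reported are agreement with the
imputed labels and the per-tissue majority vote against tissue truth.

**Generalization.** `evaluate_splits()` repeats a random 3:1
train/test split of the tissues (default 20 times), tunes on the
training part only, and reports mean held-out accuracy and mean
selected-feature count. Splits are stratified by class — plain random
quarters of a 12/16/16 cohort would regularly leave a class absent from
training, which the model cannot tolerate; stratification is therefore
a deliberate, documented strengthening of "random split".

**Discrimination.** `roc_analysis()` computes one-vs-rest ROC curves
per class, using that class's predicted probability as score, and
summarizes them by the macro-averaged AUC (trapezoidal; equal to the
concordance probability, which the tests verify by exhaustive pair
enumeration). A single multiclass AUC requires choosing a construction;
macro one-vs-rest is the declared choice.

## The feature catalog

* **Nuclear roundness** is the form factor $FF = P^2 / (4\pi A)$ with
  $A$ the in-mask pixel count and $P$ the boundary length. $P$ is
  measured on the ordered boundary-pixel chain with corner-corrected
  step weights (0.980 per axial step, 1.406 per diagonal step, −0.091
  per direction change). A plain marching-squares polygon overestimates
  the perimeter of digitized smooth shapes by ~6% (inflating $FF$ by
  ~12%); the corrected chain estimator is accurate to about 1% at the
  nucleus sizes used here, and its residual error decays with
  resolution (verified at radii 10/25/50).
* **Run-length texture.** In-mask intensities are quantized into
  $G = 16$ equal-width bins over $[0, 255]$ (conventional for run-length
  texture; the choice is configurable). Maximal runs of equal bin value
  are enumerated along each direction in a configurable subset of
  $\{0°, 45°, 90°, 135°\}$ (default $0°$ and $90°$), truncated at the
  mask boundary, giving counts $r(i, j)$ for level $i$ and length $j$
  with the conservation law $\sum_{i,j} j\,r(i,j) = N_p$ per direction.
  From the direction-summed counts with total run count $N_r$ over $D$
  directions: short run emphasis
  $\mathrm{SRE} = \frac{1}{N_r}\sum r(i,j)/j^2$, long run emphasis
  $\mathrm{LRE} = \frac{1}{N_r}\sum r(i,j)\,j^2$, run percentage
  $N_r / (D\,N_p)$ (each direction's runs tile the mask once, so
  $D\,N_p$ is the total run length and the ratio stays in $(0, 1]$),
  and mean run length $D\,N_p / N_r$, so run percentage × mean run
  length ≡ 1.
* **Lightly stained pixels.** The count of in-mask pixels with
  intensity strictly above a threshold (default 180 on the 0 = fully
  stained, 255 = light scale). The optical-density calibration behind
  "lightly stained" is not standardized; the threshold is a free,
  recorded parameter.
* Extras: area, perimeter, mean and SD of in-mask intensity, raw run
  count.

Two catalog conventions deserve flagging. Historical karyometry tables
report a scalar "run length matrix" feature in the 10–13 range and a
"run percentage" in the hundreds; neither is compatible with the
standard definitions above (the ratio form of run percentage is ≤ 1).
The package exports `rlm_summary` = mean run length as its best guess
for the former, and exports both the run-percentage *ratio* and the raw
run *count* for the latter. Both mappings are conventions of this
package, configurable, and deliberately excluded from image-tier
validation claims; the feature-tier generator simply treats the
published magnitudes as generative parameters for the dimensions of the
same names.

## Segmentation

The original semi-automated segmentation system is not reproduced.
`segment_nuclei()` is a simple, documented, deterministic stand-in:
global Otsu threshold (nuclei darker than background), 4-connected
component labeling, hole filling, and an area filter; each surviving
component is returned as a tight crop with its offset recorded.

## The synthetic-cohort generator

No images from the motivating study design are publicly deposited, so
the generator is a first-class module that emulates the study
conditions:

* **Cohort composition.** 12 CP, 16 IPMN, 16 PC tissues by default.
* **Feature tier.** Six informative features per tissue, drawn as
  independent normals with the per-class means and SDs of
  `informative_defaults()` (e.g. CP nuclear roundness 1.63 ± 0.04, PC
  lightly stained pixels 581.29 ± 227.73), embedded in a 93-dimensional
  panel whose remaining 87 dimensions are standard normal and
  identically distributed across classes. Only means and SDs of the
  informative features are published; independent normals are the
  minimal distributional assumption consistent with them, and that
  assumption is the generator's main simplification — real karyometric
  features are correlated (roundness and perimeter, the run-length
  statistics among themselves), and nothing here emulates that.
* **Nucleus tier.** Each tissue receives a latent mean vector from the
  class distribution; nuclei are drawn around it with SD equal to
  3 × the tissue-level SD (`nucleus_dispersion`). The within-tissue
  dispersion of nuclei is not published at all; 3× is a deliberate
  stand-in chosen so that within-tissue variance dominates the
  between-tissue variance of the mean — the regime in which pooling by
  averaging is actually useful — and it is configurable. Nuclei counts
  per tissue are normal(180, 22), rounded, truncated at 1.
* **Image tier.** `render_nucleus()` rasterizes an elliptical mask and
  fills it with a base staining level plus Gaussian-smoothed random
  chromatin blobs; the brightest target fraction of in-mask pixels is
  lifted above the light threshold. Class presets solve the axis ratio
  analytically from the class's target form factor (Ramanujan perimeter
  inversion) with a small per-class multiplicative correction fitted
  once by `scripts/calibrate_presets.R` to compensate rasterization
  bias, and set the light fraction to the target light-pixel count over
  the expected mask area. The renderer makes no attempt at
  photorealistic H&E appearance; it exists so that extracted features
  respond monotonically and quantitatively to known generating knobs.

Because the generator defines the study conditions, passing tests show
that the *pipeline* behaves correctly under those conditions — feature
recovery, accuracy, AUC, certainty separation. They do not show that
real pancreatic cohorts are this cleanly separable: the independence
assumption, the absence of feature correlations, of imaging artifacts,
and of class-overlapping subpopulations all make the synthetic task
somewhat easier than histology.

## Conventions for degenerate cases

* Argmax ties → earlier class in CP < IPMN < PC (deterministic).
* Empty feature-tier cohort request → empty, schema-complete table;
  an empty nucleus-tier cohort is an error (no counts can be drawn).
* Masks with fewer than 8 pixels are rejected as degenerate by the
  shape extractor; nuclei smaller than 8 px diameter are refused by the
  renderer.
* A whole-data replicate with zero misclassified lesions counts as
  exhibiting certainty separation (the correct-vs-incorrect comparison
  is vacuously satisfied); with the default generator most replicates
  are error-free, so this convention matters and is applied
  consistently in tests and reports.
* Accuracies are reported as exact fractions of the cohort analyzed;
  no rounding convention is imposed on ratios like 39/44.

## Problem sizes used in validation

The shipped validation suite uses 50 replicate whole-data cohorts
(12/16/16 tissues each) for training accuracy, feature recovery, AUC,
and certainty separation; 10 replicate cohorts × 20 splits for held-out
accuracy; 2000-tissue single-class cohorts for generator moments; and
reduced cohorts (≤ 25 nuclei per tissue, ≤ 20 noise features) for the
nuclear-level property tests, whose full-size version is
computationally heavy but statistically identical in structure.

## Known limitations

* Three-class contract: arbitrary class sets beyond {CP, IPMN, PC} are
  not supported by the pipeline layer (the solver itself is K-class).
* No elastic-net mixing, sample weights, or coefficient inference.
* The image tier validates feature extraction, not biology: its
  chromatin texture is statistically convenient, not histological.
* Tissue-level and nuclear-level analyses share the feature schema; a
  cohort whose nuclei were extracted with different parameters (gray
  bins, directions, threshold) from the model's training data will not
  be flagged automatically — the CLI's JSON sidecar and manifest exist
  to catch this by inspection.
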