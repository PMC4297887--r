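---
title: "Predicting conversion from CIS to multiple sclerosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting conversion from CIS to multiple sclerosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisconvert)
```

## The clinical problem

A clinically isolated syndrome (CIS) is a first episode of neurological
symptoms suggestive of demyelination. Roughly a third of CIS patients
experience a second clinical attack within a year — the event that
establishes a diagnosis of clinically definite multiple sclerosis (CDMS) —
while others remain attack-free for decades. `cisconvert` implements a
single-patient prediction pipeline for this conversion: from one baseline
brain scan (a binary white-matter lesion mask with matched PD- and
T2-weighted volumes, plus the mask resampled to a standard template space)
and four clinical/demographic variables, a maximum-margin classifier
predicts whether the patient will convert within a 1- or 3-year horizon.

Because the underlying patient scans are not publicly available, the
package also contains a first-class synthetic cohort generator that
emulates the documented cohort structure, so every stage of the pipeline
is testable end to end and all empirical statements in the test suite are
computed, not transcribed.

## The twelve features

Eight features are computed from the lesion masks and intensity volumes
(native-space operations use the scanner-space mask; distance-based
operations use the template-space mask, where a fixed anatomical centre is
comparable across patients):

1. **Lesion count** — number of 18-connected components of the native
   mask. The 18-neighbourhood joins face- and edge-adjacent voxels and
   excludes corner-only contacts.
2. **Lesion load** — total lesional volume in voxels.
3. **Mean PD intensity** of lesional voxels.
4. **Mean T2 intensity** of lesional voxels.
5. **Mean distance to the brain centre** — average Euclidean distance, in
   millimetres, of all template-space lesional voxel centres from the
   central voxel of the template lattice.
6. **Central-cube presence** — 1 if any lesional voxel centre falls in a
   closed 1 cm³ cube around the template centre (a proxy for involvement
   of midline structures such as the corpus callosum).
7. **Minimum centroid distance to the vertical axis** — for each lesion,
   the unweighted centroid's in-plane (left–right × anterior–posterior)
   distance to the inferior–superior line through the template centre;
   the minimum over lesions.
8. **Size profile** — counts of small (1–15 voxels), medium (16–36) and
   large (37+) lesions. This is *one* feature spanning three dimensions:
   selection always moves its three columns together.

The four clinical features are age (years, raw), gender (1 = male,
0 = female), CIS presentation type (1 = optic neuritis, 2 = spinal cord,
3 = brainstem, 4 = other; an arbitrary ordinal coding used as-is) and
baseline EDSS (raw, 0–10 in 0.5 steps). Together the twelve features span
a 14-column design matrix.

### Numerical conventions

Several conventions are under-determined by the clinical description and
were fixed as package design choices:

* **Centre voxel** = index `floor(dim/2)` per axis (0-based): the only
  definition computable from the lattice alone. Features 5–7 use the same
  centre.
* **Distances are in millimetres**, derived from voxel sizes. Native
  voxels are strongly anisotropic (e.g. 0.9375 × 0.9375 × 3 mm), so
  index-space distances would be geometrically wrong.
* **Cube membership** uses a closed interval, |Δ| ≤ 5 mm per axis, on
  voxel centres.
* **Centroids are unweighted** voxel-centre means (the feature is defined
  on the binary mask, not on intensities).
* **Component labelling** is first-seen in raster order (first array axis
  fastest), making all tie-breaks deterministic.
* **Empty masks are a hard error** everywhere: the cohort definition
  requires at least one visible lesion per included patient.
* The third array axis is assumed inferior–superior; the in-plane axes
  are the first two.

## The classifier and its evaluation

The classifier is a soft-margin SVM with polynomial kernel
$K(\mathbf{x}, \mathbf{y}) = (\mathbf{x}^\top \mathbf{y} + c)^d$, $d \in
\{1,\dots,5\}$ — degree 1 is the familiar linear kernel; the cap at 5
guards against overfitting. The dual problem is solved by sequential
minimal optimisation (SMO), implemented in compiled code with a
deterministic working-pair heuristic, an iteration budget of $10^7$, and
explicit convergence reporting (a non-converged fold is flagged, never
silently accepted). Kernel offset $c = 1$ and margin penalty $C = 1$ are
the defaults of the MATLAB functions the original analysis used, making
them the most faithful reconstruction; both are exposed in `svm_spec()`.
Training columns are standardized per training set (zero mean, unit
variance, computed from training rows only and applied to test points;
zero-variance columns get scale 1). A decision value of exactly zero is
classified as non-converter — the deterministic, conservative choice.

One solver detail deviates from a naive reconstruction: the SMO
minimal-progress threshold is Platt's recommended $10^{-3}$ rather than a
tighter value. With a near-zero threshold the solver performs thousands of
insignificant pair updates per fit (7× slower) while the decision values
change by less than $10^{-2}$ — confirmed against an independently fitted
reference implementation in the test suite.

Evaluation follows the original design for imbalanced cohorts:

* **Balanced bootstrap**: all members of the minority class are retained
  and an equally sized subset of the majority class is drawn uniformly
  *without replacement* (the sampling statement "selected from the whole
  set … to match the group size" implies distinct patients). With 22
  converters / 52 non-converters this gives cohorts of 44; with 31/39,
  cohorts of 62.
* **Leave-one-out cross-validation** on each balanced cohort: train on
  n − 1 (43 of 44), classify the held-out patient, rotate. The slight
  21-vs-22 within-fold imbalance affects both classes symmetrically and
  is accepted unweighted.
* **B = 100 bootstraps** by default; each metric (accuracy, sensitivity,
  specificity, PPV, NPV — all percentages; ratios with zero denominator
  are NaN, never 0) is summarised by its mean, 95% percentile CI
  (2.5th/97.5th percentiles of the B values — the only interval
  computable from the bootstrap values alongside the reported range) and
  min–max range.

A subtlety worth knowing when interpreting null experiments: LOO-CV on a
balanced cohort is slightly pessimistic under the null hypothesis,
because the held-out patient's class is always the training minority.
At n = 44 the effect is small (a few points below 50%); at very small n
it grows. The null-calibration tests therefore run at the design size
n = 44.

## Feature-combination search

`forward_select()` implements the greedy wrapper search: evaluate every
feature alone (each candidate subset is scored at every degree and
represented by its best degree), keep the best, then repeatedly evaluate
adding each remaining feature, stopping as soon as the best enlarged
model's mean bootstrap accuracy does not *exceed* the incumbent's (a
plateau stops the search — the literal reading of "does not increase
anymore"). `exhaustive_search()` scores every one of the $2^{12} = 4096$
subsets (the empty model is enumerated but not evaluated). Design choices
where the original protocol is silent:

* **Bootstrap subsamples are reused** across all candidate subsets within
  one search: a paired comparison that removes resampling noise from
  selection decisions.
* **Degree selection**: each subset is represented by its best degree;
  ties go to the lower degree, then to the smaller subset, then to
  canonical feature order — lower complexity first, echoing the
  overfitting concern that motivated the degree cap.
* The exhaustive search's multiple-comparisons hazard (4096 models on one
  small cohort) is surfaced as a warning and a `note` field; no
  statistical correction is applied, matching the original analysis.

By construction the exhaustive optimum's accuracy can never fall below
the forward result's on the same seeds (greedy dominance), and a feature
duplicating information already selected is never added — both are
verified as properties in the test suite, including a constructed
XOR-style interaction where greedy search provably stalls and the
exhaustive search is strictly better.

## The synthetic cohort generator

`generate_cohort()` emulates the documented cohort; its defaults *are*
the stated world and are not tuned to test outcomes:

* **Class sizes** 22/52 (1-year) or 31/39 (3-year).
* **Lesion count** per patient: negative binomial truncated to ≥ 1
  (µ = 13.98, size = 0.983), fitted so the ≤ 3 / 4–10 / > 10 lesion bins
  match the published cohort composition (14/74, 23/74, 37/74).
  Overdispersed counts are standard for lesion data.
* **Lesion size**: geometric on {1, 2, …} truncated at 200 voxels with
  p = 0.03, which populates the three size bins roughly equally, as
  described for the original data.
* **Lesion shape**: a random-walk blob grown voxel by voxel from a seed
  voxel, guaranteeing a single 18-connected (indeed 6-connected)
  component of the requested size.
* **Placement**: 70% of lesions around a periventricular ring (radius
  0.25 × the in-plane brain semi-axis) inside an ellipsoidal brain
  support, 30% uniform; placement centres are kept ≥ 8 mm apart to limit
  confluence, though merging can still occur (as in real masks).
* **Intensities**: background ~ Normal(100, 10), lesions hyperintense by
  +30 on both PD and T2. No intensity statistics were reported for the
  original data; these arbitrary defaults are configurable knobs
  (`background_mean`, `contrast`, `noise_sd`), which is exactly why mean
  lesion intensity carries no planted class signal by default.
* **Template mask**: the same lesion voxels mapped by a fixed
  scale-about-centre affine to a 91 × 109 × 91 lattice at 2 mm.
  Deformable registration is deliberately not emulated — it is irrelevant
  to the downstream mathematics being tested.
* **Planted converter effects** (standardized shifts, converters minus
  non-converters): lesion load +1.0, lesion count +0.8, axis distance
  −0.8, age −0.5, gender −0.5 (female predominance), plus an enriched
  spinal-cord presentation probability. Directions are the documented
  group differences; magnitudes are generator design choices with the
  1.0 SD lesion-load shift as reference.
* **Reproducibility**: one master seed, split into per-patient streams by
  a counter scheme, so cohorts are bit-identical across runs and
  independent of generation order.

What the generator does *not* emulate: MRI physics (bias fields, partial
voluming), brain anatomy beyond an ellipsoidal support, deformable
registration, and realistic feature correlations beyond those induced by
the count/size/placement model. A green test on synthetic data therefore
establishes that the *machinery* (features, resampling, classifier,
search) behaves as specified — not that any particular accuracy level
will be reached on clinical data. For studies of the selection machinery
itself, `simulate_feature_cohort()` bypasses image synthesis entirely and
produces exactly independent Gaussian features with named planted shifts
— something no image-derived feature set can be.

The Table-1 bin calibration is asserted on the *drawn* per-patient counts
(`draw_lesion_counts()`): at the reduced lattice sizes used in tests,
lesion confluence would otherwise confound the count distribution with a
lattice artefact.

## Scaling in the test suite

Full-scale runs (B = 100, degrees 1–5, twelve features, default lattices)
complete in well under an hour on one CPU. The shipped tests scale down
where the property under test is scale-free: B = 20 for stochastic
acceptance checks (as the acceptance protocol itself prescribes), reduced
image lattices (~24–32 voxels per axis) for cohort-level simulations, and
degree-restricted searches for replicate studies (a mean-shift signal is
linear, so degree 1 suffices for recovery experiments). The Monte-Carlo
replicate counts (100 seeds) are kept at full size.

## Known limitations

* LOO-CV accuracy of a *selected* model is positively biased; nested
  cross-validation, which would remove the bias, is out of scope here as
  it was in the original analysis.
* The CIS-type coding is an arbitrary ordinal; permuting it can shift
  accuracies slightly. No one-hot alternative is provided.
* EDSS enters raw; no transformation was documented.
* The NIfTI reader covers the single-file little-endian NIfTI-1 subset
  the package writes (plus nibabel output); it is not a general-purpose
  neuroimaging I/O layer.
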