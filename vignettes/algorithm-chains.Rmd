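---
title: "Algorithm chains for microscopy image classification and annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Algorithm chains for microscopy image classification and annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imgchain)
```

## The problem

Biological image classification rarely has a single best recipe: which
texture, moment or object features discriminate, and which classifier
exploits them, depends on the imaging modality, the structures of interest
and the amount of training data.  `imgchain` treats the whole recipe as the
unit of model selection: an **algorithm chain** is an ordered list of feature
extractors, an optional cascade of feature selectors and exactly one
classifier.  Candidate chains are compared empirically by repeated
cross-validation on the user's own labeled data, and the winning chain is
trained and saved as a reusable model.  Chains that share algorithm types but
differ in parameters are distinct candidates, so parameter variants are
compared the same way as algorithm variants.  The winner is the best among
the compared chains, not a global optimum — the package deliberately has no
hyperparameter search loop.

Models apply at two granularities:

* **whole images** — each image is one sample (classification / multi-label
  annotation);
* **regions of interest (ROIs)** — each sample is the fixed-size patch of
  `(2rx+1) x (2ry+1) x (2rz+1)` voxels around a coordinate, so a trained
  model can annotate every voxel of a new image by sliding-window
  classification.

## Data model and conventions

Images are held as `image_volume` objects: numeric arrays indexed `(x, y, z)`
with `nz = 1` for 2D images; a k-page TIFF loads as `nz = k`.  Intensities
are kept as the integer sample values of the file (no rescaling to `[0, 1]`);
extractors define their own normalization.  For multi-channel images one
channel is selected at read time (fluorescence workflows typically classify
on the channel carrying the relevant stain, e.g. the GFP/green channel);
`"all"` averages channels.

Coordinates are 0-based `(x, y, z)` voxel indices throughout.  Two external
landmark formats are supported with their native conventions: Vaa3D `.marker`
files are 1-based (shifted by −1 on read, +1 on write) and ImageJ ROI
archives are treated as 0-based.  ImageJ rectangle and oval ROIs are reduced
to their integer centers; whether the original workflows used area ROIs as
masks is unknowable from the outside, and centers are what the ROI-patch
model consumes.

Training labels reach the package in three ways: a *target file* mapping
image names to one or more labels; a *directory tree* with one subdirectory
per class; or *ROI files* (ImageJ zip / Vaa3D marker) whose base file name is
the class (`pos.zip` → class `"pos"`).  Directory loading is deterministic
(sorted by class, then file name).

## The anisotropic 3D wavelet texture feature

Confocal stacks resolve much more finely in x–y than in z, and a full 3D
wavelet transform would also grow the feature count cubically in the patch
side.  The package's 3D texture feature therefore treats z differently from
x–y.  For the patch around a voxel:

1. the `2rz+1` slices are collapsed into one plane with Gaussian weights,

   $$P(x, y) = \sum_{z_i = -r_z}^{r_z} w(z_i)\, I(x, y, z_i), \qquad
     w(z_i) \propto e^{-z_i^2 / 2\sigma^2},\ \textstyle\sum w = 1,$$

   so the middle slices weigh heaviest (default `sigma = max(rz, 1)/2`,
   exposed as a parameter);
2. a `levels`-level 2D Haar discrete wavelet transform of `P` is taken
   (default 2 levels, i.e. two dilation scales);
3. all coefficients are returned, flattened in a fixed, documented order
   (coarsest LL block first, then per level — coarsest first — LH, HL, HH,
   each block column-major).  Saved models depend on this order being
   stable.

The feature length equals the padded patch area — quadratic in the patch
side, independent of `rz` — and `rz = 0` degenerates exactly to the 2D Haar
features of the center slice.  Because the z-collapse and the 2D transform
are both linear, collapsing first and transforming once is identical to
transforming each slice and summing; the tests verify both readings agree.

Numerical choices:

* **Orthonormal scaling** (`1/sqrt(2)` filters).  For power-of-two inputs the
  transform then conserves energy exactly, which gives a clean test oracle.
* **Padding.**  ROI patches have odd sides (`2r+1`), while the Mallat layout
  needs each level to see even block sizes.  Sides are padded up front to the
  next multiple of `2^levels` by *edge replication*.  Replication (rather
  than zero-fill) keeps a constant patch constant, so constant inputs have
  exactly zero detail coefficients at every geometry, and linearity of the
  feature map is preserved; zero-fill would manufacture artificial edge
  detail at the pad boundary.
* Decomposition depth is capped at `floor(log2(min side))`; deeper requests
  are an error rather than a silent truncation.

For whole images of varying size the raw coefficient vector is not usable
(its length would depend on the image), so a second pooling mode returns per
subband and level the mean and standard deviation of absolute coefficients —
`2(3·levels + 1)` values regardless of image size.  Which pooling a chain
uses is a configuration field.

## Morphological and differential extractors

* **2D Hu moments (8 values).**  The seven classical Hu invariants computed
  from intensity-weighted, scale-normalized central moments, plus Flusser's
  third-order skew invariant as the documented 8th value.  Invariant to
  translation, scaling and rotation; moments are computed on raw gray values,
  not on a binarized mask.
* **3D moment invariants (8 values).**  The field reports "8 3D Hu moments"
  without published formulas, so the package documents its own fixed set:
  the three second-order rotation invariants `J1`, `J2`, `J3` of the
  normalized second-moment matrix, plus five translation- and
  scale-invariant central-moment summaries (off-diagonal energy, the three
  third-order energy groupings, and the squared norm of the third-order
  "gradient" vector).  All eight are exactly translation-invariant; `J1..J3`
  are additionally rotation-invariant.
* **Zernike moments (default 20).**  Magnitudes `|A_nm|` of projections onto
  the complex Zernike polynomials over the unit disk centered on the
  intensity centroid, with disk radius equal to the largest
  centroid-to-corner distance so every pixel participates.  Enumeration is
  `n` ascending, `m >= 0` ascending with `n − m` even; magnitudes are
  rotation-invariant.
* **Object statistics (7 values)** after Otsu (or fixed) thresholding and
  8-/26-connected component labeling: object count; mean and variance of
  object sizes; mean and variance of the centroid distances to the image's
  intensity center of mass; largest/smallest size ratio; furthest/closest
  distance ratio.  Variances are population variances so a single object
  yields 0, not `NA`.  Component centroids are binary, the image reference
  point is intensity-weighted; distances are Euclidean in voxel units
  (anisotropy ignored).  **Object territory** is the total foreground voxel
  count.
* **Differential features.**  Per Gaussian scale: smoothed first derivatives,
  the Laplacian, and the eigenvalues of the Hessian (sorted per voxel).
  Kernels are sampled Gaussian derivatives normalized so polynomial inputs
  respond exactly (a ramp differentiates to 1, a parabola twice to 2);
  borders replicate edges.  On tube-like (neuronal) structures one Hessian
  eigenvalue dominates the others in magnitude, which is what makes these
  features ridge detectors.  Pooling is either map statistics (whole images)
  or values at a coordinate (ROI mode).

Every extractor's output length is a pure function of its configuration,
never of image content; the chain engine enforces this contract at run time,
also for user plugins.

## Feature selection

The Fisher criterion scores each feature column

$$\mathrm{score}_j \;=\;
  \frac{\sum_c p_c\,(\mu_{cj} - \mu_j)^2}
       {\sum_c p_c\, s^2_{cj} + \varepsilon},$$

with class proportions `p_c`, class means, the grand mean and population
class variances; `eps = 1e-12` lets zero-within-variance columns rank on top
without division by zero.  Selection keeps the `n_keep` best columns in their
original order, ties toward the lower index.  Multiple selectors cascade:
each stage re-scores the survivors of the previous stage.  Crucially,
selectors are fitted **inside each cross-validation training fold**, never on
the full set — fitting them globally would leak held-out information into the
accuracy estimate, and the test suite contains an explicit no-leakage check.

## Classifiers

Five kinds behind one train/predict contract: `knn` (default `k = 3`),
`svm-linear` (linear kernel, regularization `C = 1`), `naive-bayes`,
`decision-tree` and `random-forest` (100 trees, reproducible under the chain
seed).  The SVM, naive Bayes, tree and forest are backed by the standard R
implementations (e1071, rpart, randomForest); kNN is implemented in the
package because its tie-break is part of the contract: on a vote tie the
label of the single nearest neighbor among the tied classes wins.  Features
are used unscaled by default; an optional per-column z-scaling (fitted on
training rows) is a classifier option, since distance-based kinds are
sensitive to column scale.  Prediction validates that probe columns carry
exactly the training columns' provenance tags.

## Evaluating and comparing chains

The default protocol is five-fold cross-validation repeated five times with
reshuffling — 25 train/test runs — reporting the mean and the *population*
variance of the 25 recognition rates (the N vs N−1 ambiguity is resolved
toward N).  Folds are stratified to preserve class ratios; a class smaller
than the fold count clamps the folds with a warning.  Fold assignments are
derived deterministically from the protocol seed and the labels alone, so
every chain under comparison sees identical partitions (paired comparison);
the per-run fold-membership hashes are recorded in each result so pairing is
verifiable.  Ranking is by mean accuracy, ties broken by fewer selected
features (preferring compact models), then by chain order.  Reports are
written as JSON plus a CSV summary.

Trained models serialize to a single versioned archive; a reloaded model
produces identical predictions, and loading anything that is not a model
archive (or a different format version) is a clean data error.

## Annotating new images

* **Sliding window.**  A ROI model is applied on the lattice
  `{0, interval, 2·interval, ...}` per axis; `interval = 1` annotates every
  voxel.  Border sites are annotated using zero-filled patches (matching the
  dark background of fluorescence imagery) rather than skipped.
* **Local maxima.**  In largely dark 3D images most voxels are uninformative,
  so decisions can be restricted to grayscale local maxima: voxels whose
  intensity equals the morphological dilation of the image at that position
  (cubic structuring element, default radius 1) and exceeds an intensity
  floor (default Otsu).  Within a constant plateau only the lexicographically
  smallest coordinate is kept — adjacent maxima necessarily share one
  intensity, so plateaus are exactly the connected candidate components.
* **Counting.**  Positive decisions are moved by mean shift — each point
  iterates to the intensity-weighted centroid of its spherical neighborhood
  until the displacement falls below 0.5 voxel or 50 iterations (constants
  exposed as arguments) — then merged by single linkage at the merge radius;
  the cluster count is the object count.  Centers export as Vaa3D markers.
* **Multi-label annotation** is formulated as independent binary
  present/absent problems, one model per label; the consolidated report lists
  every image with its label set, which may be empty.

## Synthetic data

The generators produce, deterministically under a seed, the study conditions
used by the test suite and the acceptance script — written in the real
external formats (TIFF stacks, marker files, directory trees) so the IO paths
are exercised rather than bypassed.

* **Blob volumes** emulate a nucleus-channel confocal stack: by default
  64×64×16 voxels, 20 anisotropic Gaussian blobs (`sigma_xy = 2.5`,
  `sigma_z = 1.5`, mirroring coarser z sampling), peak 180 on clipped
  Gaussian noise (s.d. 5), centers at least `4·sigma_xy` apart so each blob
  is resolvable, with exact centers returned as ground truth.  Infeasible
  placement requests fail rather than silently crowding blobs.
* **Texture sets** are two classes of sinusoid-modulated noise images (32×32,
  10 per class) differing in spatial frequency (2 vs 8 cycles).  The `"easy"`
  preset keeps noise low (s.d. 2) and fixes the sinusoid phase, so images
  within a class differ by noise alone; at generation time it asserts its
  separation guarantee — the distance between class centroids in Haar-stat
  feature space exceeds 10× the intra-class spread — which is what makes
  "mean CV accuracy 1.0" a *constructed* property rather than an empirical
  hope.  The `"hard"` preset adds heavy noise (s.d. 40) and a uniform random
  phase per image.
* **Tube images** provide a bright ridge at a chosen orientation and width
  for the Hessian-feature tests; with zero noise, orientations 90° apart give
  exactly transposed images.

What the generators deliberately do **not** emulate: realistic confocal point
spread beyond axial anisotropy, intensity falloff with depth, autofluorescent
background structure, touching/overlapping nuclei, or class-correlated
artifacts.  Passing tests on these fixtures demonstrate that the machinery is
correct and leak-free — not that any particular chain will win on real data;
that judgment is exactly what `compare_chains` is for, on the user's own
images.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` run at deliberately small scale —
20-image texture sets, 64×64×16 blob volumes, 60 training ROIs with 7×7×5
patches — sizes at which every quantity recomputes from scratch in seconds
while still exercising each code path.  All randomness flows from explicit
seeds (fold shuffling from the protocol seed, generators from their spec
seed, stochastic classifiers from the chain seed), so every reported number
is bit-reproducible.

## Known limitations

* Pure-R loops make voxel-dense operations (interval-1 annotation of large
  volumes, component labeling of very dense masks) slow; the design targets
  method correctness and desk-scale data.
* The extractor inventory omits co-occurrence (Haralick), Gabor and Chebyshev
  textures by design.
* No probability calibration, boosting or neural classifiers; no nested CV or
  hyperparameter optimization.
* Only PNG and (multi-page) TIFF input; no OME-XML metadata, registration or
  denoising — preprocessing belongs upstream (e.g. ImageJ).
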