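---
title: "Methods: segmentation, descriptors and evaluation in mammocad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, descriptors and evaluation in mammocad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mammocad implements a classical computer-aided-diagnosis (CAD) chain for
mammographic masses: tumour-centred region-of-interest (ROI) cropping,
seeded region-growing segmentation, four texture/gradient feature families
plus chord-based shape descriptors, and a battery of five classifiers
evaluated under stratified k-fold cross-validation. This vignette explains
the modelling choices, the tunable parameters, and what the built-in
synthetic phantoms do and do not establish.

```{r setup, message = FALSE}
library(mammocad)
```

## The processing model

A study consists of 8-bit grayscale images with per-lesion annotations
(centre, approximate radius, benign/malignant label). The pipeline crops the
axis-aligned square of side `2 * radius` around the annotated centre, clipped
at image borders rather than padded — padding would fabricate tissue.
Annotations in the MIAS convention are 0-based with the y origin at the
*bottom* edge; `crop_roi()` converts to the top-left, 1-based row/column
convention of R matrices. Grid descriptors (HOG, CS-LBP) need rectangular
support, which is why the crop is square rather than circular.

## Seeded region growing

`region_grow()` performs FIFO breadth-first growth from a seed pixel,
accepting a frontier pixel when its intensity is within `tolerance` gray
levels of a reference value. Two acceptance criteria are provided:

* `"seed-value"` — the reference is the seed intensity. The result then
  equals the connected component of the thresholded band
  `|I - I(seed)| <= tolerance` containing the seed, which the tests verify
  against a brute-force oracle. This criterion is order-independent.
* `"running-mean"` (default) — the reference is the incrementally updated
  mean of accepted pixels. This tolerates noise on an intensity plateau, but
  is traversal-order dependent, which is why the traversal order (FIFO,
  fixed neighbour order) is pinned down: it makes the output deterministic.

Defaults: `tolerance = 45` gray levels, 8-connectivity, seed at the ROI
centre (the crops are tumour-centred by construction). The tolerance sits
comfortably between the default phantom noise scale (pixel sd about 12 gray
levels combining texture and noise) and the lesion/background contrast (90
gray levels), so plateau pixels are accepted at several noise standard
deviations while background pixels stay excluded. No clinically calibrated
tolerance exists for MIAS in this package; on real data the tolerance is the
first parameter to revisit. `postprocess_mask()` fills fully enclosed holes
(noise pixels inside the lesion that failed the criterion) and flags the
degenerate singleton case instead of failing.

## First-order and co-occurrence texture features

First-order features are moments of the gray-level histogram (L = 256):
mean, variance, and *unnormalised* third and fourth central moments for
skewness and kurtosis — deliberately not sigma-standardised, so that the
degenerate constant-image case is exactly zero and the values remain plain
histogram moments. Energy is `sum(p^2)` and entropy `-sum(p log2 p)` bits.
A variant form of energy and entropy that weights each term by the gray
level itself is available behind `printed_forms = TRUE`; it is not the
default because only the standard forms behave as homogeneity/uncertainty
measures (a constant image then scores energy 1 and entropy 0 regardless of
its level).

The co-occurrence (GLCM) features use the four standard orientations 0, 45,
90 and 135 degrees and report the orientation average of seven statistics:
correlation, inertia, inverse difference, angular second moment, absolute
value, maximum probability and entropy. Defaults: 8 quantised levels
(uniform binning of [0, 255]), displacement 1, symmetric counting. Eight
levels keep the matrix dense enough for the small, masked lesion regions the
pipeline feeds in; both parameters are configurable. Correlation is defined
as 0 for degenerate marginals. Entropies use base 2 throughout the package.
Histogram and GLCM features are computed on the segmented lesion pixels by
default (`features_on = "mask"`), since the descriptors should describe the
mass, not the surrounding crop; `"roi"` switches to the full rectangle.

## HOG

`hog_descriptor()` resamples the ROI to 64 x 64 (bilinear), takes centred
`[-1, 0, +1]` differences with replicated borders, and bins unsigned
orientations (0--180 degrees) into 9 bins of 20 degrees per 8 x 8 cell,
weighting each vote by gradient magnitude — low-magnitude pixels thus
contribute proportionally little without any hard threshold. Votes are
linearly interpolated between the two nearest bin centres (circular);
`interpolate = FALSE` gives hard assignment. Cells are gathered into 2 x 2
blocks at stride 1, each block L2-normalised with an epsilon guard
(`1e-6`), and concatenated: `(64/8 - 2 + 1)^2` blocks x 4 cells x 9 bins =
1764 values. The geometry (64/8/2/1) is the canonical published HOG
configuration; nothing in the mammography setting argues for a different
one, and all of it is configurable.

## CS-LBP

The centre-symmetric local binary pattern compares the four
centre-symmetric pairs among 8 neighbours sampled on a radius-2 circle:
`code = sum_i [d_i - d_{i+4} >= T] 2^i`, 16 possible codes (plain LBP's
comparison against the centre gives 256). Intensities are scaled to [0, 1]
by division by 255 so the threshold `T = 0.1` is meaningful; the threshold
buys robustness on flat regions. Sampling starts east and proceeds
counter-clockwise with bilinear interpolation; these conventions are fixed
for determinism (they are not identified by the operator's definition), and
an integer-snapped ring (`interpolate = FALSE`) exists for oracle testing.
Codes are histogrammed over a 4 x 4 location grid and the concatenated
256-vector is L2-normalised.

## Chord-based shape features

`shape_features()` reports area (pixel count), convex area (pixel count of
the rasterised convex hull of pixel centres — keeping both areas in the
same units so solidity stays in (0, 1]), perimeter (sum of 1/sqrt(2) steps
along the traced closed boundary), major axis (the longest chord: maximum
pairwise distance over hull vertices, verified against an all-pairs brute
force), minor axis, eccentricity and solidity.

Two conventions deserve emphasis:

* **Eccentricity is minor/major**, the short-to-long chord ratio: 1 for a
  circle, 0 for a line. This is the *reverse* of the conic-section
  convention and follows from defining both axes as chords.
* **Minor axis is the hull width perpendicular to the major-axis
  direction.** The alternative reading — the longest perpendicular chord
  through the major-axis midpoint — is ambiguous on concave shapes; the
  hull-width reading is well defined on every mask and coincides on convex
  ones.

Solidity is the discriminative quantity for mass margins: spiculated
(malignant-like) outlines lose convex-hull coverage, smooth (benign-like)
outlines do not.

## Classification and evaluation

Five classifiers are provided: 5-NN with Euclidean distance (ties broken
toward the single nearest neighbour), a linear soft-margin SVM (cost 1,
via e1071/libsvm), Fisher LDA with pooled covariance, a Gini decision tree
(rpart, minimum leaf 2), and an ensemble. The ensemble is a majority vote
of KNN + SVM + LDA with ties toward the SVM; a bagged-tree variant is
available behind `ensemble_type = "bagged-tree"`. The LDA adds a ridge of
`1e-6` to the pooled covariance diagonal and switches to a low-rank
(Woodbury) solve when the feature dimension exceeds the fold size — with
1764-dimensional HOG blocks and fold sizes near 100, the pooled covariance
is always singular, so a plain inverse is not an option. Features are
z-scored with statistics fitted on the training fold only; Euclidean
distances across heterogeneous feature families are meaningless without it,
and fitting on the training fold only keeps the cross-validation honest
(a property the tests assert by recomputation).

Evaluation pools test-fold predictions over the k folds and computes one
confusion matrix per classifier and family set (malignant = positive), with
accuracy, sensitivity, specificity, MCC (all percent) and Cohen's kappa.
Pooling, rather than averaging per-fold metrics, is what makes the reported
percentages consistent with integer confusion counts. The MCC denominator
takes the square root of the product of the four marginal sums — with the
reference confusion matrix (TP = 48, FN = 3, TN = 57, FP = 1 on 109 ROIs)
the square-rooted form gives 92.68%, matching the accompanying accuracy
96.3%, sensitivity 94.12% and specificity 98.28%, whereas the un-rooted
product does not; all zero-denominator cases return 0. Kappa is
`(g0 - ge) / (1 - ge)` with the degenerate all-one-class, all-correct case
defined as 1; on the same matrix it evaluates to 0.926.

## The synthetic phantom model

Real annotated mammograms cannot be redistributed with the package, so
`generate_phantom()` builds what the discriminative claim actually needs: a
bright lesion plateau on a darker textured background, with the class
difference carried by outline regularity.

* **Geometry.** Benign lesions are ellipses with axis ratio in [0.7, 1];
  malignant lesions follow the radial outline
  `r(theta) = base_radius * (1 + amplitude * max(0, cos(k * theta)))` with
  `k >= 5` spicules (defaults: 8 spicules, amplitude 0.5). The truth mask is
  this noise-free support.
* **Intensities.** Background 90, lesion 180, i.i.d. Gaussian noise sd 10,
  plus background texture made by Gaussian-smoothing white noise (sigma 8
  px, rescaled to sd 6 gray levels) to mimic glandular correlation without
  external data. The 90-level contrast is far above the growing tolerance,
  yet the combined noise makes zero-tolerance growth fail — segmentation is
  non-trivial but solvable.
* **Dataset draws.** `generate_dataset()` randomises base radii over 14--22
  px, centres uniformly under a containment margin, benign axis ratios over
  [0.7, 1] and malignant spicule counts over 5--12, all from one master
  seed. The manifest's annotation radius is the enclosing radius
  `ceiling(base_radius * (1 + amplitude)) + 3`, mirroring how a clinical
  annotation radius encloses the whole abnormality, so crops contain
  spicule tips.

What the phantoms do **not** emulate: pectoral muscle and film labels
(the pipeline assumes pre-cropped ROIs), partial-volume blur at lesion
margins, non-Gaussian film grain, overlapping glandular structures, and any
calibration of contrast statistics to MIAS. Passing phantom tests therefore
demonstrates that the chain is implemented correctly and that shape
separability propagates through segmentation to classification — not that
the clinical accuracy figures transfer to real mammograms.

## Numerical and degenerate-input choices

* Region growing visits each pixel once; rejected pixels are never
  re-examined even if the running mean later drifts toward them.
* Boundary tracing starts at the topmost-then-leftmost pixel and proceeds
  counter-clockwise (in screen coordinates); a singleton mask traces to a
  length-1 chain with perimeter 0.
* A collinear mask has a degenerate hull: convex area falls back to the
  pixel count, solidity 1, minor axis 0, eccentricity 0 (also the
  singleton convention).
* HOG of a constant image is all zeros (the epsilon guard, not a division
  by zero); CS-LBP of a constant image is a delta at code 0 in every cell.
* GLCM errors name the orientation when a mask leaves an orientation
  without a single pixel pair.
* All randomness (phantom draws, fold assignment, bagging) flows through
  explicit integer seeds via `withr::with_seed`, so identical configs give
  byte-identical `features.csv` and `report.json`.

## Problem sizes in the test suite

The package's own checks run at desk scale: oracle equivalences use
8 x 8 to 16 x 16 random images (100 cases for the region-growing band
oracle, 50 random masks for the chord oracle), and the end-to-end battery
uses 50 benign + 50 malignant default phantoms at 128 x 128, where it
checks mean segmentation Dice >= 0.90 against truth masks, pooled 10-fold
shape-family ensemble accuracy >= 90%, and a label-shuffled control with
|MCC| <= 15. These sizes were chosen as the smallest at which the class
separability and the permutation null are stable across seeds.

## Known limitations

* Phantom realism, as above; no MIAS calibration of tolerance or contrast.
* The CS-LBP rotation behaviour is a code permutation only away from the
  threshold band; histograms are not rotation-invariant by construction.
* The chord-based eccentricity convention differs from moment-based
  regionprops-style ellipse fits; values are not interchangeable with
  those tools.
* `mias-dir` mode expects one lesion annotation per image file; multi-
  abnormality records are processed as independent rows only if their
  `ref_id`s are unique.
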