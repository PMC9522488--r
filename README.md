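# mammocad

Computer-aided diagnosis (CAD) of mammographic masses in R: from annotated
grayscale mammograms to a cross-validated benign/malignant classification
report, through seeded region-growing segmentation and composite texture,
gradient and shape descriptors.

The package targets image-analysis researchers who want a fully inspectable,
classical CAD baseline: every stage is an exported, tested function, and a
built-in phantom generator makes the whole chain reproducible without access
to clinical data.

## The method

Given an image and a lesion annotation (centre, approximate radius, label),
the pipeline:

1. **Crops** the tumour-centred square ROI of side 2r (MIAS bottom-left
   coordinates are converted; border crops are clipped, never padded).
2. **Segments** the mass by seeded region growing: FIFO breadth-first growth
   from the ROI centre, accepting a connected pixel when
   |I − ref| ≤ tolerance, with ref either the seed value or the running mean
   of accepted pixels (default, tolerance 45), then fills enclosed holes.
3. **Describes** the lesion with five feature families:
   - first-order histogram statistics — mean, variance, unnormalised
     skewness/kurtosis central moments, energy Σp², entropy −Σp·log₂p;
   - seven GLCM features (correlation, inertia, inverse difference, angular
     second moment, absolute value, maximum probability, entropy), averaged
     over the orientations θ ∈ {0°, 45°, 90°, 135°};
   - HOG: 9 unsigned orientation bins per 8×8 cell on a 64×64 resample,
     2×2-cell blocks at stride 1, L2-normalised (1764 values);
   - CS-LBP: 4-bit centre-symmetric codes, CS-LBP(x) = Σᵢ [dᵢ − dᵢ₊₄ ≥ T]·2ⁱ
     with R = 2, T = 0.1 on [0,1]-scaled intensities — 16 codes per pixel,
     histogrammed over a 4×4 grid (256 values);
   - chord-based shape features: area, convex area, perimeter, major/minor
     chord axes, eccentricity = minor/major (1 for a circle — note the
     reversed convention) and solidity = area / convex area.
4. **Classifies** with 5-NN, linear SVM, ridged Fisher LDA, a Gini decision
   tree, and a KNN+SVM+LDA majority-vote ensemble, under stratified 10-fold
   cross-validation with per-fold z-scoring. Pooled test predictions yield
   accuracy, sensitivity, specificity, MCC (with the square-rooted
   denominator) and Cohen's kappa.

## Worked example

Generate 15 phantoms per class, run the full pipeline, and inspect the
report (phantom lesions differ by outline only: smooth ellipses for benign,
spiculated stars for malignant):

```r
library(mammocad)

res <- run_pipeline(list(
  out_dir = "demo", seed = 42, verbose = FALSE,
  phantom = list(n_benign = 15, n_malignant = 15),
  families = c("stat", "shape"), cv = list(k = 10)
))
dplyr::select(tidy(res$report), family_set, classifier, tp, fp, tn, fn,
              accuracy, mcc, kappa)
#> # A tibble: 15 × 9
#>    family_set classifier    tp    fp    tn    fn accuracy    mcc   kappa
#>  1 stat       knn            7     8     7     8     46.7  -6.67 -0.0667
#>  2 stat       svm            8    10     5     7     43.3 -13.6  -0.133
#>  3 stat       lda           11     5    10     4     70    40.1   0.4
#>  4 stat       dtree          6    10     5     9     36.7 -26.7  -0.267
#>  5 stat       ensemble       9     9     6     6     50     0     0
#>  6 shape      knn           15     0    15     0    100   100     1
#>  7 shape      svm           15     0    15     0    100   100     1
#>  8 shape      lda           15     0    15     0    100   100     1
#>  9 shape      dtree         14     0    15     1     96.7  93.5   0.933
#> 10 shape      ensemble      15     0    15     0    100   100     1
#> ...
```

The report reads directly: on phantoms the intensity histogram (`stat`)
carries no class signal — both classes share the same lesion intensity
model, so its runs hover at chance with MCC near 0 — while the shape family
separates the smooth from the spiculated outlines essentially perfectly,
and the fused vector inherits that. `run_pipeline()` also writes
`features.csv`, the segmentation masks, `report.csv`/`report.json` and a
`run_metadata.json` that can be re-fed as a config to reproduce the run
byte-for-byte.

Single stages are just as accessible:

```r
ph <- generate_phantom(phantom_spec("malignant", seed = 7))
ph
#> <mammocad_phantom> malignant, 128x128 px, lesion area 1417 px (seed 7)
round(shape_features(ph$truth_mask), 3)
#>   shape_area shape_convex_area shape_perimeter shape_major_axis
#> 1       1417              2057         239.765               54
#>   shape_minor_axis shape_eccentricity shape_solidity
#> 1               54                  1          0.689
autoplot(ph)   # phantom with its ground-truth outline
```

A spiculated mass keeps a round envelope (eccentricity 1) but loses
convex-hull coverage: solidity 0.689, against ≈ 1 for a benign ellipse —
the separation the classifiers exploit.

A thin CLI wrapper ships in `inst/scripts/mammocad`
(`mammocad phantom ...`, `mammocad run --config cfg.yaml`).

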