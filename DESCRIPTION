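Package: mammocad
Title: Mammography Computer-Aided Diagnosis with Region Growing and
    Composite Texture, Gradient and Shape Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end computer-aided diagnosis (CAD) toolkit for
    mammographic masses. Reads MIAS-convention annotated mammograms (PGM or
    PNG), crops tumour-centred regions of interest, segments the lesion by
    seeded region growing, and extracts four feature families: first-order
    histogram statistics, direction-averaged grey-level co-occurrence matrix
    (GLCM) features, histograms of oriented gradients (HOG), and
    centre-symmetric local binary patterns (CS-LBP), together with chord-based
    shape descriptors of the segmented mask. Feature families are fused and
    evaluated with KNN, linear SVM, LDA, decision-tree and majority-vote
    ensemble classifiers under stratified k-fold cross-validation, reporting
    accuracy, sensitivity, specificity, Matthews correlation and Cohen's
    kappa. A built-in synthetic phantom generator produces labelled lesion
    images with ground-truth masks so the whole pipeline is testable without
    access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    e1071,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    pracma,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    class,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
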