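Package: spliceSVM
Title: Donor Splice Site Prediction with Positional, Dependency and
    Compositional Sequence Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts donor (5') splice sites in nucleotide sequences
    using a support vector machine over three families of sequence
    features: positional scores derived from per-position nucleotide
    frequency models (weight-matrix and Shapiro-Senapathy style),
    dependency scores derived from pairwise conditional frequency models
    (weight-array and sum-of-absolute-error style), and overlapping
    k-mer composition frequencies. Includes F-score filter feature
    selection, a GT-dimer candidate scanner for FASTA input, exact
    trapezoidal AUC-ROC and Davis-Goadrich interpolated AUC-PR
    evaluation, a repeated stratified cross-validation protocol for
    balanced and imbalanced designs, and a seeded synthetic splice-site
    generator for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, Sequencing, SupportVectorMachine
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
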