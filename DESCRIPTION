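Package: genoDraw
Title: SNP-to-Image Genomic Prediction of Fruit Shape with Convolutional
    Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts fruit images from small SNP panels. A convolutional
    autoencoder compresses single-fruit images into a 64-value embedding; a
    two-layer predictor maps SNP dosages to per-genotype mean embeddings; the
    predictor and the trained decoder are assembled into an SNP-to-image model.
    Includes silhouette morphometrics (fruit shape index, shoulder ratio,
    five-class shape categories), a parametric fruit-and-genotype simulator
    for fully reproducible desk-scale experiments, and an evaluation battery:
    MAE comparisons between targeted and random SNP panels, a resampling null
    threshold, one-dimensional Wasserstein distances, shape-class confusion
    analysis, and panel-dilution ladders.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png,
    EBImage,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
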