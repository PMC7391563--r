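Package: sandsift
Title: Transgressive Segregation, Morphometrics and QTL Mapping in an F2 Cichlid Cross
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for an F2 intercross between two Lake Malawi
    cichlid species: quantification of sand-sifting behaviour from two-layer
    sand-tray images, transgressive-segregation statistics with permutation
    tests, geometric morphometrics (generalized Procrustes analysis with
    sliding semilandmarks, allometry correction, shape PCA and projection of
    external specimens), hard-filtering of RADseq variants, linkage-map
    construction with the Kosambi mapping function, and single-QTL interval
    mapping via a genotype-probability hidden Markov model and EM, with
    genome-wide permutation thresholds, Bayesian credible intervals and
    percent variance explained. A synthetic-data module generates crosses,
    phenotypes, landmark configurations, sand images and VCFs with the
    statistical structure the analyses assume, so every stage is testable
    without the original field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png,
    tiff
Config/testthat/edition: 3
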