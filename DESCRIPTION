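Package: kircnv
Title: Hybrid qPCR/SNP-Array Copy-Number Calling for KIR3DL1 and KIR3DS1
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint copy-number genotyping of the KIR3DL1/KIR3DS1 locus from
    multiplexed qPCR crossing-point data, and imputation of the resulting
    copy-number groups into SNP-array samples. Implements per-plate delta-Ct
    normalisation anchored by 1-D k-medoids, an eight-component bivariate
    Gaussian mixture fitted by EM with hard-zero component masks, multiple
    imputation of hard calls from posterior probabilities, k-nearest-neighbour
    imputation from Illumina (R, theta) signals with leave-one-out model
    selection, and case-control association tests (Rubin-pooled logistic
    regression, HLA-epitope subset tests, case-only chi-square interaction
    test), together with a synthetic-data generator emulating plate batch
    effects, amplification dropout and SNP cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    class,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
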