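Package: ishreid
Title: Gene Re-Identification Embeddings for In Situ Hybridization Brain Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns patch-level embeddings of brightfield in situ hybridization
    (ISH) brain images with a batch-hard soft-margin triplet loss, using gene
    identity as the contrastive training signal. Provides tissue-foreground
    segmentation, seeded random patch extraction with foreground filtering,
    hierarchical embedding aggregation (patch to image, donor and gene), a
    donor-excluding rank-1 gene re-identification metric with analytic and
    permutation chance baselines, gene-level train/validation/test splitting,
    and downstream evaluation of embeddings for gene-annotation and diagnosis
    prediction with demographic covariates. A synthetic ISH study generator
    with known gene phenotypes and donor effects makes the whole pipeline
    testable without any image download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
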