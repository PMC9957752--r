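Package: hepatodecon
Title: Marker-Ratio Deconvolution of Liver Transcriptomes and
    Signature-Based Disease Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the transcriptome fraction contributed by each
    liver cell type to whole-tissue bulk RNA-seq using ratios of
    marker-gene transcriptome fractions between tissue and pure
    cell-type reference libraries, sums nonparenchymal fractions and
    obtains the hepatocyte fraction by subtraction, and apportions the
    expression of shared genes across cell types.  Also provides
    library preprocessing (extraneous-biotype removal, isoform
    collapsing, reads-per-kilobase conversion, total and median
    normalization), derivation of cell-type-exclusive marker sets,
    cross-cohort gene-signature scoring with ordinal-stage trend
    testing, univariate logistic-regression ROC staging with a
    train/test split, gene-set overlap statistics, and a synthetic-data
    generator with known ground truth for validating every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
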