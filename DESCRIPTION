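Package: endosign
Title: Epigenetic Signature Scoring and Imprinting Calls for Endosperm
    Allele-Specific Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying imprinted paternally expressed genes (PEGs)
    in triploid endosperm from a tripartite epigenetic signature: central-cell
    CHG methylation together with maternal-allele H3K27me3 and H3K9me2.
    Includes allele-resolved ChIP-seq normalization against an H3 control
    (log2 ratios in fixed-width bins, z-score standardization, metagene
    profiles, per-gene body z-scores), weighted bisulfite methylation levels by
    sequence context and cell type, a discrete combined epigenetic score with a
    maximum-score PEG prediction set, an allele-specific expression imprinting
    caller for reciprocal-cross RNA-seq counts (chi-square dosage test against
    the 2:1 maternal:paternal endosperm ratio, FDR control, reciprocal
    classification rules), a maternal seed-coat contamination estimator, gene
    set enrichment and distribution-comparison statistics, and a synthetic-data
    generator emulating the allele-specific structure of endosperm sequencing
    data so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
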