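Package: ctcconcord
Title: Genomic Concordance of Circulating Tumor Cells and Bulk Tumors
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for comparing the somatic mutation and
    copy-number landscape of whole-genome-amplified circulating tumor cell
    (CTC) samples with matched bulk tumor, germline and white-blood-cell
    control samples. Implements somatic-call filtering (artifact k-mer,
    cross-patient, allele-frequency with bulk rescue), the bulk/CTC mutation
    taxonomy (bulk, CTC-bulk, CTC-shared, CTC-private), recovery curves over
    CTC sample subsets, coverage-conditioned selection, variant-allele-
    fraction concordance statistics, 96-class trinucleotide-context spectra
    with complete-linkage clustering under a log-correlation distance, and a
    window-based copy-number pipeline with circular binary segmentation,
    grid-search purity/ploidy correction, ploidy-2 normalization,
    copy-number categorization and Spearman profile concordance. Ships a
    synthetic-data generator that emulates clonal tumors, impure bulk
    biopsies and single-cell whole-genome-amplification noise (allele
    dropout, locus dropout, artifact mutations with patient-specific context
    spectra) so the entire pipeline can be exercised at desk scale with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    ape,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
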