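Package: lavageMut
Title: Somatic Mutation Analysis of Uterine Lavage Trios
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for ultra-deep targeted sequencing of uterine
    lavage samples collected as matched trios (germline PBMC, lavage cell
    pellet, lavage cell-free DNA). Reads per-caller VCF output, applies
    concordance-based merging, panel targeting, matched-normal subtraction
    and a 1% allele-fraction reporting threshold; verifies trio identity from
    a germline SNP fingerprint spike-in; parses short protein-change (HGVS-p)
    notation; nominates mutations as drivers, potential drivers or passengers
    against a hotspot/impact knowledge base; computes cohort-level allele-
    fraction binning, cell-pellet/cfDNA concordance, cancer enrichment and
    clinical association statistics; plans orthogonal (ddPCR/Sanger)
    validation; and simulates synthetic cohorts with the same statistical
    structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    VariantAnnotation,
    rtracklayer,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
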