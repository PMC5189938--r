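#' @import methods
#' @importFrom GenomicRanges GRanges start end width seqnames reduce
#'   findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

setClassUnion("df_or_NULL", c("data.frame", "NULL"))

#' Targeted amplicon panel definition
#'
#' Holds the amplicon regions of a targeted sequencing panel (GRCh37), the
#' gene each amplicon covers, and the germline SNP fingerprint loci spiked
#' into the panel for sample-identity checking. Regions are stored 1-based
#' inclusive (`GRanges`); on-disk BED interchange is 0-based half-open, so a
#' BED region `(c, s, e)` contains a 1-based variant position `p` iff
#' `s < p <= e`.
#'
#' @slot name Panel name.
#' @slot amplicons `GRanges` of amplicons with a `gene` metadata column.
#' @slot snpLoci `GRanges` of width-1 SNP fingerprint loci with `ref`,
#'   `alt` and `maf` metadata columns.
#' @export
setClass("PanelDefinition",
  representation(name = "character", amplicons = "GRanges",
                 snpLoci = "GRanges"))

setValidity("PanelDefinition", function(object) {
  msg <- character()
  if (is.null(mcols(object@amplicons)$gene))
    msg <- c(msg, "amplicons must carry a 'gene' metadata column")
  if (length(object@snpLoci) && any(width(object@snpLoci) != 1L))
    msg <- c(msg, "snpLoci must be width-1 positions")
  if (length(msg)) msg else TRUE
})

#' @describeIn PanelDefinition Gene symbols covered by the panel.
#' @param panel A `PanelDefinition`.
#' @export
panelGenes <- function(panel) unique(mcols(panel@amplicons)$gene)

#' @describeIn PanelDefinition Amplicon regions (`GRanges`).
#' @export
panelAmplicons <- function(panel) panel@amplicons

#' @describeIn PanelDefinition Merged, non-overlapping target regions used
#'   for variant filtering.
#' @export
panelRegions <- function(panel) reduce(panel@amplicons)

#' @describeIn PanelDefinition SNP fingerprint loci (`GRanges`).
#' @export
panelSnpLoci <- function(panel) panel@snpLoci

#' @describeIn PanelDefinition Number of amplicons.
#' @export
ampliconCount <- function(panel) length(panel@amplicons)

#' @describeIn PanelDefinition Mean amplicon length in bp.
#' @export
meanAmpliconLength <- function(panel) mean(width(panel@amplicons))

setMethod("show", "PanelDefinition", function(object) {
  cat("PanelDefinition:", object@name, "\n",
      " ", length(panelGenes(object)), "genes,",
      ampliconCount(object), "amplicons (mean",
      round(meanAmpliconLength(object)), "bp),",
      length(object@snpLoci), "SNP fingerprint loci\n")
})

#' Driver-nomination knowledge base
#'
#' Gene roles, the hotspot registry (with endometrial/TCGA recurrence
#' counts) and per-variant functional-impact annotations that drive the
#' driver / potential-driver / passenger nomination. The bundled default
#' reproduces the published hotspot registry for the 12-gene endometrial
#' panel; impact scores follow the Mutation-Assessor convention
#' (neutral < low < medium < high).
#'
#' @slot genes `data.frame` with columns `symbol`, `role` (oncogene /
#'   tumor_suppressor / other), `major_ec_driver`, `on_12_gene_panel`,
#'   `tcga_hotspot_count`, `tcga_mutation_count`.
#' @slot hotspots `data.frame` with columns `gene`, `label`, `aa_start`,
#'   `aa_end`, `lavage_count` (observed study multiplicity, used as
#'   simulation weights), `recurrence_endometrial`, `recurrence_pancancer`,
#'   `novel`, `example_change`.
#' @slot variants `data.frame` with columns `gene`, `protein_change`,
#'   `impact_score`, `seen_in_endometrial`, `seen_in_other_cancers`.
#' @export
setClass("KnowledgeBase",
  representation(genes = "data.frame", hotspots = "data.frame",
                 variants = "data.frame"))

setValidity("KnowledgeBase", function(object) {
  msg <- character()
  g <- object@genes; h <- object@hotspots; v <- object@variants
  if (!all(c("symbol", "role", "major_ec_driver") %in% names(g)))
    msg <- c(msg, "genes table needs symbol/role/major_ec_driver")
  if (!all(g$role %in% c("oncogene", "tumor_suppressor", "other")))
    msg <- c(msg, "unknown gene role")
  if (nrow(h)) {
    if (!all(h$gene %in% g$symbol))
      msg <- c(msg, "hotspot gene absent from gene table")
    prior <- !h$novel
    if (any(prior) &&
        any(h$recurrence_endometrial[prior] +
            h$recurrence_pancancer[prior] < 1))
      msg <- c(msg, "non-novel hotspots must have recurrence >= 1")
  }
  if (nrow(v) && !all(v$impact_score %in% IMPACT_LEVELS))
    msg <- c(msg, "impact_score outside neutral/low/medium/high")
  if (length(msg)) msg else TRUE
})

#' @describeIn KnowledgeBase Gene annotation table.
#' @param kb A `KnowledgeBase`.
#' @export
kbGenes <- function(kb) kb@genes

#' @describeIn KnowledgeBase Hotspot registry.
#' @export
kbHotspots <- function(kb) kb@hotspots

#' @describeIn KnowledgeBase Per-variant impact annotations.
#' @export
kbVariants <- function(kb) kb@variants

setMethod("show", "KnowledgeBase", function(object) {
  cat("KnowledgeBase:", nrow(object@genes), "genes,",
      nrow(object@hotspots), "hotspot entries (",
      sum(object@hotspots$novel), "novel ),",
      nrow(object@variants), "variant annotations\n")
})

#' One patient's matched sample trio
#'
#' Germline (PBMC), lavage cell-pellet and lavage cfDNA call sets plus the
#' SNP fingerprint genotypes for one patient. A tumor call set is optional.
#'
#' @slot patientId Patient identifier.
#' @slot calls Canonical call table covering all fractions of the trio.
#' @slot snpGenotypes `data.frame` of fingerprint genotypes with columns
#'   `locus`, `fraction`, `genotype` ("0/0", "0/1", "1/1" or `NA`).
#' @export
setClass("PatientTrio",
  representation(patientId = "character", calls = "data.frame",
                 snpGenotypes = "df_or_NULL"))

setValidity("PatientTrio", function(object) {
  msg <- character()
  calls <- object@calls
  if (nrow(calls)) {
    if (!all(calls$patient_id == object@patientId))
      msg <- c(msg, "all calls must share the trio's patient_id")
    if (!all(calls$fraction %in% FRACTIONS))
      msg <- c(msg, "unknown sample fraction in calls")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a [PatientTrio-class]
#'
#' @param patientId Patient identifier.
#' @param calls Canonical call table (all fractions, one patient).
#' @param snpGenotypes Optional fingerprint genotype `data.frame`.
#' @return A `PatientTrio`.
#' @export
PatientTrio <- function(patientId, calls, snpGenotypes = NULL) {
  validate_calls(calls)
  new("PatientTrio", patientId = patientId, calls = calls,
      snpGenotypes = snpGenotypes)
}

#' @describeIn PatientTrio Calls for one fraction of the trio.
#' @param trio A `PatientTrio`.
#' @param fraction One of `"germline"`, `"cell_pellet"`, `"cfdna"`,
#'   `"tumor"`.
#' @export
trioCalls <- function(trio, fraction = NULL) {
  if (is.null(fraction)) return(trio@calls)
  assert_fraction(fraction)
  trio@calls[trio@calls$fraction %in% fraction, , drop = FALSE]
}

setMethod("show", "PatientTrio", function(object) {
  tab <- table(factor(object@calls$fraction, levels = FRACTIONS))
  cat("PatientTrio", object@patientId, ":",
      paste(names(tab), tab, collapse = ", "), "\n")
})

#' Sample-identity report for one trio
#'
#' Pairwise SNP fingerprint concordance between the fractions of one trio.
#'
#' @slot patientId Patient identifier.
#' @slot pairs `data.frame` with columns `fraction_a`, `fraction_b`,
#'   `callable`, `concordance`.
#' @slot verdict `"match"`, `"mismatch"` or `"insufficient"`.
#' @export
setClass("IdentityReport",
  representation(patientId = "character", pairs = "data.frame",
                 verdict = "character"))

setValidity("IdentityReport", function(object) {
  ok <- is.na(object@pairs$concordance) |
    (object@pairs$concordance >= 0 & object@pairs$concordance <= 1)
  if (!all(ok)) return("concordance outside [0, 1]")
  if (!object@verdict %in% c("match", "mismatch", "insufficient"))
    return("unknown verdict")
  TRUE
})

#' @describeIn IdentityReport The verdict string.
#' @param report An `IdentityReport`.
#' @export
identityVerdict <- function(report) report@verdict

#' @describeIn IdentityReport Pairwise concordance table.
#' @export
identityPairs <- function(report) report@pairs

setMethod("show", "IdentityReport", function(object) {
  cat("IdentityReport", object@patientId, "- verdict:", object@verdict, "\n")
  print(object@pairs, row.names = FALSE)
})

#' Allele-fraction binned mutation table
#'
#' Per gene x fraction x AF-bin mutation counts, the backbone of the
#' cohort summary. Default bins are (0, 5%], (5%, 10%], (10%, 100%],
#' matching the reported "<=5.00% / 5.01-10.00% / >=10.01%" strata.
#'
#' @slot counts 3-d integer array `gene x fraction x bin`.
#' @slot breaks Numeric bin breakpoints (including 0 and 1).
#' @export
setClass("AFBinnedTable",
  representation(counts = "array", breaks = "numeric"))

setValidity("AFBinnedTable", function(object) {
  if (length(dim(object@counts)) != 3)
    return("counts must be a gene x fraction x bin array")
  if (is.unsorted(object@breaks, strictly = TRUE))
    return("breaks must be strictly increasing")
  if (dim(object@counts)[3] != length(object@breaks) - 1)
    return("bin dimension does not match breaks")
  TRUE
})

#' @describeIn AFBinnedTable Per-gene totals for one fraction (the "Sum of
#'   mutations" column).
#' @param x An `AFBinnedTable`.
#' @param fraction Fraction name.
#' @export
geneSums <- function(x, fraction) {
  apply(x@counts[, fraction, , drop = FALSE], 1, sum)
}

#' @describeIn AFBinnedTable The raw count array.
#' @export
binCounts <- function(x) x@counts

#' @describeIn AFBinnedTable Bin breakpoints.
#' @export
binBreaks <- function(x) x@breaks

setMethod("show", "AFBinnedTable", function(object) {
  d <- dim(object@counts)
  cat("AFBinnedTable:", d[1], "genes x", d[2], "fractions x", d[3],
      "AF bins\n")
  for (f in dimnames(object@counts)[[2]]) {
    cat("--", f, "--\n")
    m <- object@counts[, f, , drop = TRUE]
    print(cbind(m, sum = rowSums(m)))
  }
})
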