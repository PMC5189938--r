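#' Genotype the SNP fingerprint loci of one sample
#'
#' Assigns diploid genotypes at the panel's fingerprint loci from observed
#' read support, using allele-fraction cuts suited to the ~200X fingerprint
#' depth: AF < 0.10 is called `0/0`, 0.10-0.90 `0/1`, and > 0.90 `1/1`.
#' Loci below `minDepth` are returned as missing (`NA`).
#'
#' @param support `data.frame` with columns `chrom`, `pos`, `depth`,
#'   `alt_reads` giving the pileup at fingerprint loci.
#' @param panel A [PanelDefinition-class]; every supported locus must be a
#'   panel fingerprint locus.
#' @param minDepth Minimum callable depth (default 50).
#' @return Named character vector of genotypes (`"chrom:pos"` names),
#'   one per panel locus; `NA` where depth is insufficient or the locus
#'   was not observed.
#' @export
genotypeSnpLoci <- function(support, panel, minDepth = 50L) {
  loci <- panelSnpLoci(panel)
  locus_id <- paste(as.character(seqnames(loci)), start(loci), sep = ":")
  gt <- stats::setNames(rep(NA_character_, length(loci)), locus_id)
  if (nrow(support) == 0) return(gt)
  sid <- paste(support$chrom, support$pos, sep = ":")
  unknown <- setdiff(sid, locus_id)
  if (length(unknown))
    stop("locus not in fingerprint panel: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  af <- ifelse(support$depth > 0, support$alt_reads / support$depth, NA)
  call <- ifelse(support$depth < minDepth | is.na(af), NA_character_,
                 ifelse(af < 0.10, "0/0",
                        ifelse(af > 0.90, "1/1", "0/1")))
  gt[sid] <- call
  gt
}

#' SNP fingerprint concordance across a trio
#'
#' Computes pairwise genotype concordance (matching genotypes over jointly
#' callable loci) for every pair of fractions and returns an
#' [IdentityReport-class]. The verdict is `"match"` only if every pair
#' reaches `matchThreshold` with at least `minCallable` jointly callable
#' loci; any under-powered pair makes the verdict `"insufficient"`, and an
#' adequately powered pair below threshold makes it `"mismatch"`.
#'
#' @param genotypes Named list of genotype vectors (as returned by
#'   [genotypeSnpLoci()]), one per fraction.
#' @param patientId Patient identifier for the report.
#' @param minCallable Minimum jointly callable loci per pair (default 10).
#' @param matchThreshold Minimum concordance for a match (default 0.90).
#' @return An [IdentityReport-class].
#' @export
trioConcordance <- function(genotypes, patientId = "unknown",
                            minCallable = 10L, matchThreshold = 0.90) {
  fr <- names(genotypes)
  if (length(fr) < 2)
    stop("trioConcordance needs at least two fractions", call. = FALSE)
  combs <- utils::combn(fr, 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
    a <- genotypes[[combs[1, i]]]; b <- genotypes[[combs[2, i]]]
    shared <- intersect(names(a), names(b))
    if (length(shared) == 0)
      stop("fractions share no fingerprint loci", call. = FALSE)
    a <- a[shared]; b <- b[shared]
    ok <- !is.na(a) & !is.na(b)
    data.frame(fraction_a = combs[1, i], fraction_b = combs[2, i],
               callable = sum(ok),
               concordance = if (any(ok)) mean(a[ok] == b[ok]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  verdict <- if (any(pairs$callable < minCallable)) "insufficient"
  else if (all(pairs$concordance >= matchThreshold)) "match"
  else "mismatch"
  new("IdentityReport", patientId = patientId, pairs = pairs,
      verdict = verdict)
}

#' Identity-check a whole cohort of trios
#'
#' @param supportByPatient Nested named list:
#'   `patient -> fraction -> support data.frame` (see
#'   [genotypeSnpLoci()]).
#' @param panel A [PanelDefinition-class].
#' @param ... Passed to [trioConcordance()].
#' @return `data.frame` with one row per patient pair comparison plus the
#'   per-patient verdict.
#' @export
cohortIdentityCheck <- function(supportByPatient, panel, ...) {
  do.call(rbind, lapply(names(supportByPatient), function(p) {
    gts <- lapply(supportByPatient[[p]], genotypeSnpLoci, panel = panel)
    rep <- trioConcordance(gts, patientId = p, ...)
    cbind(patient_id = p, identityPairs(rep),
          verdict = identityVerdict(rep))
  }))
}
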