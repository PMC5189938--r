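#' Read one caller's VCF into the canonical call table
#'
#' Parses a per-sample, per-caller VCF (4.x) and emits one call per ALT
#' allele. Depth is taken from the per-sample `DP` field and allelic depth
#' from `AD` (ref followed by one count per ALT); the allele fraction is
#' `AD[alt] / DP`. Optional `GENE` and `PCHG` INFO fields (gene symbol and
#' short protein change, as amplicon pipelines annotate) are carried
#' through when present.
#'
#' @param path VCF path.
#' @param patientId Patient identifier recorded on every call.
#' @param fraction Sample fraction: `"germline"`, `"cell_pellet"`,
#'   `"cfdna"` or `"tumor"`.
#' @param caller Caller name recorded in the `callers` column.
#' @return A call-table `data.frame`, one row per ALT allele.
#' @examples
#' vcf <- system.file("extdata", "example_trio", "PT001_cell_pellet_mutect.vcf",
#'                    package = "lavageMut")
#' if (nzchar(vcf)) head(readCallerVcf(vcf, "PT001", "cell_pellet", "mutect"))
#' @importFrom VariantAnnotation readVcf geno alt ref info
#' @export
readCallerVcf <- function(path, patientId, fraction, caller) {
  assert_fraction(fraction)
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(vcf) == 0) return(empty_calls())
  gen <- VariantAnnotation::geno(vcf)
  if (!all(c("DP", "AD") %in% names(gen)))
    stop("VCF '", path, "' lacks per-sample DP/AD depth fields",
         call. = FALSE)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alts <- VariantAnnotation::alt(vcf)  # DNAStringSetList, one set per row
  nalt <- lengths(alts)
  dp <- as.integer(gen$DP[, 1])
  ad <- gen$AD[, 1]                    # list: ref count + one per alt
  inf <- VariantAnnotation::info(vcf)
  gene <- if (!is.null(inf$GENE)) as.character(inf$GENE) else
    rep(NA_character_, nrow(vcf))
  pchg <- if (!is.null(inf$PCHG)) as.character(inf$PCHG) else
    rep(NA_character_, nrow(vcf))

  rows <- lapply(seq_len(nrow(vcf)), function(i) {
    if (is.na(dp[i]) || is.null(ad[[i]]) || all(is.na(ad[[i]])))
      stop("VCF '", path, "' record ", i, " (",
           as.character(seqnames(rr)[i]), ":", start(rr)[i],
           ") has no usable depth information", call. = FALSE)
    k <- nalt[i]
    data.frame(
      patient_id = patientId, fraction = fraction,
      chrom = as.character(seqnames(rr)[i]), pos = start(rr)[i],
      ref = as.character(VariantAnnotation::ref(vcf)[i]),
      alt = as.character(alts[[i]]),
      gene = gene[i], protein_change = pchg[i],
      depth = dp[i],
      alt_reads = as.integer(ad[[i]][seq_len(k) + 1L]),
      allele_fraction = as.integer(ad[[i]][seq_len(k) + 1L]) / dp[i],
      callers = caller, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  validate_calls(calls)
}

#' Merge per-caller call sets by concordance
#'
#' Variants from several callers run on the same (patient, fraction)
#' library are keyed by (chrom, pos, ref, alt) and retained only when at
#' least `minCallers` callers report them (two-caller concordance by
#' default, matching the study's treatment of single-caller variants as
#' not called). The `callers` column becomes the union; depth and
#' alt-reads are taken from the caller reporting the greatest depth.
#'
#' @param callsByCaller Named list of call tables, one per caller.
#' @param minCallers Minimum number of concordant callers (default 2).
#' @return A merged call table.
#' @export
mergeCallerOutputs <- function(callsByCaller, minCallers = 2L) {
  if (minCallers < 1) stop("minCallers must be >= 1", call. = FALSE)
  all <- do.call(rbind, unname(callsByCaller))
  if (is.null(all) || nrow(all) == 0) return(empty_calls())
  validate_calls(all)
  if (length(unique(all$patient_id)) > 1 ||
      length(unique(all$fraction)) > 1)
    stop("mergeCallerOutputs expects calls from one (patient, fraction)",
         call. = FALSE)
  key <- variant_key(all$chrom, all$pos, all$ref, all$alt)
  merged <- lapply(split(all, key), function(grp) {
    callers <- sort(unique(unlist(strsplit(grp$callers, ","))))
    if (length(callers) < minCallers) return(NULL)
    best <- grp[which.max(grp$depth), , drop = FALSE]
    best$callers <- paste(callers, collapse = ",")
    gg <- grp$gene[!is.na(grp$gene)]
    pp <- grp$protein_change[!is.na(grp$protein_change)]
    best$gene <- if (length(gg)) gg[1] else NA_character_
    best$protein_change <- if (length(pp)) pp[1] else NA_character_
    best
  })
  merged <- do.call(rbind, merged)
  if (is.null(merged)) return(empty_calls())
  rownames(merged) <- NULL
  merged[order(merged$chrom, merged$pos, merged$alt), , drop = FALSE]
}

#' Restrict calls to panel target regions
#'
#' Keeps calls whose 1-based position falls inside a merged panel region.
#' Under the BED convention a region `(c, s, e)` (0-based half-open)
#' contains position `p` iff `s < p <= e`. Calls on chromosomes absent
#' from the panel are dropped with a message, not an error.
#'
#' @param calls A call table.
#' @param panel A [PanelDefinition-class].
#' @return The subset of `calls` inside the panel.
#' @export
filterByPanel <- function(calls, panel) {
  if (nrow(calls) == 0) return(calls)
  validate_calls(calls)
  regions <- panelRegions(panel)
  off <- !(calls$chrom %in% as.character(unique(seqnames(regions))))
  if (any(off))
    message(sum(off), " call(s) on chromosomes absent from panel '",
            panel@name, "' removed")
  q <- GRanges(calls$chrom, IRanges(calls$pos, width = 1))
  # calls may carry chromosomes the panel lacks (e.g. fingerprint loci);
  # the seqlevel-merge warning is expected there
  hits <- suppressWarnings(findOverlaps(q, regions))
  calls[sort(unique(queryHits(hits))), , drop = FALSE]
}

#' Subtract germline variants from the lavage fractions
#'
#' Matched-normal somatic filtering: any cell-pellet or cfDNA call whose
#' (chrom, pos, ref, alt) also appears in the germline call set is
#' removed, regardless of its germline allele fraction. Calls at SNP
#' fingerprint loci are likewise never emitted as somatic when a panel is
#' supplied.
#'
#' @param trio A [PatientTrio-class]; the germline fraction must be
#'   present (there is no tumor-only mode).
#' @param panel Optional [PanelDefinition-class] whose SNP loci are
#'   excluded from the somatic output.
#' @return Named list of call tables (`cell_pellet`, `cfdna`, and `tumor`
#'   if present).
#' @export
subtractGermline <- function(trio, panel = NULL) {
  germ <- trioCalls(trio, "germline")
  if (nrow(germ) == 0 && !"germline" %in% trio@calls$fraction)
    stop("trio ", trio@patientId,
         " has no germline fraction; somatic subtraction requires a ",
         "matched normal", call. = FALSE)
  gkey <- variant_key(germ$chrom, germ$pos, germ$ref, germ$alt)
  snp_pos <- character()
  if (!is.null(panel) && length(panelSnpLoci(panel)))
    snp_pos <- paste(as.character(seqnames(panelSnpLoci(panel))),
                     start(panelSnpLoci(panel)), sep = ":")
  out <- list()
  for (f in intersect(c("cell_pellet", "cfdna", "tumor"),
                      unique(trio@calls$fraction))) {
    calls <- trioCalls(trio, f)
    key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
    keep <- !(key %in% gkey) &
      !(paste(calls$chrom, calls$pos, sep = ":") %in% snp_pos)
    out[[f]] <- calls[keep, , drop = FALSE]
  }
  out
}

#' Apply the allele-fraction reporting threshold
#'
#' Retains calls at or above `minAf`. The study's lower limit of detection
#' is the 1% allele fraction and validated variants at exactly 1.0% were
#' reportable, so the threshold is inclusive.
#'
#' @param calls A call table.
#' @param minAf Minimum allele fraction in (0, 1]; default 0.01.
#' @return The subset of `calls` with `allele_fraction >= minAf`.
#' @export
applyReportingThreshold <- function(calls, minAf = 0.01) {
  if (!is.numeric(minAf) || length(minAf) != 1 || minAf <= 0 || minAf > 1)
    stop("minAf must be a single value in (0, 1]", call. = FALSE)
  calls[calls$allele_fraction >= minAf, , drop = FALSE]
}

#' Ingest one patient trio from per-caller VCFs
#'
#' Convenience wrapper chaining [readCallerVcf()], [mergeCallerOutputs()],
#' [filterByPanel()], [subtractGermline()] and
#' [applyReportingThreshold()].
#'
#' @param vcfPaths Nested named list: `fraction -> caller -> path`.
#' @param patientId Patient identifier.
#' @param panel A [PanelDefinition-class].
#' @param minCallers Concordance threshold passed to
#'   [mergeCallerOutputs()].
#' @param minAf Reporting threshold passed to
#'   [applyReportingThreshold()].
#' @return A list with `trio` (the merged, panel-filtered
#'   [PatientTrio-class]) and `somatic` (named list of somatic call
#'   tables per lavage fraction).
#' @export
ingestTrio <- function(vcfPaths, patientId, panel, minCallers = 2L,
                       minAf = 0.01) {
  merged <- lapply(names(vcfPaths), function(f) {
    per_caller <- lapply(names(vcfPaths[[f]]), function(cl)
      readCallerVcf(vcfPaths[[f]][[cl]], patientId, f, cl))
    names(per_caller) <- names(vcfPaths[[f]])
    filterByPanel(mergeCallerOutputs(per_caller, minCallers), panel)
  })
  names(merged) <- names(vcfPaths)
  trio <- PatientTrio(patientId, do.call(rbind, unname(merged)))
  somatic <- lapply(subtractGermline(trio, panel),
                    applyReportingThreshold, minAf = minAf)
  list(trio = trio, somatic = somatic)
}
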