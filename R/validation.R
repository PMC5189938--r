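#' Orthogonal method for a given allele fraction
#'
#' Sanger sequencing for NGS allele fractions at or above 10%, droplet
#' digital PCR below.
#'
#' @param af Numeric allele fraction(s).
#' @return `"sanger"` or `"ddpcr"` per element.
#' @export
validationMethod <- function(af) {
  ifelse(af >= 0.10, "sanger", "ddpcr")
}

#' Select mutations for orthogonal validation
#'
#' Draws a stratified random sample of reported mutations for
#' confirmation by an orthogonal technology (30% by default). Strata are
#' the AF bins, sampled proportionally to stratum size (largest-remainder
#' apportionment so the plan size equals `round(selectionFraction * n)`
#' exactly), guaranteeing low-AF variants are represented. The assay for
#' each entry follows the 10% rule of [validationMethod()].
#'
#' @param mutations Mutation table with `patient_id`, `gene`,
#'   `protein_change`, `fraction`, `allele_fraction`.
#' @param selectionFraction Proportion to select, in (0, 1].
#' @param seed RNG seed; identical seed and input give an identical plan.
#' @param breaks AF stratum breakpoints.
#' @return `data.frame` plan: the selected rows plus `method`, ordered by
#'   stratum.
#' @export
selectValidationSet <- function(mutations, selectionFraction = 0.30,
                                seed = 1L, breaks = DEFAULT_AF_BREAKS) {
  if (selectionFraction <= 0 || selectionFraction > 1)
    stop("selectionFraction must be in (0, 1]", call. = FALSE)
  if (nrow(mutations) == 0) {
    mutations$method <- character()
    return(mutations)
  }
  idx <- af_bin_index(mutations$allele_fraction, breaks)
  n_target <- round(selectionFraction * nrow(mutations))
  raw <- selectionFraction * tabulate(idx, nbins = length(breaks) - 1)
  take <- floor(raw)
  rem <- n_target - sum(take)
  if (rem > 0) {
    extra <- order(raw - take, decreasing = TRUE)[seq_len(rem)]
    take[extra] <- take[extra] + 1L
  }
  take <- pmin(take, tabulate(idx, nbins = length(breaks) - 1))
  sel <- with_seed(seed, {
    unlist(lapply(seq_along(take), function(b) {
      pool <- which(idx == b)
      if (take[b] == 0) integer() else pool[sample.int(length(pool),
                                                       take[b])]
    }))
  })
  plan <- mutations[sort(sel), , drop = FALSE]
  plan$method <- validationMethod(plan$allele_fraction)
  rownames(plan) <- NULL
  plan
}

#' Reflex testing of the paired lavage fraction
#'
#' When a mutation is validated by ddPCR in one lavage fraction, the
#' paired fraction is also assayed, even if NGS called nothing there.
#' Reflex detections below the 1% NGS reporting threshold are recorded as
#' sub-threshold confirmations. Sanger entries trigger no reflex.
#'
#' @param planEntry One row of a validation plan.
#' @param pairedAf True/measured allele fraction of the same variant in
#'   the paired fraction (`NA` when absent).
#' @param minAf The NGS reporting threshold (default 0.01).
#' @return `data.frame` with the reflex request and its outcome (zero
#'   rows for Sanger entries).
#' @export
reflexPairTest <- function(planEntry, pairedAf = NA_real_, minAf = 0.01) {
  if (planEntry$method != "ddpcr")
    return(data.frame())
  other <- setdiff(LAVAGE_FRACTIONS, planEntry$fraction)
  detected <- !is.na(pairedAf) && pairedAf > 0
  data.frame(
    patient_id = planEntry$patient_id, gene = planEntry$gene,
    protein_change = planEntry$protein_change, fraction = other,
    reflex = TRUE, measured_af = pairedAf, detected = detected,
    sub_threshold = detected && pairedAf < minAf,
    stringsAsFactors = FALSE)
}

#' Summarise orthogonal validation results
#'
#' @param results `data.frame` with columns `detected` (logical),
#'   `measured_af`, `ngs_af` (the NGS allele fraction, `NA` for reflex
#'   entries NGS never called) and optionally `reflex`.
#' @param minAf NGS reporting threshold used to classify sub-threshold
#'   confirmations.
#' @return List with counts `validated`, `sub_threshold`, `discordant`,
#'   the discordant rows, and per-variant NGS-vs-assay AF deltas.
#' @export
assessConcordance <- function(results, minAf = 0.01) {
  if (nrow(results) == 0)
    return(list(validated = 0L, sub_threshold = 0L, discordant = 0L,
                discordant_rows = results, af_delta = numeric()))
  det <- results$detected
  sub <- det & !is.na(results$measured_af) & results$measured_af < minAf
  validated <- det & !sub
  delta <- ifelse(det & !is.na(results$ngs_af),
                  results$measured_af - results$ngs_af, NA_real_)
  list(validated = sum(validated), sub_threshold = sum(sub),
       discordant = sum(!det),
       discordant_rows = results[!det, , drop = FALSE],
       af_delta = delta)
}

#' Screen spiked-control replicates for artifactual variants
#'
#' Control replicates (well-characterised reference DNA processed through
#' the full wet-lab and analysis pipeline) must recover the reference
#' truth set and nothing else. Calls are partitioned into truth-set
#' matches and novel calls; a truth variant counts as *recovered* when
#' its observed AF is within `afTol` relative deviation of expectation.
#' The screen passes when the novel count is zero.
#'
#' @param controlCalls Call table from a control replicate.
#' @param truthSet `data.frame` with `chrom`, `pos`, `ref`, `alt`,
#'   `expected_af`.
#' @param afTol Relative AF tolerance for recovery (default 0.20).
#' @return List with `recovered` (truth rows with observed AF and
#'   deviation), `missed`, `novel` (calls matching no truth variant),
#'   `novel_count` and `pass`.
#' @export
artifactScreen <- function(controlCalls, truthSet, afTol = 0.20) {
  tkey <- variant_key(truthSet$chrom, truthSet$pos, truthSet$ref,
                      truthSet$alt)
  ckey <- variant_key(controlCalls$chrom, controlCalls$pos,
                      controlCalls$ref, controlCalls$alt)
  novel <- controlCalls[!(ckey %in% tkey), , drop = FALSE]
  m <- match(tkey, ckey)
  obs_af <- controlCalls$allele_fraction[m]
  dev <- abs(obs_af - truthSet$expected_af) / truthSet$expected_af
  recovered <- !is.na(obs_af) & dev <= afTol
  truth_out <- cbind(truthSet, observed_af = obs_af,
                     relative_deviation = dev, recovered = recovered)
  list(recovered = truth_out[recovered, , drop = FALSE],
       missed = truth_out[!recovered, , drop = FALSE],
       novel = novel, novel_count = nrow(novel),
       pass = nrow(novel) == 0L)
}
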