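#' Synthetic cohort-scale mutation list
#'
#' A deterministic, fully synthetic stand-in for a cohort-wide unique
#' somatic mutation list (the study's own list is only distributed as a
#' supplementary spreadsheet and is not bundled). The list is engineered
#' to mirror the published composition: 126 unique mutations comprising
#' 89 missense, 9 stop, 9 frameshift, 6 in-frame and 13 silent changes,
#' which nominate under the bundled knowledge base into 75 drivers, 23
#' potential drivers and 28 passengers, with the potential drivers
#' sub-annotated 11 recurrent-in-other-cancers / 2 endometrial-only /
#' 10 novel. Driver entries are drawn from (and extended along) the
#' published hotspot registry; potential-driver and passenger entries
#' use synthetic protein changes at non-hotspot positions with synthetic
#' impact annotations.
#'
#' @param kb Base knowledge base (default [defaultKnowledgeBase()]).
#' @return List with `mutations` (columns `patient_id`, `gene`,
#'   `protein_change`, `allele_fraction`) and `kb` (the knowledge base
#'   augmented with the synthetic impact annotations).
#' @examples
#' sl <- syntheticMutationList()
#' table(nominate(sl$mutations, sl$kb)$label)
#' @export
syntheticMutationList <- function(kb = defaultKnowledgeBase()) {
  hot <- kbHotspots(kb)

  ## drivers: every registry spelling except one frameshift, plus extra
  ## substitutions at hotspot positions and one hotspot in-frame deletion
  reg <- hot$example_change
  names(reg) <- hot$gene
  drop_fs <- which(reg == "Q165fs")[1]          # keep 9 frameshifts
  reg <- reg[-drop_fs]
  extra_missense <- data.frame(
    gene = c("PIK3CA", "PIK3CA", "PIK3CA", "KRAS", "KRAS", "KRAS",
             "PTEN", "CTNNB1", "PIK3CA", "PIK3CA"),
    protein_change = c("H1047L", "E545A", "E542A", "G12V", "G12C",
                       "G12S", "R130Q", "D32A", "R93Q", "N345T"),
    stringsAsFactors = FALSE)
  drivers <- rbind(
    data.frame(gene = names(reg), protein_change = unname(reg),
               stringsAsFactors = FALSE),
    extra_missense,
    data.frame(gene = c("PTEN", "PIK3CA"),
               protein_change = c("R130*", "E545del"),
               stringsAsFactors = FALSE))

  ## potential drivers: functional missense away from hotspots,
  ## 11 recurrent-other / 2 endometrial-only / 10 novel
  pd_genes <- rep(c("PIK3CA", "PTEN", "TP53", "KRAS", "CTNNB1", "FBXW7",
                    "ARID1A", "PIK3R1", "FGFR2", "ATM", "APC", "RB1"),
                  length.out = 23)
  pd <- make_offhotspot(pd_genes, hot, base = 950L, kind = "missense")
  pd_ann <- data.frame(
    gene = pd$gene, protein_change = pd$protein_change,
    impact_score = "high",
    seen_in_endometrial = rep(c(FALSE, TRUE, FALSE),
                              c(11, 2, 10)),
    seen_in_other_cancers = rep(c(TRUE, FALSE, FALSE),
                                c(11, 2, 10)),
    stringsAsFactors = FALSE)

  ## passengers: 15 low-impact missense + 13 silent
  ps_genes <- rep(c("ATM", "APC", "RB1", "FBXW7", "ARID1A"),
                  length.out = 15)
  ps <- make_offhotspot(ps_genes, hot, base = 1150L, kind = "missense")
  ps_ann <- data.frame(
    gene = ps$gene, protein_change = ps$protein_change,
    impact_score = "low", seen_in_endometrial = FALSE,
    seen_in_other_cancers = FALSE, stringsAsFactors = FALSE)
  si_genes <- rep(c("PTEN", "PIK3CA", "TP53", "KRAS"), length.out = 13)
  si <- make_offhotspot(si_genes, hot, base = 1300L, kind = "silent")

  mutations <- rbind(drivers, pd[, c("gene", "protein_change")],
                     ps[, c("gene", "protein_change")],
                     si[, c("gene", "protein_change")])
  mutations$patient_id <- sprintf("PTS%02d",
                                  (seq_len(nrow(mutations)) %% 40) + 1)
  mutations$allele_fraction <-
    round(seq(0.011, 0.30, length.out = nrow(mutations)), 4)
  rownames(mutations) <- NULL
  list(mutations = mutations,
       kb = augmentKnowledgeBase(kb, rbind(pd_ann, ps_ann)))
}

# deterministic non-hotspot protein changes, unique per (gene, position)
make_offhotspot <- function(genes, hot, base, kind) {
  used <- new.env()
  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    taken <- hot$aa_start[hot$gene == g]
    prev <- if (!is.null(used[[g]])) used[[g]] else integer()
    pos <- base + 7L * (i - 1L)
    while (pos %in% c(taken, prev)) pos <- pos + 1L
    used[[g]] <- c(prev, pos)
    ref <- AA20[(pos %% 19) + 1]
    alt <- if (kind == "silent") ref else AA20[((pos + 5) %% 19) + 1]
    if (kind != "silent" && alt == ref) alt <- AA20[((pos + 6) %% 19) + 1]
    data.frame(gene = g, protein_change = paste0(ref, pos, alt),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
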