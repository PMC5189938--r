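#' Read a knowledge base from TSV files
#'
#' @param genes,hotspots,variants Paths to the gene-role, hotspot-registry
#'   and variant-annotation tables (see [KnowledgeBase-class] for the
#'   expected columns).
#' @return A [KnowledgeBase-class].
#' @export
readKnowledgeBase <- function(genes, hotspots, variants) {
  g <- utils::read.delim(genes, stringsAsFactors = FALSE)
  h <- utils::read.delim(hotspots, stringsAsFactors = FALSE)
  v <- utils::read.delim(variants, stringsAsFactors = FALSE)
  new("KnowledgeBase", genes = g, hotspots = h, variants = v)
}

#' The bundled endometrial-cancer knowledge base
#'
#' Gene roles and TCGA per-gene statistics for the 12-gene panel, the
#' published per-hotspot registry (including the novel entries flagged as
#' such), and curated variant impact annotations.
#'
#' @return A [KnowledgeBase-class].
#' @examples
#' kb <- defaultKnowledgeBase()
#' head(kbHotspots(kb))
#' @export
defaultKnowledgeBase <- function() {
  ext <- function(f) system.file("extdata", f, package = "lavageMut",
                                 mustWork = TRUE)
  readKnowledgeBase(ext("kb_genes.tsv"), ext("kb_hotspots.tsv"),
                    ext("kb_variants.tsv"))
}

#' Add variant impact annotations to a knowledge base
#'
#' @param kb A [KnowledgeBase-class].
#' @param variants `data.frame` of additional rows for the variant
#'   annotation table.
#' @return The augmented [KnowledgeBase-class].
#' @export
augmentKnowledgeBase <- function(kb, variants) {
  new("KnowledgeBase", genes = kb@genes, hotspots = kb@hotspots,
      variants = rbind(kb@variants, variants[, names(kb@variants)]))
}

impact_rank <- function(score) {
  r <- match(score, IMPACT_LEVELS)
  ifelse(is.na(r), 0L, r)
}

# hotspot registry rows whose residue range covers the parsed change
match_hotspot <- function(hot, gene, pos, end_pos, change) {
  rows <- hot[hot$gene == gene &
                hot$aa_start <= ifelse(is.na(end_pos), pos, end_pos) &
                hot$aa_end >= pos, , drop = FALSE]
  if (nrow(rows) <= 1) return(rows)
  exact <- rows[rows$example_change == change | rows$label == change, ,
                drop = FALSE]
  if (nrow(exact)) exact[1, , drop = FALSE] else rows[1, , drop = FALSE]
}

#' Nominate mutations as drivers, potential drivers or passengers
#'
#' Implements the three-way nomination: a mutation is a *driver* when it
#' lies in a registered hotspot of a major endometrial driver gene
#' (matching at the protein-position level, so any substitution at KRAS
#' G12 qualifies) or when it truncates (stop / frameshift) a major-gene
#' tumor suppressor; a *potential driver* when it is a predicted
#' functional missense change (impact at or above `impactThreshold`) in a
#' major gene; everything else, and every silent change, is a
#' *passenger*. Driver takes precedence when both rules fire. Potential
#' drivers additionally carry exactly one provenance sub-flag:
#' `recurrent_other_cancers`, `endometrial_only` or `novel`.
#'
#' @param calls `data.frame` with at least `gene` and `protein_change`
#'   columns (any call-table columns are carried through).
#' @param kb A [KnowledgeBase-class]; every gene in `calls` must be
#'   present.
#' @param impactThreshold Minimum impact score treated as predicted
#'   functional (default `"medium"`).
#' @return `calls` with added columns `consequence`, `truncating`,
#'   `label`, `evidence` (comma-joined flags) and `subflag`.
#' @examples
#' kb <- defaultKnowledgeBase()
#' nominate(data.frame(gene = c("KRAS", "PTEN", "TP53"),
#'                     protein_change = c("G12D", "W111*", "C176F")), kb)
#' @export
nominate <- function(calls, kb, impactThreshold = "medium") {
  if (nrow(calls) == 0) {
    calls$consequence <- character(); calls$truncating <- logical()
    calls$label <- character(); calls$evidence <- character()
    calls$subflag <- character()
    return(calls)
  }
  genes <- kbGenes(kb)
  absent <- setdiff(unique(calls$gene), genes$symbol)
  if (length(absent))
    stop("gene(s) absent from knowledge base: ",
         paste(absent, collapse = ", "), call. = FALSE)
  thr <- match(impactThreshold, IMPACT_LEVELS)
  if (is.na(thr)) stop("unknown impactThreshold", call. = FALSE)
  parsed <- parseProteinChange(calls$protein_change)
  cons <- classifyConsequence(parsed)
  hot <- kbHotspots(kb)
  vars <- kbVariants(kb)

  out <- calls
  out$consequence <- cons$class
  out$truncating <- cons$truncating
  out$label <- "passenger"; out$evidence <- ""; out$subflag <- NA_character_
  for (i in seq_len(nrow(out))) {
    g <- genes[genes$symbol == out$gene[i], ]
    if (cons$class[i] %in% c("silent", "other")) next
    ev <- character()
    hs <- match_hotspot(hot, out$gene[i], parsed$pos[i], parsed$end_pos[i],
                        out$protein_change[i])
    if (nrow(hs) && g$major_ec_driver) ev <- c(ev, "hotspot")
    if (cons$truncating[i] && g$role == "tumor_suppressor" &&
        g$major_ec_driver) ev <- c(ev, "truncating_tsg")
    if (length(ev)) {
      out$label[i] <- "driver"
      out$evidence[i] <- paste(ev, collapse = ",")
      next
    }
    if (cons$class[i] == "missense" && g$major_ec_driver) {
      va <- vars[vars$gene == out$gene[i] &
                   vars$protein_change == out$protein_change[i], ,
                 drop = FALSE]
      if (nrow(va) && impact_rank(va$impact_score[1]) >= thr) {
        out$label[i] <- "potential_driver"
        out$subflag[i] <-
          if (va$seen_in_endometrial[1]) "endometrial_only"
          else if (va$seen_in_other_cancers[1]) "recurrent_other_cancers"
          else "novel"
        out$evidence[i] <- paste(c("functional_missense", out$subflag[i]),
                                 collapse = ",")
      }
    }
  }
  out
}

#' Sub-annotation counts for potential drivers
#'
#' Partitions the potential drivers by provenance: recurrent in other
#' cancers (but not endometrial), observed in endometrial cancer only, or
#' newly described.
#'
#' @param nominated Output of [nominate()].
#' @return Named integer vector over the three sub-flags; sums to the
#'   number of potential drivers.
#' @export
subannotatePotentialDrivers <- function(nominated) {
  pd <- nominated[nominated$label == "potential_driver", , drop = FALSE]
  tab <- table(factor(pd$subflag,
                      levels = c("recurrent_other_cancers",
                                 "endometrial_only", "novel")))
  stats::setNames(as.integer(tab), names(tab))
}

#' Rank patients by driver burden
#'
#' Orders patients by the sum of driver and potential-driver mutations
#' (descending), breaking ties by driver count and then patient id.
#'
#' @param nominated Output of [nominate()]; must carry `patient_id`.
#' @return `data.frame` with `patient_id`, `driver_count`,
#'   `potential_driver_count`, `burden`, ordered for plotting.
#' @export
rankPatients <- function(nominated) {
  sp <- split(nominated, nominated$patient_id)
  res <- do.call(rbind, lapply(sp, function(d) data.frame(
    patient_id = d$patient_id[1],
    driver_count = sum(d$label == "driver"),
    potential_driver_count = sum(d$label == "potential_driver"),
    stringsAsFactors = FALSE)))
  res$burden <- res$driver_count + res$potential_driver_count
  res <- res[order(-res$burden, -res$driver_count, res$patient_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-gene hotspot comparison table
#'
#' Summarises nominated driver mutations per gene against the knowledge
#' base's TCGA statistics: per-hotspot (lavage count / TCGA count) pairs
#' with novel entries flagged, plus gene-level totals. The gene-level
#' lavage count is by construction the sum of its per-hotspot lavage
#' counts; genes without any nominated driver are omitted.
#'
#' @param nominated Output of [nominate()].
#' @param kb A [KnowledgeBase-class].
#' @return List with `genes` (gene-level totals plus TCGA per-gene
#'   counts) and `hotspots` (per-hotspot lavage/TCGA counts).
#' @export
buildTcgaComparison <- function(nominated, kb) {
  drv <- nominated[nominated$label == "driver", , drop = FALSE]
  if (nrow(drv) == 0)
    return(list(genes = data.frame(), hotspots = data.frame()))
  parsed <- parseProteinChange(drv$protein_change)
  hot <- kbHotspots(kb)
  lab <- vapply(seq_len(nrow(drv)), function(i) {
    hs <- match_hotspot(hot, drv$gene[i], parsed$pos[i], parsed$end_pos[i],
                        drv$protein_change[i])
    if (nrow(hs)) paste(hs$gene[1], hs$label[1], sep = "|")
    else paste(drv$gene[i], drv$protein_change[i], "novel", sep = "|")
  }, character(1))
  cnt <- table(lab)
  hs_rows <- do.call(rbind, lapply(names(cnt), function(k) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    reg <- hot[hot$gene == p[1] & hot$label == p[2], , drop = FALSE]
    data.frame(gene = p[1], label = p[2],
               lavage_count = as.integer(cnt[[k]]),
               tcga_count = if (nrow(reg)) reg$recurrence_endometrial[1]
                            else 0L,
               novel = if (nrow(reg)) reg$novel[1] else TRUE,
               stringsAsFactors = FALSE)
  }))
  genes <- do.call(rbind, lapply(split(hs_rows, hs_rows$gene), function(d) {
    kb_g <- kbGenes(kb)[kbGenes(kb)$symbol == d$gene[1], ]
    data.frame(gene = d$gene[1],
               lavage_count = sum(d$lavage_count),
               tcga_hotspot_count = kb_g$tcga_hotspot_count,
               tcga_mutation_count = kb_g$tcga_mutation_count,
               stringsAsFactors = FALSE)
  }))
  genes <- genes[order(-genes$lavage_count), , drop = FALSE]
  rownames(genes) <- NULL
  rownames(hs_rows) <- NULL
  list(genes = genes, hotspots = hs_rows)
}

#' Patient-by-gene mutation matrix
#'
#' Reduces nominated mutations to one label per patient/gene cell using
#' the hierarchical colouring convention driver > potential driver >
#' passenger, for oncoprint-style display.
#'
#' @param nominated Output of [nominate()].
#' @param genes Gene order for the columns (default: all observed).
#' @return Character matrix, patients as rows, `NA` where unmutated.
#' @export
mutationMatrix <- function(nominated, genes = sort(unique(nominated$gene))) {
  pats <- sort(unique(nominated$patient_id))
  m <- matrix(NA_character_, length(pats), length(genes),
              dimnames = list(pats, genes))
  rank <- c(driver = 3L, potential_driver = 2L, passenger = 1L)
  for (i in seq_len(nrow(nominated))) {
    r <- nominated$patient_id[i]; c <- nominated$gene[i]
    cur <- m[r, c]
    if (is.na(cur) || rank[[nominated$label[i]]] > rank[[cur]])
      m[r, c] <- nominated$label[i]
  }
  m
}
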