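# Default AF strata: (0, 5%], (5%, 10%], (10%, 100%] — matching the
# reported "<=5.00% / 5.01-10.00% / >=10.01%" labels (a fraction of
# exactly 0.05 falls in the first bin).
DEFAULT_AF_BREAKS <- c(0, 0.05, 0.10, 1)

af_bin_index <- function(af, breaks = DEFAULT_AF_BREAKS) {
  if (any(af <= 0 | af > 1))
    stop("allele fractions must lie in (0, 1]", call. = FALSE)
  findInterval(af, breaks, left.open = TRUE, rightmost.closed = TRUE)
}

#' Bin mutations by allele fraction
#'
#' Counts mutations per gene x fraction x AF bin. Bin membership uses
#' left-open intervals, so an allele fraction of exactly 0.05 falls in
#' the first stratum and 0.10 in the second.
#'
#' @param mutations `data.frame` with `gene`, `fraction` and
#'   `allele_fraction` columns.
#' @param breaks Bin breakpoints partitioning (0, 1].
#' @param genes,fractions Row/column universe (defaults: observed values).
#' @return An [AFBinnedTable-class].
#' @export
binByAlleleFraction <- function(mutations, breaks = DEFAULT_AF_BREAKS,
                                genes = sort(unique(mutations$gene)),
                                fractions = sort(unique(mutations$fraction))) {
  nb <- length(breaks) - 1
  idx <- af_bin_index(mutations$allele_fraction, breaks)
  counts <- table(factor(mutations$gene, levels = genes),
                  factor(mutations$fraction, levels = fractions),
                  factor(idx, levels = seq_len(nb)))
  arr <- array(as.integer(counts), dim = dim(counts),
               dimnames = list(genes, fractions, paste0("bin", seq_len(nb))))
  new("AFBinnedTable", counts = arr, breaks = breaks)
}

#' Build an [AFBinnedTable-class] from pre-tabulated counts
#'
#' For working with published summary tables, where only per-gene bin
#' counts are available.
#'
#' @param counts `data.frame` with columns `gene`, `fraction` and one
#'   `bin<k>` column per stratum.
#' @param breaks Bin breakpoints the counts refer to.
#' @return An [AFBinnedTable-class].
#' @export
afBinnedTableFromCounts <- function(counts, breaks = DEFAULT_AF_BREAKS) {
  bins <- grep("^bin[0-9]+$", names(counts), value = TRUE)
  genes <- unique(counts$gene); fracs <- unique(counts$fraction)
  arr <- array(0L, dim = c(length(genes), length(fracs), length(bins)),
               dimnames = list(genes, fracs, bins))
  for (i in seq_len(nrow(counts)))
    arr[counts$gene[i], counts$fraction[i], ] <-
      as.integer(counts[i, bins])
  new("AFBinnedTable", counts = arr, breaks = breaks)
}

#' The published per-gene AF-bin counts
#'
#' The bundled cohort summary table: mutation counts per gene and AF
#' stratum in each lavage fraction, the per-gene concordance columns, and
#' the bottom-row cancer-patient counts per stratum.
#'
#' @return List with `counts` (an [AFBinnedTable-class]), `concordance`
#'   and `patients` data frames.
#' @export
publishedCohortSummary <- function() {
  ext <- function(f) system.file("extdata", f, package = "lavageMut",
                                 mustWork = TRUE)
  list(counts = afBinnedTableFromCounts(
         utils::read.delim(ext("cohort_bin_counts.tsv"))),
       concordance = utils::read.delim(ext("cohort_gene_concordance.tsv")),
       patients = utils::read.delim(ext("cohort_bin_patients.tsv")))
}

#' Pellet/cfDNA concordance of per-gene mutation totals
#'
#' Pearson correlation between the per-gene mutation sums of the
#' cell-pellet and cfDNA fractions.
#'
#' @param table An [AFBinnedTable-class] containing both lavage
#'   fractions.
#' @return List with `pearson_r`, `r_squared` (full precision) and
#'   `r_squared_2dp` for report display.
#' @examples
#' geneSumCorrelation(publishedCohortSummary()$counts)$r_squared_2dp
#' @export
geneSumCorrelation <- function(table) {
  a <- geneSums(table, "cell_pellet"); b <- geneSums(table, "cfdna")
  if (sum(a > 0 | b > 0) < 3)
    stop("need at least 3 genes with nonzero totals", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(pearson_r = NA_real_, r_squared = NA_real_,
                r_squared_2dp = NA_real_, degenerate = TRUE))
  r <- stats::cor(a, b)
  list(pearson_r = r, r_squared = r^2, r_squared_2dp = round(r^2, 2),
       degenerate = FALSE)
}

#' Cancer-diagnosed fraction of patients per AF stratum
#'
#' A patient belongs to a stratum of a fraction when they carry at least
#' one mutation in that stratum there (a patient may appear in several
#' strata). Given per-mutation data plus the clinical table this computes
#' the counts; given a pre-tabulated `data.frame` of counts (columns
#' `fraction`, `bin`, `cancer`, `total`) it computes percentages
#' directly.
#'
#' @param x Mutation `data.frame` (with `patient_id`, `fraction`,
#'   `allele_fraction`) or a counts `data.frame`.
#' @param clinical Clinical table with `patient_id` and `cancer`; ignored
#'   for pre-tabulated input.
#' @param breaks AF bin breakpoints.
#' @return `data.frame` with `fraction`, `bin`, `cancer`, `total`,
#'   `percentage` (integer-rounded; `NA` for empty strata).
#' @export
cancerFractionByBin <- function(x, clinical = NULL,
                                breaks = DEFAULT_AF_BREAKS) {
  if (all(c("cancer", "total") %in% names(x))) {
    out <- x
  } else {
    stopifnot(!is.null(clinical))
    idx <- af_bin_index(x$allele_fraction, breaks)
    nb <- length(breaks) - 1
    out <- do.call(rbind, lapply(unique(x$fraction), function(f) {
      do.call(rbind, lapply(seq_len(nb), function(b) {
        pats <- unique(x$patient_id[x$fraction == f & idx == b])
        data.frame(fraction = f, bin = b,
                   cancer = sum(clinical$cancer[
                     clinical$patient_id %in% pats]),
                   total = length(pats))
      }))
    }))
  }
  out$percentage <- ifelse(out$total > 0,
                           as.integer(round(100 * out$cancer / out$total)),
                           NA_integer_)
  out
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test; the two-sided p-value sums all tables with
#' the observed margins whose probability does not exceed the observed
#' table's.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"two_sided"`, `"greater"` or `"less"`.
#' @return The exact p-value.
#' @export
fisherExact2x2 <- function(table, alternative = c("two_sided", "greater",
                                                  "less")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (!all(dim(table) == 2) || any(table < 0) ||
      any(table != round(table)))
    stop("table must be a 2x2 matrix of non-negative integers",
         call. = FALSE)
  alt <- c(two_sided = "two.sided", greater = "greater", less = "less")
  stats::fisher.test(table, alternative = alt[[alternative]])$p.value
}

#' One-tailed Mann-Whitney-Wilcoxon test
#'
#' Tests the alternative that `groupA` (e.g. the mutated patients) is
#' stochastically larger than `groupB`. Small, tie-free samples (both
#' groups at most 20) use the exact null distribution; larger or tied
#' samples use the normal approximation with tie correction.
#'
#' @param groupA,groupB Numeric vectors (each non-empty).
#' @return List with the rank-sum statistic `U` and one-sided `p`.
#' @export
mannWhitneyOneTailed <- function(groupA, groupB) {
  if (!length(groupA) || !length(groupB))
    stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(groupA, groupB)) > 0
  exact <- length(groupA) <= 20 && length(groupB) <= 20 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(groupA, groupB, alternative = "greater",
                       exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; output is capped at 1 and
#' never smaller than the input.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bhAdjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' One-sided bootstrap confidence bound for a location difference
#'
#' Lower confidence bound for `mean(groupA) - mean(groupB)` via the
#' one-sided bootstrap percentile method; the interval is
#' `[bound, Inf)`.
#'
#' @param groupA,groupB Numeric vectors (each with at least 2 values).
#' @param level Confidence level (default 0.95).
#' @param nboot Bootstrap resamples (default 10000).
#' @param seed RNG seed for reproducibility.
#' @return The lower bound.
#' @export
oneSidedLocationCi <- function(groupA, groupB, level = 0.95,
                               nboot = 10000L, seed = 1L) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("both groups need at least 2 values", call. = FALSE)
  boots <- with_seed(seed, {
    vapply(seq_len(nboot), function(i)
      mean(sample(groupA, replace = TRUE)) -
        mean(sample(groupB, replace = TRUE)), numeric(1))
  })
  unname(stats::quantile(boots, 1 - level))
}

#' Cancer enrichment in the high allele-fraction stratum
#'
#' Contrasts patients carrying at least one >10% AF mutation in the given
#' fraction against patients whose mutations there all lie in the lower
#' strata, testing association with cancer diagnosis by Fisher's exact
#' test. (The exact 2x2 construction behind the published p-values is not
#' recoverable from the printed counts; this construction is the
#' package's documented choice.)
#'
#' @param mutations Mutation table (`patient_id`, `fraction`,
#'   `allele_fraction`).
#' @param clinical Clinical table (`patient_id`, `cancer`).
#' @param fraction Which lavage fraction to test.
#' @param breaks AF bin breakpoints; the last stratum is the "high" one.
#' @param alternative Passed to [fisherExact2x2()].
#' @return List with the 2x2 `table` and `p` (`NA` with a warning when a
#'   margin is degenerate).
#' @export
binEnrichmentTest <- function(mutations, clinical, fraction = "cfdna",
                              breaks = DEFAULT_AF_BREAKS,
                              alternative = "two_sided") {
  m <- mutations[mutations$fraction == fraction, , drop = FALSE]
  if (nrow(m) == 0) {
    warning("no mutations in fraction ", fraction)
    return(list(table = NULL, p = NA_real_))
  }
  idx <- af_bin_index(m$allele_fraction, breaks)
  high_bin <- length(breaks) - 1
  pats <- unique(m$patient_id)
  high <- vapply(pats, function(p) any(idx[m$patient_id == p] == high_bin),
                 logical(1))
  cancer <- clinical$cancer[match(pats, clinical$patient_id)]
  if (length(unique(high)) < 2 || length(unique(cancer)) < 2 ||
      anyNA(cancer)) {
    warning("degenerate margins; enrichment test not defined")
    return(list(table = NULL, p = NA_real_))
  }
  tab <- table(cancer = factor(cancer, c(TRUE, FALSE)),
               high_af = factor(high, c(TRUE, FALSE)))
  list(table = tab, p = fisherExact2x2(tab, alternative))
}

#' Univariate clinical association scan
#'
#' Tests each clinical covariate against per-patient mutation status
#' (carrying at least one driver or potential-driver mutation, or a
#' caller-supplied status). Continuous and ordinal covariates (age, BMI,
#' parity, menopausal status coded 0/1, smoking coded ordinal
#' never < former < current) use the one-tailed Mann-Whitney test of the
#' mutated group being larger; nominal covariates (race) use Fisher's
#' exact test on the contingency table. P-values are BH-adjusted across
#' the scanned family, and continuous covariates get a one-sided 95%
#' bootstrap lower bound for the mutated-minus-unmutated mean
#' difference.
#'
#' @param clinical Clinical table (see [readClinical()]).
#' @param status Logical vector of mutation status aligned with
#'   `clinical`, or a nominated-mutation table from which status is
#'   derived.
#' @param covariates Covariates to scan.
#' @param ciSeed Seed for the bootstrap bounds.
#' @return `data.frame` with one row per covariate: test name, group
#'   summaries, raw and BH-adjusted p, and CI lower bound.
#' @export
clinicalAssociationScan <- function(clinical, status,
                                    covariates = c("age", "race", "bmi",
                                                   "diabetes", "parity",
                                                   "smoking", "menopausal"),
                                    ciSeed = 1L) {
  if (is.data.frame(status)) {
    carriers <- unique(status$patient_id[
      status$label %in% c("driver", "potential_driver")])
    status <- clinical$patient_id %in% carriers
  }
  stopifnot(length(status) == nrow(clinical))
  if (length(unique(status)) < 2) {
    warning("all patients share one mutation status; tests undefined")
    return(data.frame(covariate = covariates, test = NA, p = NA,
                      p_adjusted = NA))
  }
  smoking_levels <- c(never = 0, former = 1, current = 2)
  rows <- lapply(covariates, function(cv) {
    v <- clinical[[cv]]
    if (all(is.na(v))) {
      warning("covariate ", cv, " entirely missing; skipped")
      return(NULL)
    }
    if (cv == "race") {
      keep <- !is.na(v)
      tab <- table(v[keep], status[keep])
      p <- stats::fisher.test(tab)$p.value
      return(data.frame(covariate = cv, test = "fisher_exact",
                        mean_mutated = NA_real_, mean_other = NA_real_,
                        ci_lower = NA_real_, p = p,
                        stringsAsFactors = FALSE))
    }
    num <- switch(cv,
                  menopausal = as.numeric(v),
                  diabetes = as.numeric(v),
                  smoking = unname(smoking_levels[as.character(v)]),
                  as.numeric(v))
    keep <- !is.na(num)
    a <- num[keep & status]; b <- num[keep & !status]
    mw <- mannWhitneyOneTailed(a, b)
    ci <- if (cv %in% c("age", "bmi") && length(a) > 1 && length(b) > 1)
      oneSidedLocationCi(a, b, seed = ciSeed) else NA_real_
    data.frame(covariate = cv, test = "mann_whitney_one_tailed",
               mean_mutated = mean(a), mean_other = mean(b),
               ci_lower = ci, p = mw$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- bhAdjust(res$p)
  rownames(res) <- NULL
  res
}

#' Per-gene association scans
#'
#' Runs [clinicalAssociationScan()] with mutation status restricted to
#' each gene in turn (its own BH family per gene).
#'
#' @param clinical Clinical table.
#' @param nominated Nominated-mutation table.
#' @param genes Genes to scan (default: all mutated genes).
#' @param ... Passed through to [clinicalAssociationScan()].
#' @return Named list of per-gene scan results.
#' @export
perGeneAssociationScan <- function(clinical, nominated,
                                   genes = sort(unique(nominated$gene)),
                                   ...) {
  out <- lapply(genes, function(g) {
    carriers <- unique(nominated$patient_id[
      nominated$gene == g &
        nominated$label %in% c("driver", "potential_driver")])
    clinicalAssociationScan(clinical,
                            clinical$patient_id %in% carriers, ...)
  })
  stats::setNames(out, genes)
}

#' Cross-fraction mutation concordance
#'
#' Partitions mutations (keyed by patient, gene and protein change) by
#' the lavage fractions they were observed in, and summarises per-gene
#' patient counts.
#'
#' @param mutations Mutation table with `patient_id`, `gene`,
#'   `protein_change`, `fraction`.
#' @param clinical Optional clinical table for cancer-diagnosed patient
#'   counts.
#' @return List with `per_mutation` (columns `patient_id`, `gene`,
#'   `protein_change`, `observed_in`), `summary` (counts of pellet-only /
#'   cfdna-only / both) and `per_gene` (mutations seen in both fractions,
#'   unique mutated patients, cancer-diagnosed patients).
#' @export
fractionConcordance <- function(mutations, clinical = NULL) {
  key <- paste(mutations$patient_id, mutations$gene,
               mutations$protein_change, sep = "|")
  per <- do.call(rbind, lapply(split(mutations, key), function(d) {
    fr <- unique(d$fraction)
    obs <- if (all(LAVAGE_FRACTIONS %in% fr)) "both"
    else if ("cell_pellet" %in% fr) "pellet_only" else "cfdna_only"
    data.frame(patient_id = d$patient_id[1], gene = d$gene[1],
               protein_change = d$protein_change[1], observed_in = obs,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  summ <- table(factor(per$observed_in,
                       c("pellet_only", "cfdna_only", "both")))
  per_gene <- do.call(rbind, lapply(split(per, per$gene), function(d) {
    pats <- unique(d$patient_id)
    data.frame(gene = d$gene[1],
               mut_both = sum(d$observed_in == "both"),
               unique_patients = length(pats),
               cancer_patients = if (is.null(clinical)) NA_integer_
               else sum(clinical$cancer[
                 match(pats, clinical$patient_id)], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  list(per_mutation = per,
       summary = stats::setNames(as.integer(summ), names(summ)),
       per_gene = per_gene)
}
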