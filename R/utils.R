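# Internal helpers shared across modules.

FRACTIONS <- c("germline", "cell_pellet", "cfdna", "tumor")
LAVAGE_FRACTIONS <- c("cell_pellet", "cfdna")
IMPACT_LEVELS <- c("neutral", "low", "medium", "high")

#' Run code with a temporary RNG seed
#'
#' Evaluates an expression under `set.seed(seed)` and restores the caller's
#' RNG state afterwards, so seeded simulation calls do not perturb the
#' session stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' @noRd
assert_fraction <- function(fraction) {
  if (!all(fraction %in% FRACTIONS))
    stop("fraction must be one of: ", paste(FRACTIONS, collapse = ", "),
         call. = FALSE)
  fraction
}

# Canonical empty call table; every reader/filter returns this shape.
empty_calls <- function() {
  data.frame(
    patient_id = character(), fraction = character(), chrom = character(),
    pos = integer(), ref = character(), alt = character(),
    gene = character(), protein_change = character(),
    depth = integer(), alt_reads = integer(), allele_fraction = numeric(),
    callers = character(), stringsAsFactors = FALSE)
}

validate_calls <- function(calls) {
  need <- names(empty_calls())
  miss <- setdiff(need, names(calls))
  if (length(miss))
    stop("call table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(calls$alt_reads > calls$depth, na.rm = TRUE))
    stop("alt_reads exceeds depth", call. = FALSE)
  invisible(calls)
}

#' Read the canonical tab-separated call table
#'
#' @param path Path to a TSV written by [writeCallTable()].
#' @return A call-table `data.frame`.
#' @export
readCallTable <- function(path) {
  calls <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = NA, na.strings = c("NA", ""))
  calls$pos <- as.integer(calls$pos)
  validate_calls(calls)
}

#' Write the canonical tab-separated call table
#'
#' @param calls A call-table `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCallTable <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
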