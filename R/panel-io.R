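#' Read a panel definition from a BED file
#'
#' Amplicon regions are read from a BED file (0-based half-open; the `name`
#' column carries the gene symbol) and SNP fingerprint loci from a
#' tab-separated table with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#' `maf`.
#'
#' @param bed Path to the amplicon BED file.
#' @param snpLoci Optional path to the SNP-locus TSV.
#' @param name Panel name.
#' @return A [PanelDefinition-class].
#' @examples
#' panel <- defaultPanel()
#' ampliconCount(panel)
#' @importFrom rtracklayer import
#' @export
readPanelBed <- function(bed, snpLoci = NULL, name = basename(bed)) {
  gr <- rtracklayer::import(bed, format = "BED")
  mcols(gr)$gene <- mcols(gr)$name
  snp <- GRanges()
  if (!is.null(snpLoci)) {
    tab <- utils::read.delim(snpLoci, stringsAsFactors = FALSE)
    snp <- GRanges(tab$chrom, IRanges(tab$pos, width = 1),
                   ref = tab$ref, alt = tab$alt, maf = tab$maf)
  }
  new("PanelDefinition", name = name, amplicons = gr, snpLoci = snp)
}

#' The bundled 12-gene endometrial cancer panel
#'
#' A 12-gene, 102-amplicon targeted panel (mean amplicon length 138 bp,
#' GRCh37) covering PTEN, PIK3CA, TP53, CTNNB1, KRAS, FGFR2, FBXW7, RB1,
#' ATM, APC, ARID1A and PIK3R1, with a 24-locus germline SNP fingerprint
#' spike-in. Amplicon coordinates tile the real GRCh37 gene loci but are a
#' synthetic stand-in layout (the study's exact amplicon table is not
#' redistributed); the SNP set is likewise a synthetic high-MAF stand-in.
#'
#' @return A [PanelDefinition-class].
#' @export
defaultPanel <- function() {
  readPanelBed(
    system.file("extdata", "panel_12gene_synthetic.bed",
                package = "lavageMut", mustWork = TRUE),
    system.file("extdata", "snp_loci_synthetic.tsv",
                package = "lavageMut", mustWork = TRUE),
    name = "endometrial-12gene")
}

#' Read a clinical covariate table
#'
#' Expects a CSV with header `patient_id, age, race, bmi, diabetes, parity,
#' smoking, menopausal, preop_dx, final_dx, cancer, stage, grade`.
#' `diabetes`, `menopausal` and `cancer` are coerced to logical; `stage`
#' and `grade` may be empty for non-cancer patients.
#'
#' @param path CSV path.
#' @return A `data.frame`, one row per patient.
#' @export
readClinical <- function(path) {
  cl <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  need <- c("patient_id", "age", "race", "bmi", "diabetes", "parity",
            "smoking", "menopausal", "cancer")
  miss <- setdiff(need, names(cl))
  if (length(miss))
    stop("clinical table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("diabetes", "menopausal", "cancer"))
    cl[[col]] <- as.logical(cl[[col]])
  if (any(cl$age <= 0, na.rm = TRUE)) stop("age must be positive")
  cl
}
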