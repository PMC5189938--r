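# Independent oracles: brute-force / closed-form references kept separate
# from the implementation paths they check.

# Full hypergeometric enumeration of a 2x2 table with fixed margins.
fisher_enum <- function(tab, alternative = "two_sided") {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  supp <- lo:hi
  probs <- stats::dhyper(supp, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  switch(alternative,
    two_sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
    greater = sum(probs[supp >= a]),
    less = sum(probs[supp <= a]))
}

# Exact permutation enumeration of the one-sided Mann-Whitney test
# (alternative: group a stochastically larger).
mw_perm <- function(a, b) {
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pooled <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(pooled), n)
  u_obs <- u_stat(a, b)
  us <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
  mean(us >= u_obs - 1e-9)
}

# Step-up adjustment applied from the definition.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    prev <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- prev
  }
  pmin(adj, 1)
}

# Minimal call-table row builder.
make_call <- function(patient_id = "PT001", fraction = "cell_pellet",
                      chrom = "chr10", pos = 89623200L, ref = "A",
                      alt = "T", gene = "PTEN", protein_change = "R130G",
                      depth = 5000L, alt_reads = 100L,
                      callers = "mutect") {
  data.frame(patient_id = patient_id, fraction = fraction, chrom = chrom,
             pos = as.integer(pos), ref = ref, alt = alt, gene = gene,
             protein_change = protein_change, depth = as.integer(depth),
             alt_reads = as.integer(alt_reads),
             allele_fraction = alt_reads / depth, callers = callers,
             stringsAsFactors = FALSE)
}

# Hand-written VCF fixture writer (body lines supplied verbatim).
write_fixture_vcf <- function(body, path = tempfile(fileext = ".vcf"),
                              sample = "S1") {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
           "##INFO=<ID=PCHG,Number=1,Type=String,Description=\"p\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  writeLines(c(hdr, body), path)
  path
}

# Small three-region panel on one chromosome for interval tests
# (BED 0-based half-open).
small_panel <- function(regions = data.frame(
                          chrom = "chr1",
                          start = c(100L, 500L, 900L),
                          end = c(200L, 650L, 1000L),
                          name = c("G1", "G2", "G3"))) {
  bed <- tempfile(fileext = ".bed")
  utils::write.table(regions, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  readPanelBed(bed, name = "small")
}
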