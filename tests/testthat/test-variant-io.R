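test_that("VCF parsing decomposes records into per-ALT calls", {
  # empty VCF
  p0 <- write_fixture_vcf(character())
  expect_identical(nrow(readCallerVcf(p0, "PT001", "cfdna", "mutect")), 0L)

  # 3 records, one multi-allelic -> 4 calls; hand-parsed expectations
  body <- c(
    "chr10\t89623300\t.\tA\tT\t.\tPASS\tGENE=PTEN;PCHG=R130G\tGT:DP:AD\t0/1:5000:4900,100",
    "chr10\t89623400\t.\tC\tG,CA\t.\tPASS\tGENE=PTEN\tGT:DP:AD\t0/1:4000:3700,250,50",
    "chr12\t25358300\t.\tG\tA\t.\tPASS\tGENE=KRAS;PCHG=G12D\tGT:DP:AD\t0/1:5200:5044,156")
  calls <- readCallerVcf(write_fixture_vcf(body), "PT001", "cell_pellet",
                         "mutect")
  expect_identical(nrow(calls), 4L)
  expect_equal(calls$allele_fraction[calls$pos == 89623300], 100 / 5000)
  multi <- calls[calls$pos == 89623400, ]
  expect_setequal(multi$alt, c("G", "CA"))
  expect_equal(sort(multi$alt_reads), c(50L, 250L))
  expect_equal(multi$depth, c(4000L, 4000L))
  expect_equal(calls$allele_fraction[calls$pos == 25358300], 0.03)
  expect_identical(calls$gene[calls$pos == 25358300], "KRAS")
  expect_identical(calls$protein_change[calls$pos == 25358300], "G12D")

  # depth fields missing -> field error
  hdr_nodp <- c("##fileformat=VCFv4.2",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
                "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
                "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1")
  p2 <- tempfile(fileext = ".vcf"); writeLines(hdr_nodp, p2)
  expect_error(readCallerVcf(p2, "PT001", "cfdna", "mutect"), "DP/AD")
})

test_that("caller merging enforces the concordance rule", {
  v <- make_call(callers = "mutect")
  # single-caller variant dropped at the default 2-caller rule
  expect_identical(nrow(mergeCallerOutputs(list(mutect = v))), 0L)
  expect_identical(nrow(mergeCallerOutputs(list(mutect = v),
                                           minCallers = 1L)), 1L)

  # identical call from 3 callers -> one call, callers = union
  three <- list(mutect = v,
                varscan = transform(v, callers = "varscan", depth = 5100L),
                lofreq = transform(v, callers = "lofreq"))
  m <- mergeCallerOutputs(three)
  expect_identical(nrow(m), 1L)
  expect_identical(m$callers, "lofreq,mutect,varscan")
  expect_identical(m$depth, 5100L)  # greatest-depth caller wins

  expect_error(mergeCallerOutputs(list(mutect = v), minCallers = 0L),
               "minCallers")
})

test_that("merging retains exactly the caller intersection", {
  set.seed(42)
  pos <- sample(1000:9999, 10)
  mk <- function(idx, who) do.call(rbind, lapply(idx, function(i)
    make_call(pos = pos[i], alt = "G", callers = who)))
  a_idx <- 1:7; b_idx <- 4:10       # overlap of size 4
  m <- mergeCallerOutputs(list(mutect = mk(a_idx, "mutect"),
                               lofreq = mk(b_idx, "lofreq")))
  expect_identical(nrow(m), 4L)
  expect_setequal(m$pos, pos[intersect(a_idx, b_idx)])
})

test_that("panel filtering honours the half-open BED convention", {
  panel <- small_panel()
  at <- function(pos) make_call(chrom = "chr1", pos = pos)
  # pos == BED start is outside; pos == BED end is inside
  expect_identical(nrow(filterByPanel(at(100L), panel)), 0L)
  expect_identical(nrow(filterByPanel(at(101L), panel)), 1L)
  expect_identical(nrow(filterByPanel(at(200L), panel)), 1L)
  expect_identical(nrow(filterByPanel(at(201L), panel)), 0L)
  # off-panel chromosome is logged, not an error
  expect_message(
    out <- filterByPanel(make_call(chrom = "chrX", pos = 150L), panel),
    "absent from panel")
  expect_identical(nrow(out), 0L)
})

test_that("panel filtering matches a brute-force interval scan", {
  panel <- small_panel()
  set.seed(7)
  pos <- sample(1:1200, 100, replace = TRUE)
  calls <- do.call(rbind, lapply(pos, function(p)
    make_call(chrom = "chr1", pos = p)))
  kept <- filterByPanel(calls, panel)
  regions <- data.frame(s = c(100, 500, 900), e = c(200, 650, 1000))
  inside <- vapply(pos, function(p)
    any(regions$s < p & p <= regions$e), logical(1))
  expect_setequal(kept$pos, pos[inside])
  expect_identical(nrow(kept), sum(inside))
})

test_that("germline subtraction removes matched-normal and SNP loci", {
  germ <- rbind(make_call(fraction = "germline", pos = 89623300L,
                          alt_reads = 2500L),
                make_call(fraction = "germline", pos = 89623400L,
                          alt_reads = 400L))  # AF 0.08: still germline
  pel <- rbind(make_call(pos = 89623300L),          # in germline
               make_call(pos = 89623400L),          # low-AF germline
               make_call(pos = 89623500L))          # somatic
  cf <- make_call(fraction = "cfdna", pos = 89623500L)
  trio <- PatientTrio("PT001", rbind(germ, pel, cf))
  som <- subtractGermline(trio)
  expect_identical(som$cell_pellet$pos, 89623500L)
  expect_identical(som$cfdna$pos, 89623500L)

  # idempotence: subtracting again changes nothing
  trio2 <- PatientTrio("PT001", rbind(germ, som$cell_pellet, som$cfdna))
  som2 <- subtractGermline(trio2)
  expect_identical(som2$cell_pellet, som$cell_pellet)

  # missing germline is a hard error
  expect_error(subtractGermline(PatientTrio("PT001", pel)), "germline")

  # SNP fingerprint loci never emitted as somatic
  panel <- defaultPanel()
  snp1 <- panelSnpLoci(panel)[1]
  pel_snp <- make_call(chrom = as.character(GenomicRanges::seqnames(snp1)),
                       pos = GenomicRanges::start(snp1))
  trio3 <- PatientTrio("PT001", rbind(germ, pel_snp))
  expect_identical(nrow(subtractGermline(trio3, panel)$cell_pellet), 0L)
})

test_that("planted germline/somatic mix survives subtraction exactly", {
  set.seed(11)
  gpos <- sample(1e6:2e6, 25)
  germ <- do.call(rbind, lapply(gpos[1:20], function(p)
    make_call(fraction = "germline", pos = p)))
  pellet <- do.call(rbind, lapply(gpos, function(p) make_call(pos = p)))
  trio <- PatientTrio("PT001", rbind(germ, pellet))
  som <- subtractGermline(trio)$cell_pellet
  expect_identical(nrow(som), 5L)
  expect_setequal(som$pos, gpos[21:25])
})

test_that("reporting threshold is inclusive at 1%", {
  calls <- rbind(make_call(pos = 1L, alt_reads = 45L),    # 0.009
                 make_call(pos = 2L, alt_reads = 50L),    # 0.010 exactly
                 make_call(pos = 3L, alt_reads = 150L))   # 0.030
  out <- applyReportingThreshold(calls)
  expect_setequal(out$pos, c(2L, 3L))
  expect_error(applyReportingThreshold(calls, minAf = 0), "minAf")
  expect_error(applyReportingThreshold(calls, minAf = 1.2), "minAf")
})

test_that("panel and threshold filters commute and outputs obey invariants", {
  panel <- small_panel()
  set.seed(3)
  calls <- do.call(rbind, lapply(1:200, function(i)
    make_call(chrom = "chr1", pos = sample(1:1200, 1),
              alt_reads = sample(10:500, 1))))
  a <- applyReportingThreshold(filterByPanel(calls, panel), 0.01)
  b <- filterByPanel(applyReportingThreshold(calls, 0.01), panel)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a[order(a$pos), ], b[order(b$pos), ],
               ignore_attr = TRUE)
  expect_true(all(a$allele_fraction >= 0.01))
  regions <- data.frame(s = c(100, 500, 900), e = c(200, 650, 1000))
  expect_true(all(vapply(a$pos, function(p)
    any(regions$s < p & p <= regions$e), logical(1))))
})

test_that("call tables round-trip through the TSV interchange format", {
  calls <- rbind(make_call(), make_call(pos = 2L, protein_change = NA))
  path <- tempfile(fileext = ".tsv")
  writeCallTable(calls, path)
  back <- readCallTable(path)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$allele_fraction, calls$allele_fraction)
  expect_identical(back$protein_change[2], NA_character_)
})
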