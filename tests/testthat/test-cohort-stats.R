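test_that("AF binning honours the stratum boundaries", {
  m <- data.frame(gene = "PTEN", fraction = "cell_pellet",
                  allele_fraction = c(0.049, 0.05, 0.0501, 0.10, 0.1001,
                                      1.0))
  tab <- binByAlleleFraction(m)
  expect_equal(unname(binCounts(tab)["PTEN", "cell_pellet", ]),
               c(2L, 2L, 2L))
  expect_error(
    binByAlleleFraction(data.frame(gene = "X", fraction = "cfdna",
                                   allele_fraction = 0)),
    "allele fractions")
})

test_that("AF binning equals a brute-force comparison loop", {
  set.seed(31)
  m <- data.frame(gene = sample(c("A", "B", "C"), 1000, replace = TRUE),
                  fraction = sample(c("cell_pellet", "cfdna"), 1000,
                                    replace = TRUE),
                  allele_fraction = runif(1000, 1e-6, 1))
  tab <- binByAlleleFraction(m)
  breaks <- binBreaks(tab)
  for (g in c("A", "B", "C")) for (f in c("cell_pellet", "cfdna")) {
    af <- m$allele_fraction[m$gene == g & m$fraction == f]
    brute <- vapply(seq_len(length(breaks) - 1), function(b)
      sum(af > breaks[b] & af <= breaks[b + 1]), integer(1))
    expect_equal(unname(binCounts(tab)[g, f, ]), brute)
  }
  # row sums always reproduce the per-gene totals
  expect_equal(unname(geneSums(tab, "cfdna")),
               unname(vapply(c("A", "B", "C"), function(g)
                 sum(m$gene == g & m$fraction == "cfdna"), integer(1))))
})

test_that("gene-sum correlation matches the from-definition formula", {
  pub <- publishedCohortSummary()$counts
  # identical vectors give r^2 = 1
  ident <- afBinnedTableFromCounts(data.frame(
    gene = rep(c("A", "B", "C"), 2),
    fraction = rep(c("cell_pellet", "cfdna"), each = 3),
    bin1 = c(1, 5, 9, 1, 5, 9), bin2 = 0, bin3 = 0))
  expect_equal(geneSumCorrelation(ident)$r_squared, 1.0)
  # random vectors vs covariance-formula oracle
  set.seed(17)
  x <- rpois(12, 10); y <- rpois(12, 10)
  tab <- afBinnedTableFromCounts(data.frame(
    gene = rep(paste0("G", 1:12), 2),
    fraction = rep(c("cell_pellet", "cfdna"), each = 12),
    bin1 = c(x, y), bin2 = 0, bin3 = 0))
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(geneSumCorrelation(tab)$pearson_r, r_oracle,
               tolerance = 1e-12)
  # symmetry under swapping the fraction vectors
  swapped <- afBinnedTableFromCounts(data.frame(
    gene = rep(paste0("G", 1:12), 2),
    fraction = rep(c("cfdna", "cell_pellet"), each = 12),
    bin1 = c(x, y), bin2 = 0, bin3 = 0))
  expect_equal(geneSumCorrelation(swapped)$r_squared,
               geneSumCorrelation(tab)$r_squared)
  # zero variance is flagged, not an error
  flat <- afBinnedTableFromCounts(data.frame(
    gene = rep(c("A", "B", "C"), 2),
    fraction = rep(c("cell_pellet", "cfdna"), each = 3),
    bin1 = c(3, 3, 3, 1, 5, 9), bin2 = 0, bin3 = 0))
  expect_true(geneSumCorrelation(flat)$degenerate)
})

test_that("cancer fractions per stratum reproduce the published row", {
  res <- cancerFractionByBin(publishedCohortSummary()$patients)
  pellet <- res$percentage[res$fraction == "cell_pellet"]
  cfdna <- res$percentage[res$fraction == "cfdna"]
  expect_identical(pellet, c(9L, 27L, 50L))
  expect_identical(cfdna, c(15L, 25L, 75L))
  # from per-mutation data: all-cancer cohort gives 100% everywhere
  m <- data.frame(patient_id = c("P1", "P2", "P1"),
                  fraction = "cfdna",
                  allele_fraction = c(0.02, 0.08, 0.2))
  cl <- data.frame(patient_id = c("P1", "P2"), cancer = TRUE)
  r2 <- cancerFractionByBin(m, cl)
  expect_true(all(r2$percentage[r2$total > 0] == 100L))
  expect_true(is.na(r2$percentage[r2$total == 0][1]))
})

test_that("Fisher wrapper equals hypergeometric enumeration", {
  expect_equal(fisherExact2x2(matrix(c(4, 4, 7, 7), 2)), 1.0)
  t1 <- matrix(c(3, 6, 1, 31), 2)
  expect_equal(fisherExact2x2(t1), fisher_enum(t1), tolerance = 1e-9)
  expect_equal(fisherExact2x2(t1, "greater"),
               fisher_enum(t1, "greater"), tolerance = 1e-9)
  # extreme table closed form: 2 / C(20, 10)
  t2 <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(fisherExact2x2(t2), 2 / choose(20, 10), tolerance = 1e-9)
  expect_error(fisherExact2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  # random small tables vs enumeration
  set.seed(23)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 5), 2)
    for (alt in c("two_sided", "greater", "less"))
      expect_equal(fisherExact2x2(tab, alt), fisher_enum(tab, alt),
                   tolerance = 1e-9)
  }
})

test_that("one-tailed Mann-Whitney equals permutation enumeration", {
  # extreme ordering closed form: 1 / C(6, 3)
  expect_equal(mannWhitneyOneTailed(c(4, 5, 6), c(1, 2, 3))$p, 0.05)
  set.seed(29)
  for (i in 1:10) {
    vals <- sample(seq(-3, 3, by = 0.01), 15)  # tie-free
    a <- vals[1:8]; b <- vals[9:15]
    expect_equal(mannWhitneyOneTailed(a, b)$p, mw_perm(a, b),
                 tolerance = 1e-9)
  }
  expect_error(mannWhitneyOneTailed(numeric(), 1:3), "non-empty")
})

test_that("BH adjustment equals the step-up formula", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(37)
  for (i in 1:20) {
    p <- runif(sample(1:15, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, bh_stepup(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    # order invariance
    o <- sample(length(p))
    expect_equal(bhAdjust(p[o]), adj[o])
  }
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("bootstrap location bound is seeded and sane in the limit", {
  # identical constant groups: no variability, bound 0
  expect_equal(oneSidedLocationCi(rep(5, 10), rep(5, 12)), 0)
  # determinism under the same seed
  set.seed(41); a <- rnorm(40, 10); b <- rnorm(40, 7)
  expect_identical(oneSidedLocationCi(a, b, seed = 9L),
                   oneSidedLocationCi(a, b, seed = 9L))
  # large-n agreement with the one-sided z bound
  set.seed(43)
  a <- rnorm(400, 58, 12); b <- rnorm(400, 50, 12)
  z <- (mean(a) - mean(b)) -
    qnorm(0.95) * sqrt(var(a) / 400 + var(b) / 400)
  expect_lt(abs(oneSidedLocationCi(a, b, seed = 2L) - z), 0.25)
})

test_that("association scan finds a planted age shift and degenerates safely", {
  set.seed(47)
  n <- 300
  status <- rep(c(TRUE, FALSE), c(148, 152))
  cl <- data.frame(
    patient_id = sprintf("P%03d", 1:n),
    age = rnorm(n, 50.35, 12) + 7.61 * status,
    race = sample(c("white", "asian"), n, TRUE),
    bmi = rnorm(n, 27, 4),
    diabetes = runif(n) < 0.15,
    parity = rpois(n, 1.3),
    smoking = sample(c("never", "former"), n, TRUE),
    menopausal = runif(n) < 0.5,
    cancer = FALSE)
  res <- clinicalAssociationScan(cl, status)
  expect_identical(nrow(res), 7L)
  expect_lt(res$p[res$covariate == "age"], 0.05)
  expect_true(all(res$p_adjusted >= res$p - 1e-15))
  expect_true(is.finite(res$ci_lower[res$covariate == "age"]))
  # every patient mutated: tests undefined
  expect_warning(r2 <- clinicalAssociationScan(cl, rep(TRUE, n)),
                 "one mutation status")
  expect_true(all(is.na(r2$p)))
})

test_that("high-AF enrichment test behaves on planted and degenerate input", {
  m <- data.frame(
    patient_id = c("C1", "C2", "N1", "N2", "N3", "N4"),
    fraction = "cfdna",
    allele_fraction = c(0.2, 0.15, 0.02, 0.03, 0.02, 0.04))
  cl <- data.frame(patient_id = c("C1", "C2", "N1", "N2", "N3", "N4"),
                   cancer = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  r <- binEnrichmentTest(m, cl)
  expect_equal(r$p, fisher_enum(matrix(c(2, 0, 0, 4), 2)),
               tolerance = 1e-9)
  # single-patient cohort: degenerate
  expect_warning(
    r1 <- binEnrichmentTest(m[1, ], cl[1, ]), "degenerate")
  expect_true(is.na(r1$p))
})

test_that("fraction concordance partitions mutations and counts patients", {
  m <- data.frame(
    patient_id = c("P1", "P1", "P1", "P2", "P2"),
    gene = c("PTEN", "PTEN", "KRAS", "PTEN", "KRAS"),
    protein_change = c("R130G", "R130G", "G12D", "W111*", "G12D"),
    fraction = c("cell_pellet", "cfdna", "cell_pellet", "cfdna",
                 "cell_pellet"))
  cl <- data.frame(patient_id = c("P1", "P2"), cancer = c(TRUE, FALSE))
  fc <- fractionConcordance(m, cl)
  expect_identical(
    fc$per_mutation$observed_in[fc$per_mutation$protein_change == "R130G"],
    "both")
  expect_identical(fc$summary,
                   c(pellet_only = 2L, cfdna_only = 1L, both = 1L))
  pten <- fc$per_gene[fc$per_gene$gene == "PTEN", ]
  expect_identical(pten$unique_patients, 2L)
  expect_identical(pten$cancer_patients, 1L)
  expect_identical(pten$mut_both, 1L)
})
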