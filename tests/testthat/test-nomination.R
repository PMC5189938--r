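kb <- defaultKnowledgeBase()

test_that("nomination worked examples match the published labels", {
  ex <- data.frame(
    gene = c("KRAS", "PTEN", "TP53", "CTNNB1"),
    protein_change = c("G12D", "W111*", "C176F", "T41T"),
    stringsAsFactors = FALSE)
  nom <- nominate(ex, kb)
  expect_identical(nom$label,
                   c("driver", "driver", "potential_driver", "passenger"))
  # PTEN W111* qualifies through the truncating-TSG rule
  expect_match(nom$evidence[2], "truncating_tsg")
  # TP53 C176F is a functional missense recurrent in other cancers
  expect_identical(nom$subflag[3], "recurrent_other_cancers")
  # hotspot matching is positional: any substitution at KRAS G12
  expect_identical(nominate(data.frame(gene = "KRAS",
                                       protein_change = "G12W"),
                            kb)$label, "driver")
  # silent at a hotspot position is still a passenger
  expect_identical(nominate(data.frame(gene = "KRAS",
                                       protein_change = "G12G"),
                            kb)$label, "passenger")
  expect_error(nominate(data.frame(gene = "EGFR",
                                   protein_change = "L858R"), kb),
               "EGFR")
})

test_that("labels are exclusive, exhaustive, and evidence-backed", {
  sl <- syntheticMutationList()
  nom <- nominate(sl$mutations, sl$kb)
  expect_true(all(nom$label %in% c("driver", "potential_driver",
                                   "passenger")))
  drv <- nom[nom$label == "driver", ]
  expect_true(all(grepl("hotspot|truncating_tsg", drv$evidence)))
  pd <- nom[nom$label == "potential_driver", ]
  expect_true(all(grepl("functional_missense", pd$evidence)))
  expect_true(all(!is.na(pd$subflag)))
  expect_true(all(nom$label[nom$consequence == "silent"] == "passenger"))
})

test_that("raising an impact score never demotes a missense mutation", {
  m <- data.frame(gene = "PIK3CA", protein_change = "A700S",
                  stringsAsFactors = FALSE)
  ann <- function(score) data.frame(
    gene = "PIK3CA", protein_change = "A700S", impact_score = score,
    seen_in_endometrial = FALSE, seen_in_other_cancers = FALSE)
  lab <- vapply(c("neutral", "low", "medium", "high"), function(s)
    nominate(m, augmentKnowledgeBase(kb, ann(s)))$label, character(1))
  expect_identical(unname(lab),
                   c("passenger", "passenger", "potential_driver",
                     "potential_driver"))
  rank <- c(passenger = 1, potential_driver = 2)
  expect_true(all(diff(rank[lab]) >= 0))
})

test_that("potential-driver sub-annotation partitions correctly", {
  # engineered 23 potential drivers split 11 / 2 / 10
  sl <- syntheticMutationList()
  nom <- nominate(sl$mutations, sl$kb)
  counts <- subannotatePotentialDrivers(nom)
  expect_identical(counts,
                   c(recurrent_other_cancers = 11L, endometrial_only = 2L,
                     novel = 10L))
  expect_identical(sum(counts),
                   sum(nom$label == "potential_driver"))
  # kb flag combinations map to the right sub-flag
  both_false <- nominate(
    data.frame(gene = "PIK3CA", protein_change = "A700S"),
    augmentKnowledgeBase(kb, data.frame(
      gene = "PIK3CA", protein_change = "A700S", impact_score = "high",
      seen_in_endometrial = FALSE, seen_in_other_cancers = FALSE)))
  expect_identical(both_false$subflag, "novel")
})

test_that("patient ranking matches a brute-force sort oracle", {
  set.seed(4)
  pats <- sprintf("P%02d", 1:12)
  nom <- do.call(rbind, lapply(pats, function(p) {
    n <- sample(0:6, 1)
    if (n == 0) return(NULL)
    data.frame(patient_id = p, gene = "KRAS", protein_change = "G12D",
               label = sample(c("driver", "potential_driver", "passenger"),
                              n, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  r <- rankPatients(nom)
  # oracle: order by (burden, drivers, id) computed independently
  agg <- lapply(split(nom, nom$patient_id), function(d)
    c(d = sum(d$label == "driver"), p = sum(d$label == "potential_driver")))
  ids <- names(agg)
  burden <- vapply(agg, function(x) x[["d"]] + x[["p"]], 0)
  drivers <- vapply(agg, function(x) x[["d"]], 0)
  oracle <- ids[order(-burden, -drivers, ids)]
  expect_identical(r$patient_id, oracle)
  # a 12-driver patient outranks a 4-driver patient
  top <- rbind(
    data.frame(patient_id = "PT395", gene = "KRAS",
               protein_change = "G12D", label = rep("driver", 12)),
    data.frame(patient_id = "PT485", gene = "KRAS",
               protein_change = "G12D", label = rep("driver", 4)))
  expect_identical(rankPatients(top)$patient_id[1], "PT395")
  # all-zero cohort keeps id order
  zero <- data.frame(patient_id = c("A", "B", "C"), gene = "KRAS",
                     protein_change = "G12G", label = "passenger")
  expect_identical(rankPatients(zero)$patient_id, c("A", "B", "C"))
})

test_that("hotspot comparison table reproduces planted counts", {
  hot <- kbHotspots(kb)
  planted <- hot[rep(seq_len(nrow(hot)), hot$lavage_count), ]
  muts <- data.frame(gene = planted$gene,
                     protein_change = planted$example_change,
                     patient_id = "PT001", stringsAsFactors = FALSE)
  nom <- nominate(muts, kb)
  expect_true(all(nom$label == "driver"))
  cmp <- buildTcgaComparison(nom, kb)
  got <- stats::setNames(cmp$genes$lavage_count, cmp$genes$gene)
  want <- tapply(hot$lavage_count, hot$gene, sum)
  expect_equal(got[names(want)], want[names(want)],
               ignore_attr = TRUE)
  # gene-level counts equal the sum of per-hotspot counts
  hs_sum <- tapply(cmp$hotspots$lavage_count, cmp$hotspots$gene, sum)
  expect_equal(got[names(hs_sum)], hs_sum[names(hs_sum)],
               ignore_attr = TRUE)
  # genes without nominated drivers are omitted
  expect_false("ATM" %in% cmp$genes$gene)
})

test_that("the mutation matrix keeps the most consequential label", {
  nom <- data.frame(
    patient_id = c("P1", "P1", "P1", "P2"),
    gene = c("PTEN", "PTEN", "KRAS", "PTEN"),
    protein_change = "x",
    label = c("passenger", "driver", "potential_driver", "passenger"),
    stringsAsFactors = FALSE)
  m <- mutationMatrix(nom)
  expect_identical(m["P1", "PTEN"], "driver")
  expect_identical(m["P1", "KRAS"], "potential_driver")
  expect_identical(m["P2", "PTEN"], "passenger")
  expect_true(is.na(m["P2", "KRAS"]))
})
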