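AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
BASES <- c("A", "C", "G", "T")
DEFAULT_CALLERS <- c("lofreq", "mutect", "varscan")

#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults reproduce the
#' study conditions: 107 enrolled patients of whom 102 pass QC, 7 cancer
#' diagnoses, 58 of 102 analysable patients carrying somatic mutations,
#' 5,000X somatic coverage with a 200X SNP fingerprint spike-in, somatic
#' allele fractions drawn from a log-normal truncated to (1%, 30.4%] with
#' mean ~3%, an age shift of +7.61 y for driver/potential-driver
#' carriers over a base of 50.35 y, and a 0.75 probability that a cancer
#' patient carries a >10% AF driver (echoing 3 of 4 cancer patients in
#' the high cfDNA stratum).
#'
#' @slot seed Integer RNG seed; identical config + seed is
#'   bit-reproducible.
#' @slot nPatients,cancerPrevalence,qcPassRate,mutatedFraction Cohort
#'   structure.
#' @slot meanDepth,snpDepth Sequencing depths (reads).
#' @slot afMeanlog,afSdlog,afRange Truncated log-normal AF model.
#' @slot ageMeanBase,ageSd,ageShift Age model (years).
#' @slot cancerHighAf Probability a cancer patient carries a >10% AF
#'   driver.
#' @slot classProbs Probabilities of driver / potential-driver /
#'   passenger truth classes per mutation.
#' @slot mutMu,mutSize,mutMax Truncated negative-binomial per-patient
#'   mutation count model.
#' @slot sharedFractionProb Probability a mutation appears in both lavage
#'   fractions.
#' @slot callerDropout Per-caller probability of missing a true variant.
#' @export
setClass("SimulationConfig",
  representation(seed = "integer", nPatients = "integer",
                 cancerPrevalence = "numeric", qcPassRate = "numeric",
                 mutatedFraction = "numeric", meanDepth = "numeric",
                 snpDepth = "numeric", afMeanlog = "numeric",
                 afSdlog = "numeric", afRange = "numeric",
                 ageMeanBase = "numeric", ageSd = "numeric",
                 ageShift = "numeric", cancerHighAf = "numeric",
                 classProbs = "numeric", mutMu = "numeric",
                 mutSize = "numeric", mutMax = "integer",
                 sharedFractionProb = "numeric",
                 callerDropout = "numeric"))

setValidity("SimulationConfig", function(object) {
  props <- c(object@cancerPrevalence, object@qcPassRate,
             object@mutatedFraction, object@cancerHighAf,
             object@sharedFractionProb, object@callerDropout)
  if (any(props < 0 | props > 1)) return("proportions must lie in [0, 1]")
  if (length(object@afRange) != 2 || object@afRange[1] <= 0 ||
      object@afRange[2] > 1 || diff(object@afRange) <= 0)
    return("afRange must be an increasing pair within (0, 1]")
  if (abs(sum(object@classProbs) - 1) > 1e-9)
    return("classProbs must sum to 1")
  TRUE
})

#' Construct a [SimulationConfig-class]
#'
#' @param seed RNG seed.
#' @param nPatients,cancerPrevalence,qcPassRate,mutatedFraction,meanDepth,snpDepth,afMeanlog,afSdlog,afRange,ageMeanBase,ageSd,ageShift,cancerHighAf,classProbs,mutMu,mutSize,mutMax,sharedFractionProb,callerDropout
#'   See [SimulationConfig-class]; all default to the study conditions.
#' @return A `SimulationConfig`.
#' @examples
#' cfg <- simulationConfig(seed = 7, nPatients = 20)
#' @export
simulationConfig <- function(seed = 1L, nPatients = 107L,
                             cancerPrevalence = 7 / 107,
                             qcPassRate = 102 / 107,
                             mutatedFraction = 58 / 102,
                             meanDepth = 5000, snpDepth = 200,
                             afMeanlog = -4.4, afSdlog = 1.0,
                             afRange = c(0.01, 0.304),
                             ageMeanBase = 50.35, ageSd = 12.1,
                             ageShift = 7.61, cancerHighAf = 0.75,
                             classProbs = c(75, 23, 28) / 126,
                             mutMu = 2.0, mutSize = 1.2, mutMax = 20L,
                             sharedFractionProb = 0.6,
                             callerDropout = 0.05) {
  new("SimulationConfig", seed = as.integer(seed),
      nPatients = as.integer(nPatients),
      cancerPrevalence = cancerPrevalence, qcPassRate = qcPassRate,
      mutatedFraction = mutatedFraction, meanDepth = meanDepth,
      snpDepth = snpDepth, afMeanlog = afMeanlog, afSdlog = afSdlog,
      afRange = afRange, ageMeanBase = ageMeanBase, ageSd = ageSd,
      ageShift = ageShift, cancerHighAf = cancerHighAf,
      classProbs = classProbs, mutMu = mutMu, mutSize = mutSize,
      mutMax = as.integer(mutMax), sharedFractionProb = sharedFractionProb,
      callerDropout = callerDropout)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: n =", object@nPatients,
      "seed =", object@seed,
      sprintf("(cancer %.3f, QC %.3f, mutated %.3f)\n",
              object@cancerPrevalence, object@qcPassRate,
              object@mutatedFraction))
})

# Truncated log-normal AF draws (rejection sampling).
draw_af <- function(n, config) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2 * n + 10, config@afMeanlog, config@afSdlog)
    out <- c(out, x[x > config@afRange[1] & x <= config@afRange[2]])
  }
  out[seq_len(n)]
}

# Deterministic synthetic catalogue of non-hotspot missense and silent
# changes per gene, used to draw potential drivers and passengers; the
# functional entries are added to the knowledge base as simulation-time
# impact annotations.
variant_catalogue <- function(kb, nPerGene = 6L) {
  hot <- kbHotspots(kb)
  do.call(rbind, lapply(kbGenes(kb)$symbol, function(g) {
    taken <- hot$aa_start[hot$gene == g]
    pool <- setdiff(seq(150L, 900L, by = 7L), taken)
    mk <- function(offset, n) {
      pos <- pool[seq_len(n) + offset]
      ref <- AA20[(pos %% 19) + 1]
      alt <- AA20[((pos + 3) %% 19) + 1]
      alt[alt == ref] <- AA20[((pos[alt == ref] + 4) %% 19) + 1]
      list(pos = pos, ref = ref, alt = alt)
    }
    fun <- mk(0L, nPerGene)        # predicted-functional missense
    pas <- mk(nPerGene, nPerGene)  # low-impact missense
    sil <- mk(2L * nPerGene, nPerGene)
    data.frame(
      gene = g,
      protein_change = c(paste0(fun$ref, fun$pos, fun$alt),
                         paste0(pas$ref, pas$pos, pas$alt),
                         paste0(sil$ref, sil$pos, sil$ref)),
      kind = rep(c("potential", "passenger_missense", "silent"),
                 each = nPerGene),
      impact_score = rep(c("high", "low", "neutral"), each = nPerGene),
      seen_in_endometrial = c(rep(c(FALSE, TRUE, FALSE), length.out =
                                    nPerGene),
                              rep(FALSE, 2 * nPerGene)),
      seen_in_other_cancers = c(rep(c(TRUE, FALSE, FALSE), length.out =
                                      nPerGene),
                                rep(FALSE, 2 * nPerGene)),
      stringsAsFactors = FALSE)
  }))
}

# Map (gene, protein position) to deterministic synthetic GRCh37
# coordinates inside the gene's amplicon block.
aa_to_genomic <- function(gene, aa, kind, panel) {
  amp <- panelAmplicons(panel)
  amp <- amp[mcols(amp)$gene == gene]
  block_start <- min(start(amp))
  span <- sum(width(amp))
  pos <- block_start + (3L * aa) %% (span - 3L)
  ref1 <- BASES[(aa %% 4) + 1]
  alt1 <- BASES[((aa + 1) %% 4) + 1]
  if (kind %in% c("inframe_del")) {
    # 3-bp in-frame deletion
    list(pos = pos, ref = paste0(ref1, alt1, ref1, ref1), alt = ref1)
  } else if (kind == "frameshift") {
    # 1-bp deletion
    list(pos = pos, ref = paste0(ref1, alt1), alt = ref1)
  } else {
    list(pos = pos, ref = ref1, alt = alt1)
  }
}

#' Precomputed simulation context
#'
#' Bundles the augmented knowledge base, the synthetic variant catalogue
#' and the per-gene amplicon block table so repeated [simulateCohort()]
#' calls (e.g. across seeds) avoid re-reading the bundled files.
#'
#' @param panel A [PanelDefinition-class].
#' @return List with `kb`, `catalogue` and `blocks`.
#' @export
simulationContext <- function(panel = defaultPanel()) {
  kb <- defaultKnowledgeBase()
  cat_tab <- variant_catalogue(kb)
  kb <- augmentKnowledgeBase(
    kb, transform(cat_tab[cat_tab$kind != "silent", ], kind = NULL))
  amp <- panelAmplicons(panel)
  blocks <- do.call(rbind, lapply(split(seq_along(amp),
                                        mcols(amp)$gene), function(ii) {
    data.frame(chrom = as.character(seqnames(amp))[ii[1]],
               block_start = min(start(amp)[ii]),
               span = sum(width(amp)[ii]), stringsAsFactors = FALSE)
  }))
  blocks$gene <- rownames(blocks)
  list(kb = kb, catalogue = cat_tab, blocks = blocks)
}

#' Simulate a synthetic patient cohort
#'
#' Generates the clinical table and per-patient truth mutations with the
#' statistical structure the analysis assumes: mutation burden per gene
#' proportional to the observed per-gene driver counts, truth classes
#' drawn at the observed driver / potential-driver / passenger
#' proportions, allele fractions from the truncated log-normal model,
#' cancer patients guaranteed at least one driver and (with probability
#' `cancerHighAf`) a >10% AF driver, and age assigned as
#' `N(ageMeanBase, ageSd)` plus `ageShift` for realized
#' driver/potential-driver carriers. Menopausal status is a noisy
#' threshold of age (centred near 51 y) so the age and menopause
#' associations co-occur.
#'
#' @param config A [SimulationConfig-class].
#' @param panel Panel used for genomic coordinates.
#' @return List with `clinical` (data.frame), `truth` (one row per
#'   unique mutation, with genomic coordinates, truth class and lavage
#'   fraction assignment) and `kb` (knowledge base augmented with the
#'   generator's impact annotations).
#' @examples
#' sim <- simulateCohort(simulationConfig(seed = 42, nPatients = 30))
#' table(sim$truth$class_truth)
#' @export
simulateCohort <- function(config, panel = defaultPanel(),
                           context = simulationContext(panel)) {
  kb <- context$kb
  cat_tab <- context$catalogue
  hot <- kbHotspots(kb)
  genes <- kbGenes(kb)$symbol
  gene_w <- vapply(genes, function(g)
    max(1, sum(hot$lavage_count[hot$gene == g])), numeric(1))

  with_seed(config@seed, {
    n <- config@nPatients
    ids <- sprintf("PT%03d", seq_len(n))
    cancer <- stats::runif(n) < config@cancerPrevalence
    qc_pass <- stats::runif(n) < config@qcPassRate | cancer
    # cancer patients always carry mutations; the non-cancer carrier rate
    # is conditioned so the marginal mutated fraction among QC-passed
    # patients stays at config@mutatedFraction
    p_cancer_qc <- min(1, config@cancerPrevalence / config@qcPassRate)
    p_nc <- max(0, min(1, (config@mutatedFraction - p_cancer_qc) /
                         max(1e-12, 1 - p_cancer_qc)))
    carrier <- (stats::runif(n) < p_nc | cancer) & qc_pass

    truth <- list()
    for (i in which(carrier)) {
      nmut <- min(config@mutMax,
                  1L + stats::rnbinom(1, size = config@mutSize,
                                      mu = config@mutMu))
      g <- sample(genes, nmut, replace = TRUE, prob = gene_w)
      cls <- sample(c("driver", "potential_driver", "passenger"), nmut,
                    replace = TRUE, prob = config@classProbs)
      if (cancer[i] && !any(cls == "driver")) cls[1] <- "driver"
      rows <- lapply(seq_len(nmut), function(k) {
        gk <- g[k]
        if (cls[k] == "driver") {
          hrows <- hot[hot$gene == gk, , drop = FALSE]
          if (nrow(hrows)) {
            hr <- hrows[sample.int(nrow(hrows), 1,
                                   prob = hrows$lavage_count), ]
            pchg <- hr$example_change
          } else {
            # major-gene TSG without registry entries: truncating driver
            pos <- sample(100:500, 1)
            pchg <- paste0(AA20[(pos %% 19) + 1], pos,
                           sample(c("*", "fs"), 1))
          }
        } else if (cls[k] == "potential_driver") {
          pool <- cat_tab[cat_tab$gene == gk & cat_tab$kind == "potential", ]
          pchg <- pool$protein_change[sample.int(nrow(pool), 1)]
        } else {
          pool <- cat_tab[cat_tab$gene == gk &
                            cat_tab$kind %in% c("passenger_missense",
                                                "silent"), ]
          pchg <- pool$protein_change[sample.int(nrow(pool), 1)]
        }
        data.frame(patient_id = ids[i], gene = gk, protein_change = pchg,
                   class_truth = cls[k], stringsAsFactors = FALSE)
      })
      pm <- do.call(rbind, rows)
      pm <- pm[!duplicated(pm[, c("gene", "protein_change")]), ,
               drop = FALSE]
      pm$af <- draw_af(nrow(pm), config)
      pm$high_af_forced <- FALSE
      if (cancer[i] && stats::runif(1) < config@cancerHighAf) {
        j <- which(pm$class_truth == "driver")[1]
        pm$af[j] <- stats::runif(1, 0.101, config@afRange[2])
        pm$high_af_forced[j] <- TRUE
      }
      u <- stats::runif(nrow(pm))
      pm$observed_in <- ifelse(u < config@sharedFractionProb, "both",
                               ifelse(u < (1 + config@sharedFractionProb) / 2,
                                      "cell_pellet", "cfdna"))
      truth[[length(truth) + 1L]] <- pm
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(patient_id = character(), gene = character(),
                 protein_change = character(), class_truth = character(),
                 af = numeric(), high_af_forced = logical(),
                 observed_in = character())

    # genomic coordinates (vectorised over the gene block table)
    if (nrow(truth)) {
      parsed <- parseProteinChange(truth$protein_change)
      blk <- context$blocks[truth$gene, ]
      aa <- parsed$pos
      gpos <- blk$block_start + (3L * aa) %% (blk$span - 3L)
      ref1 <- BASES[(aa %% 4) + 1]
      alt1 <- BASES[((aa + 1) %% 4) + 1]
      ref <- ifelse(parsed$kind == "inframe_del",
                    paste0(ref1, alt1, ref1, ref1),
                    ifelse(parsed$kind == "frameshift",
                           paste0(ref1, alt1), ref1))
      alt <- ifelse(parsed$kind %in% c("inframe_del", "frameshift"),
                    ref1, alt1)
      truth <- cbind(truth,
                     data.frame(chrom = blk$chrom, pos = gpos, ref = ref,
                                alt = alt, stringsAsFactors = FALSE))
    }

    carrier_dp <- ids %in%
      truth$patient_id[truth$class_truth != "passenger"]
    age <- stats::rnorm(n, config@ageMeanBase, config@ageSd) +
      config@ageShift * carrier_dp
    menopausal <- (age + stats::rnorm(n, 0, 3)) > 51
    clinical <- data.frame(
      patient_id = ids,
      age = round(age, 1),
      race = sample(c("white", "african_american", "asian", "hispanic",
                      "other"), n, replace = TRUE,
                    prob = c(0.66, 0.13, 0.11, 0.05, 0.05)),
      bmi = round(stats::rlnorm(n, log(27), 0.2), 1),
      diabetes = stats::runif(n) < 0.15,
      parity = stats::rpois(n, 1.3),
      smoking = sample(c("never", "former", "current"), n, replace = TRUE,
                       prob = c(0.80, 0.18, 0.02)),
      menopausal = menopausal,
      preop_dx = sample(c("abnormal_bleeding", "uterine_polyp",
                          "thickened_endometrium", "other"), n,
                        replace = TRUE, prob = c(0.47, 0.28, 0.09, 0.16)),
      final_dx = ifelse(cancer, "endometrial carcinoma",
                        sample(c("polyp", "normal endometrium", "fibroid",
                                 "hyperplasia"), n, replace = TRUE,
                               prob = c(0.60, 0.17, 0.13, 0.10))),
      cancer = cancer,
      stage = ifelse(cancer, "IA", NA_character_),
      grade = ifelse(cancer, "G1", NA_character_),
      qc_pass = qc_pass,
      carrier_dp = carrier_dp,
      stringsAsFactors = FALSE)
    list(clinical = clinical, truth = truth, kb = kb)
  })
}

#' Expand truth mutations into a per-fraction call table
#'
#' One call-table row per lavage fraction the mutation was assigned to,
#' with the truth allele fraction (no read-level noise).
#'
#' @param truth Truth table from [simulateCohort()].
#' @param depth Nominal depth recorded on each call.
#' @return Canonical call table.
#' @export
truthToCalls <- function(truth, depth = 5000L) {
  if (nrow(truth) == 0) return(empty_calls())
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    fr <- if (truth$observed_in[i] == "both") LAVAGE_FRACTIONS
    else truth$observed_in[i]
    data.frame(
      patient_id = truth$patient_id[i], fraction = fr,
      chrom = truth$chrom[i], pos = truth$pos[i], ref = truth$ref[i],
      alt = truth$alt[i], gene = truth$gene[i],
      protein_change = truth$protein_change[i], depth = depth,
      alt_reads = as.integer(round(truth$af[i] * depth)),
      allele_fraction = truth$af[i], callers = "truth",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# --- VCF rendering -------------------------------------------------------

write_vcf <- function(records, path, sample = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=lavageMut-simulator",
           paste0("##INFO=<ID=GENE,Number=1,Type=String,",
                  "Description=\"Gene symbol\">"),
           paste0("##INFO=<ID=PCHG,Number=1,Type=String,",
                  "Description=\"Protein change (short HGVS-p)\">"),
           paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                  "Description=\"Genotype\">"),
           paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,",
                  "Description=\"Read depth\">"),
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths\">"),
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  body <- character()
  if (nrow(records)) {
    records <- records[order(records$chrom, records$pos), , drop = FALSE]
    info <- ifelse(is.na(records$gene), ".",
                   paste0("GENE=", records$gene, ";PCHG=",
                          records$protein_change))
    body <- paste(records$chrom, records$pos, ".", records$ref,
                  records$alt, ".", "PASS", info, "GT:DP:AD",
                  paste0(records$gt, ":", records$depth, ":",
                         records$depth - records$alt_reads, ",",
                         records$alt_reads), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Render one patient's trio as per-caller VCFs
#'
#' Writes germline, cell-pellet and cfDNA VCFs for each caller, with
#' read support drawn binomially at Poisson-distributed depth, the SNP
#' fingerprint genotyped consistently across fractions at ~200X, planted
#' germline coding variants present in all fractions, and each true
#' somatic variant dropped independently per caller with probability
#' `callerDropout` (exercising the concordance merge). Identical seed
#' and inputs give byte-identical files.
#'
#' @param patientId Patient identifier.
#' @param truth Truth rows for this patient (from [simulateCohort()]).
#' @param config A [SimulationConfig-class].
#' @param dir Output directory.
#' @param panel Panel providing fingerprint loci and coordinates.
#' @param callers Caller names.
#' @param nGermline Number of planted germline coding variants.
#' @param seed RNG seed for this trio.
#' @return List with `files` (nested `fraction -> caller -> path`),
#'   `snpSupport` (per-fraction fingerprint pileups), `germline` (the
#'   planted germline variants) and `genotypes` (true fingerprint
#'   genotypes).
#' @export
renderTrioVcfs <- function(patientId, truth, config, dir,
                           panel = defaultPanel(),
                           callers = DEFAULT_CALLERS, nGermline = 5L,
                           seed = config@seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- truth[truth$patient_id %in% patientId, , drop = FALSE]
  loci <- panelSnpLoci(panel)
  with_seed(seed, {
    # fingerprint genotypes (HWE at each locus's MAF), shared by fractions
    maf <- mcols(loci)$maf
    gt_code <- vapply(maf, function(q)
      sample(0:2, 1, prob = c((1 - q)^2, 2 * q * (1 - q), q^2)), 0L)
    # planted germline coding variants inside random amplicons
    amp <- panelAmplicons(panel)
    gi <- sample(length(amp), nGermline, replace = TRUE)
    goff <- vapply(width(amp)[gi] - 1L, function(w) sample(w, 1), 0L)
    germ <- data.frame(
      chrom = as.character(seqnames(amp))[gi],
      pos = start(amp)[gi] + goff,
      gene = mcols(amp)$gene[gi], stringsAsFactors = FALSE)
    germ$ref <- BASES[(germ$pos %% 4) + 1]
    germ$alt <- BASES[((germ$pos + 2) %% 4) + 1]
    germ$af <- ifelse(stats::runif(nGermline) < 0.8, 0.5, 1.0)
    germ <- germ[!duplicated(paste(germ$chrom, germ$pos)), , drop = FALSE]
    # never collide with somatic positions
    if (nrow(truth))
      germ <- germ[!(paste(germ$chrom, germ$pos) %in%
                       paste(truth$chrom, truth$pos)), , drop = FALSE]

    render_fraction <- function(fraction) {
      rows <- list()
      # germline variants appear in every fraction
      for (i in seq_len(nrow(germ))) {
        dp <- stats::rpois(1, config@meanDepth)
        ar <- stats::rbinom(1, dp, germ$af[i])
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = germ$chrom[i], pos = germ$pos[i], ref = germ$ref[i],
          alt = germ$alt[i], gene = germ$gene[i],
          protein_change = NA_character_,
          gt = ifelse(germ$af[i] == 1, "1/1", "0/1"), depth = dp,
          alt_reads = ar, somatic = FALSE, stringsAsFactors = FALSE)
      }
      if (fraction != "germline" && nrow(truth)) {
        here <- truth$observed_in == "both" | truth$observed_in == fraction
        for (i in which(here)) {
          dp <- stats::rpois(1, config@meanDepth)
          ar <- stats::rbinom(1, dp, truth$af[i])
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = truth$chrom[i], pos = truth$pos[i],
            ref = truth$ref[i], alt = truth$alt[i],
            gene = truth$gene[i],
            protein_change = truth$protein_change[i], gt = "0/1",
            depth = dp, alt_reads = ar, somatic = TRUE,
            stringsAsFactors = FALSE)
        }
      }
      # fingerprint pileup (all loci), het/hom-alt loci become records
      dp_snp <- stats::rpois(length(loci), config@snpDepth)
      ar_snp <- stats::rbinom(length(loci), dp_snp, gt_code / 2)
      support <- data.frame(
        chrom = as.character(seqnames(loci)), pos = start(loci),
        depth = dp_snp, alt_reads = ar_snp, stringsAsFactors = FALSE)
      snp_rec <- which(gt_code > 0)
      for (i in snp_rec)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = support$chrom[i], pos = support$pos[i],
          ref = mcols(loci)$ref[i], alt = mcols(loci)$alt[i],
          gene = NA_character_, protein_change = NA_character_,
          gt = ifelse(gt_code[i] == 2, "1/1", "0/1"),
          depth = dp_snp[i], alt_reads = ar_snp[i], somatic = FALSE,
          stringsAsFactors = FALSE)
      list(records = do.call(rbind, rows), support = support)
    }

    files <- list(); support <- list()
    for (f in c("germline", "cell_pellet", "cfdna")) {
      rf <- render_fraction(f)
      support[[f]] <- rf$support
      files[[f]] <- list()
      for (cl in callers) {
        rec <- rf$records
        if (!is.null(rec) && nrow(rec)) {
          drop <- rec$somatic & (stats::runif(nrow(rec)) <
                                   config@callerDropout)
          rec <- rec[!drop, , drop = FALSE]
        } else {
          rec <- data.frame()
        }
        path <- file.path(dir, paste0(patientId, "_", f, "_", cl,
                                      ".vcf"))
        write_vcf(rec, path, sample = paste0(patientId, "_", f))
        files[[f]][[cl]] <- path
      }
    }
    list(files = files, snpSupport = support, germline = germ,
         genotypes = stats::setNames(
           c("0/0", "0/1", "1/1")[gt_code + 1L],
           paste(as.character(seqnames(loci)), start(loci), sep = ":")))
  })
}

#' Reference truth set for spiked-control replicates
#'
#' A synthetic stand-in for the known variants of well-characterised
#' reference DNA (a single-donor control and a multiplexed cell-line
#' blend), with fixed expected allele fractions spanning 1%-40%.
#'
#' @param panel Panel providing coordinates.
#' @return `data.frame` with `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `expected_af`.
#' @export
defaultControlTruth <- function(panel = defaultPanel()) {
  genes <- c("PTEN", "PIK3CA", "TP53", "KRAS", "APC", "ATM", "FBXW7",
             "RB1", "CTNNB1", "ARID1A")
  afs <- c(0.40, 0.25, 0.12, 0.10, 0.05, 0.033, 0.02, 0.015, 0.012, 0.01)
  rows <- lapply(seq_along(genes), function(i) {
    gmap <- aa_to_genomic(genes[i], 50L + 5L * i, "missense", panel)
    amp <- panelAmplicons(panel)
    amp1 <- amp[mcols(amp)$gene == genes[i]][1]
    data.frame(chrom = as.character(seqnames(amp1)), pos = gmap$pos,
               ref = gmap$ref, alt = gmap$alt, gene = genes[i],
               expected_af = afs[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate spiked-control replicate call sets
#'
#' Renders control replicates at 12,000-26,000X: in clean mode every
#' truth variant is observed with binomial read noise and nothing else;
#' in stress mode artifactual variants are additionally injected at
#' `artifactRate` per amplicon (Poisson), at low allele fractions.
#'
#' @param truthSet Control truth set (see [defaultControlTruth()]).
#' @param nReplicates Number of replicates.
#' @param config A [SimulationConfig-class] (for the seed).
#' @param mode `"clean"` or `"stress"`.
#' @param artifactRate Expected artifacts per amplicon in stress mode.
#' @param panel Panel for artifact placement.
#' @return List of call tables, one per replicate.
#' @export
simulateControlReplicates <- function(truthSet, nReplicates = 4L, config,
                                      mode = c("clean", "stress"),
                                      artifactRate = 0.01,
                                      panel = defaultPanel()) {
  mode <- match.arg(mode)
  with_seed(config@seed, {
    lapply(seq_len(nReplicates), function(r) {
      depth0 <- stats::runif(1, 12000, 26000)
      dp <- stats::rpois(nrow(truthSet), depth0)
      ar <- stats::rbinom(nrow(truthSet), dp, truthSet$expected_af)
      calls <- data.frame(
        patient_id = paste0("CTRL", r), fraction = "cfdna",
        chrom = truthSet$chrom, pos = truthSet$pos, ref = truthSet$ref,
        alt = truthSet$alt, gene = truthSet$gene,
        protein_change = NA_character_, depth = dp, alt_reads = ar,
        allele_fraction = ar / dp, callers = "lofreq,mutect",
        stringsAsFactors = FALSE)
      if (mode == "stress") {
        amp <- panelAmplicons(panel)
        n_art <- stats::rpois(1, artifactRate * length(amp))
        if (n_art > 0) {
          gi <- sample(length(amp), n_art, replace = TRUE)
          off <- vapply(width(amp)[gi] - 1L, function(w) sample(w, 1), 0L)
          pos <- start(amp)[gi] + off
          dpa <- stats::rpois(n_art, depth0)
          afa <- stats::runif(n_art, 0.01, 0.05)
          art <- data.frame(
            patient_id = paste0("CTRL", r), fraction = "cfdna",
            chrom = as.character(seqnames(amp))[gi], pos = pos,
            ref = BASES[(pos %% 4) + 1],
            alt = BASES[((pos + 3) %% 4) + 1],
            gene = mcols(amp)$gene[gi], protein_change = NA_character_,
            depth = dpa, alt_reads = as.integer(round(afa * dpa)),
            allele_fraction = afa, callers = "lofreq,mutect",
            stringsAsFactors = FALSE)
          art <- art[!(paste(art$chrom, art$pos) %in%
                         paste(calls$chrom, calls$pos)), , drop = FALSE]
          calls <- rbind(calls, art)
        }
      }
      calls
    })
  })
}

#' Simulate orthogonal assay measurements for a validation plan
#'
#' Draws a measured allele fraction for every plan entry from the true
#' AF with multiplicative noise, standing in for the ddPCR/Sanger
#' readout.
#'
#' @param plan Output of [selectValidationSet()].
#' @param cv Coefficient of variation of the assay.
#' @param seed RNG seed.
#' @param missingIdx Optional row indices rendered as not detected.
#' @return Results `data.frame` for [assessConcordance()].
#' @export
simulateValidationResults <- function(plan, cv = 0.05, seed = 1L,
                                      missingIdx = integer()) {
  with_seed(seed, {
    measured <- pmax(0, plan$allele_fraction *
                       (1 + stats::rnorm(nrow(plan), 0, cv)))
    detected <- rep(TRUE, nrow(plan))
    detected[missingIdx] <- FALSE
    measured[missingIdx] <- NA_real_
    data.frame(plan, measured_af = measured,
               ngs_af = plan$allele_fraction, detected = detected,
               stringsAsFactors = FALSE)
  })
}

#' End-to-end recovery report over simulated cohorts
#'
#' For each seed, simulates a cohort, labels its mutations through the
#' nomination rules, and measures: the fraction of truth classes
#' recovered, the estimated age shift between driver/potential-driver
#' carriers and the rest (with its one-tailed Mann-Whitney p), and the
#' high-AF cancer enrichment p. Optionally, the first few carrier trios
#' are rendered to per-caller VCFs and pushed through the full ingestion
#' path, verifying identity checks and somatic recovery from raw files.
#'
#' @param config Base [SimulationConfig-class]; each seed replaces
#'   `config@seed`.
#' @param seeds Integer vector of seeds.
#' @param renderVcfs Run the VCF rendering + ingestion path.
#' @param nRenderPatients Carrier trios to render per seed.
#' @param dir Scratch directory for rendered VCFs.
#' @return `data.frame`, one row per seed.
#' @export
endToEndRecovery <- function(config, seeds, renderVcfs = FALSE,
                             nRenderPatients = 3L, dir = tempfile()) {
  panel <- defaultPanel()
  context <- simulationContext(panel)
  rows <- lapply(seeds, function(s) {
    cfg <- config; cfg@seed <- as.integer(s)
    sim <- simulateCohort(cfg, panel, context)
    truth <- sim$truth
    nom <- nominate(truth, sim$kb)
    recovery <- if (nrow(truth)) mean(nom$label == truth$class_truth)
    else NA_real_
    cl <- sim$clinical[sim$clinical$qc_pass, , drop = FALSE]
    carrier <- cl$patient_id %in%
      nom$patient_id[nom$label %in% c("driver", "potential_driver")]
    shift <- mean(cl$age[carrier]) - mean(cl$age[!carrier])
    age_p <- mannWhitneyOneTailed(cl$age[carrier], cl$age[!carrier])$p
    calls <- truthToCalls(truth)
    enr <- suppressWarnings(
      binEnrichmentTest(calls, sim$clinical, fraction = "cfdna"))
    out <- data.frame(seed = s, n_mutations = nrow(truth),
                      label_recovery = recovery, age_shift = shift,
                      age_p = age_p, enrichment_p = enr$p)
    if (renderVcfs) {
      carriers <- unique(truth$patient_id)
      take <- utils::head(carriers, nRenderPatients)
      rec <- vapply(take, function(p) {
        rt <- renderTrioVcfs(p, truth, cfg, file.path(dir, p),
                             panel = panel, seed = s + match(p, take))
        ing <- ingestTrio(rt$files, p, panel)
        som <- do.call(rbind, ing$somatic)
        gts <- lapply(rt$snpSupport, genotypeSnpLoci, panel = panel)
        idr <- trioConcordance(gts, p)
        tkeys <- variant_key(truth$chrom[truth$patient_id == p],
                             truth$pos[truth$patient_id == p],
                             truth$ref[truth$patient_id == p],
                             truth$alt[truth$patient_id == p])
        skeys <- unique(variant_key(som$chrom, som$pos, som$ref,
                                    som$alt))
        c(mean(tkeys %in% skeys),
          as.numeric(identityVerdict(idr) == "match"))
      }, numeric(2))
      out$vcf_truth_recovery <- mean(rec[1, ])
      out$identity_pass_rate <- mean(rec[2, ])
    }
    out
  })
  do.call(rbind, rows)
}
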