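---
title: "Somatic mutation analysis of uterine lavage trios: models and methods"
author: "lavageMut maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic mutation analysis of uterine lavage trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lavageMut)
```

## The problem

Endometrial cancer sheds cells and cell-free DNA (cfDNA) into the uterine
cavity, where a saline lavage collected at hysteroscopy can capture them.
Ultra-deep targeted sequencing of matched trios — germline PBMC DNA, the
lavage cell pellet, and lavage cfDNA — can detect somatic mutations at
allele fractions down to 1%, both in women with histopathologically
confirmed cancer and, strikingly, in many women without any cancer
diagnosis. `lavageMut` implements the full downstream analysis for such a
design: somatic filtering of per-caller VCFs, SNP-fingerprint identity
checks, protein-change parsing, driver / potential-driver / passenger
nomination, cohort statistics, orthogonal-validation planning, and a
synthetic cohort generator that makes every stage testable without any
sequencing data.

## Somatic filtering contract

The trio design supports a simple, explicit filtering chain:

1. **Concordance merge.** Each library is called by several somatic
   callers (e.g. MuTect, Varscan, LoFreq). Variants keyed by
   (chrom, pos, ref, alt) are retained only when at least two callers
   agree (`minCallers = 2`, configurable); a variant reported by a single
   caller is treated as not called. Depth and allelic depth are taken
   from the caller reporting the greatest depth — a deterministic,
   conservative choice. The merge happens before thresholding, so a
   variant's reportability is judged on its best-supported measurement.
2. **Panel targeting.** Panel regions are BED intervals (0-based,
   half-open); a 1-based variant position *p* lies in region (c, s, e)
   iff s < p ≤ e. Calls on chromosomes the panel does not cover are
   logged and dropped, never an error.
3. **Matched-normal subtraction.** Any lavage call whose key appears in
   the germline fraction is removed, with *no* allele-fraction gate on
   the normal: a 5% germline variant still counts as germline. There is
   no tumor-only mode; a missing germline fraction is a hard error.
   Fingerprint SNP loci are identity markers, not somatic targets, and
   are excluded from somatic output entirely.
4. **Reporting threshold.** Calls at allele fraction ≥ 1% are reported;
   the bound is inclusive because variants at exactly 1.0% are
   orthogonally validatable at 5,000X.

Panel filtering and thresholding are pure subset filters and therefore
commute; germline subtraction is idempotent. Both properties are enforced
as tests.

## Identity checking

A spike-in of high-minor-allele-fraction SNPs (~200X) rides along with
the somatic panel (~5,000X). Genotypes are called by allele-fraction
cuts — below 0.10 homozygous reference, 0.10–0.90 heterozygous, above
0.90 homozygous alternate — with loci under 50 reads treated as missing.
Pairwise concordance over jointly callable loci must reach 0.90 on every
pair of fractions, with at least 10 callable loci per pair; otherwise the
verdict is `mismatch` (adequately powered, discordant) or `insufficient`.
The cuts, depth gate and thresholds are not dictated by the study design
and are all configurable; the defaults suit 200X fingerprint depth, where
binomial noise around a heterozygous 0.5 essentially never crosses the
0.10/0.90 cuts. Two unrelated individuals agree at a rate of roughly
`sum(P(g)^2)` per locus (≈ 0.4 at MAF 0.3–0.5), far below the 0.90
threshold, so a single swapped sample is reliably flagged.

## Protein-change grammar and consequences

Mutations are named in short HGVS-p style. The accepted grammar covers
`X123Y` (missense, silent when X = Y), `X123*` (stop), `X123fs`
(frameshift), `X123del` and `X123delX` (single-residue in-frame
deletion, the latter spelling restating the deleted residue),
underscore ranges `X123_Y456del` / `X123_Y456fs`, and compound
two-residue frameshift anchors such as `K780Q781fs`. Anything else —
insertions included — parses as `other`, is preserved verbatim, and is
excluded from roll-up counts. Parsing round-trips: re-serialising any
grammar-conformant string reproduces it exactly.

Fine-grained classes roll up so stop, frameshift and in-frame changes
form a "nonsense" bucket, while *truncating* (the nomination predicate)
covers stop and frameshift only — an in-frame deletion removes residues
but need not abolish the protein. Silence is detected at the residue
level; nucleotide-level silent detection would need transcripts, which
the package deliberately does not bundle.

## Driver nomination

The knowledge base holds three tables: gene roles (oncogene / tumor
suppressor) with per-gene TCGA statistics; a hotspot registry with
per-hotspot endometrial recurrence counts; and per-variant
functional-impact annotations on the Mutation-Assessor scale
(neutral < low < medium < high). The bundled registry reproduces the
published per-hotspot table for the 12-gene panel, including the novel
entries (flagged `novel`, recurrence 0).

The nomination rules, in order of precedence:

* **Silent → passenger**, always, even at a hotspot position.
* **Driver** if the protein position matches a registry hotspot of a
  major endometrial driver gene (position-level matching, so any
  substitution at KRAS G12 counts), or if the change truncates a
  major-gene tumor suppressor.
* **Potential driver** if a missense change in a major gene carries a
  predicted-functional impact score (≥ medium, the conventional
  Mutation Assessor cutoff; configurable). Each potential driver gets
  exactly one provenance sub-flag: recurrent in other cancers,
  endometrial-only, or novel.
* **Passenger** otherwise.

All 12 panel genes default to `major_ec_driver = TRUE`, since the panel
was assembled from the highest-frequency endometrial TCGA genes; the
flag is configurable per gene. Upgrading an impact score can only move a
missense mutation toward potential driver, never demote it — a
monotonicity property under test. Patients are ranked by the sum of
driver and potential-driver mutations, ties broken by driver count and
then patient id. The per-gene comparison table reports, for every gene
with nominated drivers, its per-hotspot (lavage / TCGA) counts with
novel entries flagged; the gene total is by construction the sum of its
per-hotspot counts.

One genuinely open corner: the published gene table prints a TP53
hotspot total of 2 while also listing two novel truncating TP53 entries.
The package resolves this uniformly — every per-gene total is the sum of
that gene's per-hotspot rows, novel rows included — which reproduces the
printed totals for KRAS, PIK3CA and PTEN and yields 4 for TP53.

## Cohort statistics

Allele fractions are binned into (0, 5%], (5%, 10%], (10%, 100%] —
matching the "≤5.00% / 5.01–10.00% / ≥10.01%" strata, with 5% in the
first bin and 10% in the second. Pellet/cfDNA concordance is the Pearson
correlation of per-gene totals, displayed as r² to two decimals (full
precision retained). Per-stratum cancer percentages are integer-rounded;
a patient belongs to every stratum in which they carry a mutation.

The statistical wrappers delegate to the standard implementations —
`fisher.test`, `wilcox.test` (one-tailed, exact for tie-free samples of
at most 20 per group, normal approximation with tie correction
otherwise), `p.adjust(method = "BH")` — and the test-suite checks them
against fully independent oracles: complete hypergeometric enumeration,
exact permutation enumeration, and the hand-applied step-up formula. The
one-sided 95% location bound uses the bootstrap percentile method on the
difference of means (10,000 seeded resamples); the source study does not
name its interval method, and the bootstrap makes the fewest
distributional assumptions.

The high-AF enrichment test contrasts patients carrying a >10% AF
mutation in a fraction against patients whose mutations there are all
lower, as a 2×2 Fisher table against cancer status. The published
p-values for this contrast cannot be reconstructed from the printed
patient counts (the exact table construction is under-specified), so the
construction is a documented package choice and no published p-value is
asserted.

Null calibration of the exact tests deserves a note: on coarse discrete
supports both Fisher's exact test and the exact Mann-Whitney are
conservative by construction, so size checks at cohort-scale margins
would sit well below the nominal 5%. The calibration tests therefore use
large-sample nulls (groups of 50 for Mann-Whitney, binomial margins of
2,000 for Fisher) where the attainable size approaches nominal; this
verifies the wrappers, not the discreteness of small tables.

The clinical association scan codes menopausal status 0/1 and smoking
ordinally (never < former < current), tests them and the continuous
covariates by the one-tailed Mann-Whitney (mutated group larger), tests
race by Fisher's exact test on the full contingency table, and adjusts
the seven-covariate family by Benjamini-Hochberg; per-gene scans form
their own families.

## The synthetic cohort generator

The generator's defaults are the study conditions: 107 enrolled
patients, QC pass rate 102/107, cancer prevalence 7/107, mutated
fraction 58/102 among QC-passed (cancer patients always carry mutations;
the non-cancer rate is conditioned so the marginal stays at 58/102),
5,000X somatic and 200X fingerprint depth, and per-gene mutation weights
proportional to the published per-gene driver counts (ATM and APC, which
have no registry entries, get weight 1 so passengers arise there).

**Allele fractions** are log-normal truncated to (1%, 30.4%] with
meanlog −4.4 and sdlog 1.0, chosen once so the truncated mean is 0.0304,
matching the reported 3.0% average. A log-normal cannot simultaneously
reproduce that mean and the reported share of >10% observations; the
mean wins, and the high tail is instead supplied by cancer biology: each
cancer patient receives, with probability 0.75 (echoing 3 of 4 cancer
patients in the high cfDNA stratum), one driver at an AF drawn uniformly
from (10.1%, 30.4%].

**Ages** are normal with base mean 50.35 y and a +7.61 y shift for
realized driver/potential-driver carriers, so the planted shift is
exactly the quantity the association scan estimates. The standard
deviation, 12.1 y, is derived from the published age histogram: the
five 10-year bins give a marginal variance of ≈169 y², Sheppard's
correction for 10-y bins removes 100/12 ≈ 8.3 y², and subtracting the
between-group component p(1−p)·7.61² ≈ 14.5 y² leaves a within-group SD
of ≈12.1 y. Menopausal status is a noisy threshold of age centred at
51 y (SD 3 y of noise), so the age and menopause associations co-occur,
as observed.

**Mutation counts** per carrier follow a truncated negative binomial
(1 + NB(size 1.2, mean 2), capped at 20) — the study reports only the
extremes (0 to 20), so the distribution is a stand-in. Truth classes are
drawn at the observed 75/23/28 proportions; drivers land on registry
hotspots weighted by their observed multiplicities, potential drivers
and passengers come from a deterministic synthetic catalogue of
non-hotspot changes whose impact annotations are added to the knowledge
base at simulation time. Each mutation appears in both lavage fractions
with probability 0.6, else in one of them.

**Rendering** writes per-caller VCFs with depth ~ Poisson(5,000), alt
reads ~ Binomial(depth, AF), fingerprint genotypes consistent across the
trio, planted germline variants in all three fractions, and independent
per-caller dropout (probability 0.05) to exercise the concordance merge.
Genomic coordinates are a synthetic deterministic mapping of protein
positions into the bundled panel's amplicon blocks (real GRCh37 gene
loci, synthetic amplicon tiling — the study's amplicon table is not
redistributed). Identical config and seed give byte-identical files.

What the generator does *not* emulate: sequencing error processes and
strand artifacts, caller-specific sensitivity profiles, subclonal
structure, contamination, or linkage between mutations. Green tests
therefore demonstrate that the analysis correctly recovers the
structures the generator plants — not that it would be robust to every
failure mode of real amplicon sequencing.

## Problem sizes and numerical choices

The packaged tests run the cohort generator at its default size (107
patients) across 200 seeds for parameter recovery, render and re-ingest
a small number of full trios (the VCF path is exercised end-to-end, at a
few patients per seed), enumerate all 2×2 tables with margins ≤ 12
against the hypergeometric oracle, and use 1,000-replicate null
simulations for size checks — sizes chosen to make the checks sharp
while keeping the suite quick on a laptop. Percentages are rounded to
integers and r² to two decimals only at the reporting surface; all
internal computation keeps full precision. Bootstrap and sampling
functions take explicit seeds and restore the caller's RNG state.

## Known limitations

* Hotspot matching is positional; a registry built from coarser or
  finer hotspot definitions would shift driver/potential-driver
  boundaries.
* The bundled knowledge base abstracts TCGA/COSMIC/Mutation Assessor
  content into small tables; pan-cancer recurrence defaults to the
  endometrial counts where no separate source is bundled, and the
  functional-impact annotations outside the curated entries are
  synthetic simulation aids, not curated biology.
* The identity module checks concordance only; it does not estimate
  contamination fractions or kinship.
* No multivariable modelling: associations are univariate by design,
  matching the source analysis.
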