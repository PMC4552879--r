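---
title: "Methods: somatic calling, tumor fraction and sample trees from cfDNA exomes"
author: "cfexome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic calling, tumor fraction and sample trees from cfDNA exomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfexome)
```

# The problem

Tumors shed DNA fragments into blood plasma. In a cancer patient this
cell-free DNA (cfDNA) is a mixture: mostly DNA from normal cells, plus a
tumor-derived fraction (ctDNA) that carries the tumor's somatic mutations.
Whole-exome sequencing of cfDNA, tumor tissue and a matched germline sample
(buffy coat) lets one (i) call somatic mutations in each compartment,
(ii) estimate how much of the cfDNA is tumor-derived, (iii) ask whether the
plasma mirrors the primary tumor or a metastasis, and (iv) follow mutation
levels across serial blood draws during treatment. `cfexome` implements
this analysis downstream of a paired somatic caller: its inputs are
per-site, per-sample read counts (total depth, alt-supporting reads, and
the alt reads split by sequencing strand), not alignments.

# The somatic filter cascade

Candidate variants become somatic calls in a sample when all of the
following hold (all comparisons inclusive, so a value exactly at a
threshold passes):

* **germline_db** — the site is not a known germline polymorphism (dbSNP),
  unless it is also a known somatic hotspot (COSMIC), which rescues it.
  Membership is supplied as per-variant booleans keyed on exact
  (chrom, pos, ref, alt); no live database queries.
* **depth_case** — at least 30 reads cover the site in the sample being
  classified; **depth_normal** — at least 10 in the matched normal.
* **alt_support** — at least 2 reads carry the variant allele.
* **vaf** — the variant allele fraction, always computed as
  `alt_count / depth` against total depth, is at least 10% for tissue
  samples and at least 1.5% for plasma. The two thresholds reflect sample
  character: tissue biopsies are relatively pure, while ctDNA is diluted
  by normal cfDNA.

Plasma calls face two additional artifact filters:

* **normal_contamination** — the matched normal may carry at most 1
  variant-supporting read (trace tumor DNA circulates through blood, but
  more support suggests a germline or artifactual site);
* **strand** — variant reads must appear on both sequencing strands
  (at least one forward and one reverse read); single-strand support is a
  classic signature of sequencing artifacts.

Design choices worth stating: the case-depth rule applies to the sample
being classified, not jointly to all case samples; the two cfDNA-specific
rules apply only to plasma-role samples; rule evaluation never
short-circuits, so the audit table lists *every* failing rule per
(variant, sample); and since all rules are conjunctive, their order only
affects audit presentation, fixed here as germline_db, depth_case,
depth_normal, alt_support, vaf, normal_contamination, strand.

# Tumor fraction from mean clonal VAF

For clonal, heterozygous mutations in a diploid genome, each tumor-derived
fragment carries the variant on one of two alleles, so a tumor fraction
$\theta$ yields an expected VAF of $\theta/2$, and

$$\hat\theta = \min(2 \cdot \overline{\mathrm{VAF}},\ 1).$$

The estimator is deliberately naive: copy-number alterations, loss of
heterozygosity and subclonality all violate it, and dedicated dosage-aware
tools exist for those settings. Averaging is done over the mutations
*called in the plasma sample* (`mean_vaf()` over the plasma call set).
Worked through: a mean VAF of 3.7% over 47 clonal mutations gives
`estimate_tumor_fraction(0.037)` = `r estimate_tumor_fraction(0.037)`,
i.e. 7.4% of the cfDNA is tumor-derived; a mean VAF of 14% gives
`r estimate_tumor_fraction(0.14)`. Percentages are reported rounded half
away from zero (`percent()`), one decimal for fractions, whole numbers for
rates.

# Concordance, correlation, longitudinal tracking

`concordance()` partitions a reference sample's calls against a query
sample's calls (`shared`, `reference_only`, `query_only`) and additionally
reports the query-unique variants that *do* have at least one supporting
read in the reference but fall below the reference's VAF cutoff — the
"present but uncallable" category that typically explains a large share of
apparent plasma-only mutations. `vaf_correlation()` is a plain Pearson
correlation of paired VAFs (at least 3 points, non-degenerate), matching
the scatter-plot usage this mirrors; note that a correlation computed only
over mutations shared by both samples can be noise-dominated (all true
VAFs equal), so the demo pipeline correlates over the union of all
samples' calls. `longitudinal_compare()` reports, for a tracked mutation
set across two plasma draws, paired VAFs, the mean VAF per timepoint over
sites with detectable mutant reads, and the count of undetected sites —
the latter kept separate because averaging in structural zeros conflates
assay sensitivity with biology. `validation_rate()` excludes assays that
produced no sequence from its denominator.

# The maximum-parsimony sample tree

`build_mutation_matrix()` turns per-sample call sets into a binary
character matrix with the normal as an all-absent outgroup (optionally
restricted to nonsynonymous mutations, so branch lengths count
protein-changing events). `best_tree()` scores *every* unrooted binary
topology — 1, 3, 15, 105, … trees for 3, 4, 5, 6 … samples; cohorts here
have 3–5 samples, and beyond 8 the function refuses and points to
dedicated phylogenetics software. Per-character minimum changes come from
Fitch's two-state algorithm (bottom-up intersection/union with a virtual
root on the normal's pendant edge). Branch lengths are integer mutation
counts assigned by the standard Fitch backtrace with one extra convention:
at ties the ancestral (absent) state is preferred, which pushes mutation
gains toward the leaves. This is the natural convention for somatic data —
mutations arise on a normal background and losses are not modelled — but
it *is* a convention: when characters conflict, other minimum-length
assignments exist. Ties between equally parsimonious topologies are broken
lexicographically on the canonical newick string, purely for
reproducibility. Newick output uses integer lengths and canonical child
ordering, so it is invariant to input sample order.

# Detection power at low allele fraction

For a variant at true plasma VAF $f$ sequenced to depth $D$ with per-read
error rate $e$ toward the alt allele, alt reads are
$K \sim \mathrm{Binomial}(D, p)$ with $p = f + (1-f)e$ (error reads are
indistinguishable from true support and count toward detection; the null
case is evaluated at $f = 0$). The call threshold is
$k_{\min} = \max(\text{min\_alt\_reads},\ \lceil \text{min\_vaf} \cdot D \rceil)$,
with the ceiling kept inclusive at exact integer boundaries. Under the
strand rule, each alt read lands on a strand by a fair coin, so $k$ alt
reads survive with probability $1 - 2 \cdot (1/2)^k$; real strand
composition depends on library geometry and is out of scope. The power

$$P(\text{detect}) = \sum_{k = k_{\min}}^{D} \binom{D}{k} p^k (1-p)^{D-k}
\left(1 - 2 \cdot 2^{-k}\right)$$

is evaluated in closed form via two binomial tails (the $2^{-k}$ term is a
tilted binomial), so `min_depth_for_power()` can search by doubling plus
bisection cheaply. Power is monotone in $f$ everywhere, and monotone in
$D$ when $f$ exceeds the VAF cutoff; *below* the cutoff, deeper sequencing
raises $k_{\min}$ faster than the signal and power decays — the search
warns when it crosses such a regime. `detection_probability_mc()` is the
independent simulation cross-check: it draws reads and pushes them through
the same rule engine `classify_variant()` uses, with a clean matched
normal.

# The cohort simulator

`simulate_cohort()` generates read counts with known truth so that every
stage is testable without controlled-access data. Its model: mutations
belong to a trunk clone (all tumor samples), a primary-private or a
metastasis-private clone; tissue samples observe their clone at the tissue
tumor purity; plasma observes a clone mixture diluted to the plasma tumor
fraction; all sites are diploid heterozygous, so true VAF is half the
carrying tumor content. Per (site, sample): depth is negative binomial
(mean, dispersion) — real exome depths are strongly overdispersed, e.g.
a plasma sample averaging ~561x ranged roughly 181–1,197x across sites,
which dispersion size 8 reproduces; alt count is binomial at
`true_vaf + (1 - true_vaf) * error_rate`; strands split by a fair
binomial; the matched normal draws trace alt reads at its own rate.
Null (non-mutant) sites are included so the cascade's specificity is
measurable.

Two presets encode the study conditions:

* **patient1** (sarcoma-like): 48 trunk mutations + 1 primary-private,
  plasma = primary clone at tumor fraction 0.074, depths ~524x plasma,
  ~118x tumor, ~226x normal.
* **patient2** (metastatic breast-cancer-like): 30 trunk,
  9 primary-private (first one labelled as a PIK3CA-like hotspot: clonal
  in the primary, absent from metastasis and plasma), 9 metastasis-private
  (first one an ESR1-like endocrine-resistance marker, present in plasma),
  plasma = metastasis clone at tumor fraction 0.28, plasma ~309x.

Defaults chosen once, as plausible study conditions: tissue purity 0.7
(FFPE archival blocks), post-filter error rate $10^{-3}$ per read, normal
trace-contamination rate $2 \times 10^{-4}$, 200 null sites. The clone
counts for patient2 (30 + 9 + 9 = 48 total; 30 + 9 = 39 expected
plasma-visible) follow the reported totals of 48 tissue mutations and 38
plasma calls. What the simulator does *not* emulate: copy number and LOH,
subclonal structure within a clone, site-specific error profiles, FFPE
damage artifacts, germline contamination of tissue — so passing tests
demonstrate internal consistency of the methods under the stated
generative model, not performance on real cfDNA.

`simulate_treatment_response()` appends a second plasma draw at a new
(typically far lower) tumor fraction with unchanged mutation truth,
modelling response monitoring; a during-treatment fraction above the
pre-treatment one is legal (progression) and only warns.

# Numerical and degenerate-input conventions

* VAF at a zero-depth site is defined as 0 (the depth rules fail such
  sites anyway).
* `ceiling(min_vaf * depth)` is guarded with a $10^{-9}$ fuzz so an exact
  integer product is not pushed up by floating-point representation.
* Empty call sets, zero-variance VAF vectors, and fewer than 3 paired
  points are errors, not NA results.
* Simulation and Monte-Carlo functions take explicit seeds, save and
  restore the caller's RNG state, and are bit-reproducible given the seed.
* Problem sizes used in the shipped tests: filter-oracle equivalence on
  100 random cohorts of 20–200 variants; power cross-validation on a
  5 x 5 (depth x VAF) grid at $10^5$ replicates per cell; Fitch
  brute-force enumeration on 50 random 4–6-taxon, 5–25-character
  matrices; parameter recovery over 20 simulated patient1 cohorts.

# A known caption discrepancy

The source figure captions and the running text disagree slightly on the
sarcoma patient's headline numbers (46/47 vs 47/48 concordant mutations;
mean VAF 3.8% vs 3.7%; tumor fraction 7.5% vs 7.4%). The running-text
values (47 of 48, 3.7%, 7.4%) are used as canonical throughout; the
discrepancy is documented rather than resolved (note 2 x 3.8 = 7.6, not
7.5, so the caption is internally inconsistent too).

# Worked demonstration

```{r demo}
report <- run_demo("patient2", seed = 7)
report
```

The report echoes every threshold used, the per-sample call counts, the
tumor-fraction estimate against the generating truth, tissue/plasma
concordance (with the subthreshold-rescue category), VAF correlations over
the union of calls, the parsimony tree with mutation-count branch lengths,
analytic detection power at the plasma depth, and the longitudinal
comparison for the treatment-response draw.

# Limitations

Single-nucleotide variants only (no indels or structural variation in the
container's semantics, though nothing forbids them as keys); no
copy-number-aware tumor fraction; no subclonal deconvolution or
VAF-weighted trees; no UMI/duplex error modelling; exhaustive tree search
only, by design, for small cohorts.
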