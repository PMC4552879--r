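# cfexome

Somatic mutation analysis for whole-exome sequencing of circulating
cell-free DNA (cfDNA).

## What it is for

Whole-exome sequencing of blood plasma gives a "liquid biopsy" of a cancer
patient's tumor genome: cfDNA is a mixture of DNA from normal cells and a
tumor-derived fraction (ctDNA) carrying the tumor's somatic mutations.
`cfexome` is for analysts working downstream of a paired somatic caller
(per-site read counts for tumor tissue, plasma and a matched normal, from
a tabular format or VCF). It provides:

* the **matched-normal somatic filter cascade** — dbSNP exclusion with
  COSMIC rescue; depth ≥ 30x (case) / ≥ 10x (normal); VAF ≥ 10% for
  tissue, ≥ 1.5% for plasma; ≥ 2 alt reads; and for plasma additionally
  ≤ 1 alt read in the normal and alt reads on both strands — with a full
  per-rule audit table;
* **tumor-fraction estimation** from mean clonal VAF under the
  diploid-heterozygous model, `TF = min(2 · mean VAF, 1)`;
* **concordance** between samples (shared / reference-only / query-only,
  plus query-unique mutations present-but-subthreshold in the reference),
  Pearson **VAF correlation**, **longitudinal comparison** of serial
  plasma draws, validation-rate and plasma-yield accounting;
* a **maximum-parsimony sample tree** (exhaustive search, Fitch counts,
  integer mutation-count branch lengths, newick output rooted at the
  normal);
* an analytic + Monte-Carlo **detection-power model** for a variant at
  true VAF *f* and depth *D* under the plasma rules, and the minimum
  depth reaching a target power;
* a **cohort simulator** with known clonal truth (trunk /
  primary-private / metastasis-private mutations, plasma as a clone
  mixture diluted to a set tumor fraction, overdispersed depths, strand
  splits, error and null sites), with presets emulating a sarcoma-like
  and a metastatic breast-cancer-like patient.

See `vignettes/cfdna-exome-methods.Rmd` for the models, assumptions and
numerical conventions.

## Worked example

```r
library(cfexome)
report <- run_demo("patient1", seed = 7)
report
```

```
ctDNA pipeline report — preset patient1, seed 7
  sites simulated: 249; calls: primary=49, plasma=49
  plasma mean VAF 0.0378 -> tumor fraction 0.0756 (truth 0.0740)
  primary vs plasma: shared 49, primary-only 0, plasma-only 0 (subthreshold 0)
  VAF correlation with plasma: primary=-0.020
  parsimony tree (40 mutations): (normal:0,(plasma:0,primary:0):40);
  detection power at plasma depth: 0.9992
  thresholds: case depth>=30, normal depth>=10, VAF>=0.100 (tissue) / 0.015 (plasma), alt reads>=2
```

Reading it: 249 simulated sites (49 true mutations + 200 null sites); the
cascade calls all 49 mutations in both primary and plasma and no null
site; the plasma mean VAF of 0.0378 doubles to a tumor-fraction estimate
of 7.6% against a generating truth of 7.4%; every primary call is
recovered in plasma; the correlation between plasma and primary VAFs is
near zero because all mutations share one true VAF (dilution, not
biology, sets plasma VAF); the nonsynonymous mutation tree places all 40
protein-changing mutations on the trunk; and a mutation at VAF 3.7%
sequenced at 524x is detected with probability 0.999 under the plasma
rules. Single steps are available as plain functions:

```r
tab   <- read_variant_table("cohort.tsv")          # or read_vcf(...)
calls <- apply_filters(tab, filter_config())
estimate_tumor_fraction(mean_vaf(tab, calls$calls$plasma, "plasma"))
concordance(tab, calls$calls$primary, "primary", "plasma")
best_tree(build_mutation_matrix(calls$calls, tab, nonsynonymous_only = TRUE))
detection_probability(561, 0.037)                  # 0.9989
min_depth_for_power(0.037, 0.95)                   # 226
```

A thin command-line front-end wraps the same functions
(`inst/cli/ctdna.R`; subcommands `simulate`, `filter`, `metrics`, `tree`,
`power`, `demo`):

```sh
Rscript inst/cli/ctdna.R demo --preset patient2 --seed 7
```

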