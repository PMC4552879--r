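Package: cfexome
Title: Somatic Mutation Analysis for Cell-Free DNA Whole-Exome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tumor-informed analysis of whole-exome sequencing of
    circulating cell-free DNA (cfDNA) alongside tumor tissue and a matched
    normal. Implements the matched-normal somatic filter cascade (germline
    database exclusion with COSMIC rescue, depth, variant allele fraction,
    alt-read support, normal contamination and strand-balance rules),
    tumor-fraction estimation from mean clonal variant allele fraction,
    cross-sample mutation concordance and correlation, longitudinal tracking
    of circulating tumor DNA during treatment, maximum-parsimony sample trees
    with mutation-count branch lengths, an analytic and Monte-Carlo model of
    detection sensitivity at low allele fraction, and a read-count simulator
    for multi-sample cohorts with known clonal truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
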