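# Tabular and VCF ingestion of per-site read counts.

test_that("tabular round trip is the identity and VAF is derived, not stored", {
  tab <- make_table(list(
    nrm = ob("normal", c(50L, 60L), c(0L, 1L)),
    tum = ob("tumor", c(100L, 80L), c(15L, 20L))),
    in_cosmic = c(TRUE, FALSE), genes = c("KRAS", "TP53"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(tab, path)
  back <- read_variant_table(path)
  expect_true(variant_tables_equal(tab, back))
  expect_equal(unname(vaf(back, "tum")), c(0.15, 0.25))

  # empty table -> header-only file, still round trips
  empty <- subset_variants(tab, integer(0))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(empty, path2)
  expect_equal(length(readLines(path2)), 1L)
  expect_equal(n_variants(read_variant_table(path2)), 0L)
})

test_that("count invariants are enforced with line numbers on read", {
  expect_error(
    make_table(list(nrm = ob("normal", 50L, 0L),
                    tum = ob("tumor", 10L, 15L, 8L, 7L))),
    "alt_count > depth")
  expect_error(
    make_table(list(nrm = ob("normal", 50L, 0L),
                    tum = ob("tumor", 100L, 15L, 10L, 10L))),
    "alt_fwd \\+ alt_rev")

  tab <- make_table(list(nrm = ob("normal", c(50L, 50L), c(0L, 0L)),
                         tum = ob("tumor", c(100L, 90L), c(15L, 9L))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(tab, path)
  txt <- readLines(path)
  txt[3] <- sub("\t90\t9\t", "\t90\t95\t", txt[3])
  writeLines(txt, path)
  expect_error(read_variant_table(path), "line 3")

  # malformed numeric cell names its line
  write_variant_table(tab, path)
  txt <- readLines(path)
  txt[2] <- sub("\t100\t", "\tnot_a_number\t", txt[2])
  writeLines(txt, path)
  expect_error(read_variant_table(path), "line 2")
})

test_that("table constructor enforces roles and uniqueness", {
  expect_error(
    make_table(list(tum = ob("tumor", 100L, 10L),
                    tum2 = ob("tumor", 100L, 10L))),
    "exactly one normal")
  tab <- make_table(list(nrm = ob("normal", c(50L, 50L), c(0L, 0L)),
                         tum = ob("tumor", c(100L, 90L), c(15L, 9L))))
  tab$variants$pos <- c(110L, 110L)   # duplicate key
  expect_error(validate_variant_table(tab), "duplicated")
  # a sample without a declared role cannot be written
  tab2 <- make_table(list(nrm = ob("normal", 50L, 0L),
                          tum = ob("tumor", 100L, 15L)))
  tab2$roles <- tab2$roles["nrm"]
  expect_error(write_variant_table(tab2, tempfile()), "roles")
})

test_that("VCF ingestion matches tabular ingestion of the same cohort", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(vcf, records = list(
    list(chrom = "chr1", pos = 110, id = ".", ref = "A", alt = "T",
         info = "GENE=KRAS;COSMIC;NONSYN",
         gt = c("50:50,0:25,0:25,0", "100:85,15:50,8:35,7")),
    list(chrom = "chr1", pos = 120, id = "rs123", ref = "G", alt = "C",
         info = "GENE=XYZ",
         gt = c("60:59,1:30,1:29,0", "80:60,20:40,12:20,8")),
    list(chrom = "chr2", pos = 50, id = ".", ref = "C", alt = "A",
         info = ".", gt = c("40:40,0:20,0:20,0", "90:82,8:45,3:37,5"))),
    samples = c("buffy", "tumorA"))
  tab <- read_vcf(vcf, role_map = c(buffy = "normal", tumorA = "tumor"),
                  strand_fields = c(fwd = "ADF", rev = "ADR"))
  expect_equal(n_variants(tab), 3L)
  expect_equal(tab$variants$in_dbsnp, c(FALSE, TRUE, FALSE))
  expect_equal(tab$variants$in_cosmic, c(TRUE, FALSE, FALSE))
  expect_equal(tab$variants$gene[1:2], c("KRAS", "XYZ"))
  expect_equal(unname(tab$alt[, "tumorA"]), c(15L, 20L, 8L))
  expect_equal(unname(tab$alt_fwd[, "tumorA"]), c(8L, 12L, 3L))

  # same cohort via the tabular path gives an equal table
  tab2 <- make_table(list(
    buffy = ob("normal", c(50L, 60L, 40L), c(0L, 1L, 0L),
               c(0L, 1L, 0L), c(0L, 0L, 0L)),
    tumorA = ob("tumor", c(100L, 80L, 90L), c(15L, 20L, 8L),
                c(8L, 12L, 3L), c(7L, 8L, 5L))),
    in_dbsnp = c(FALSE, TRUE, FALSE), in_cosmic = c(TRUE, FALSE, FALSE),
    nonsynonymous = c(TRUE, FALSE, FALSE),
    genes = c("KRAS", "XYZ", "."))
  tab2$variants$chrom <- c("chr1", "chr1", "chr2")
  tab2$variants$pos <- c(110L, 120L, 50L)
  tab2$variants$ref <- c("A", "G", "C")
  tab2$variants$alt <- c("T", "C", "A")
  for (f in c("depth", "alt", "alt_fwd", "alt_rev"))
    expect_identical(unname(tab[[f]]), unname(tab2[[f]]))
  expect_equal(tab$variants$in_dbsnp, tab2$variants$in_dbsnp)
  expect_equal(variant_keys(tab), variant_keys(tab2))
})

test_that("multiallelic records split per alt allele; errors are specific", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(vcf, records = list(
    list(chrom = "chr1", pos = 200, id = ".", ref = "A", alt = "T,G",
         info = ".",
         gt = c("60:60,0,0:30,0,0:30,0,0", "100:70,20,10:50,12,6:20,8,4"))),
    samples = c("buffy", "tumorA"))
  tab <- read_vcf(vcf, role_map = c(buffy = "normal", tumorA = "tumor"),
                  strand_fields = c(fwd = "ADF", rev = "ADR"))
  expect_equal(n_variants(tab), 2L)
  expect_equal(tab$variants$alt, c("T", "G"))
  expect_equal(tab$variants$chrom, c("chr1", "chr1"))
  expect_equal(unname(tab$alt[, "tumorA"]), c(20L, 10L))

  # sample in role_map absent from the VCF is a configuration error
  expect_error(
    read_vcf(vcf, role_map = c(nosuch = "normal", tumorA = "tumor"),
             strand_fields = c(fwd = "ADF", rev = "ADR")),
    "nosuch")
  # missing allele-depth field is named
  vcf2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(vcf2, records = list(
    list(chrom = "chr1", pos = 200, id = ".", ref = "A", alt = "T",
         info = ".", gt = c("60:60,0", "100:70,20"))),
    samples = c("buffy", "tumorA"), strand = FALSE)
  expect_error(
    read_vcf(vcf2, role_map = c(buffy = "normal", tumorA = "tumor"),
             ad_field = "AO"),
    "AO")
  # without declared strand fields, strand counts are imputed with a warning
  expect_warning(
    tab3 <- read_vcf(vcf2, role_map = c(buffy = "normal", tumorA = "tumor")),
    "imputed")
  expect_true(isTRUE(attr(tab3, "strand_imputed")))
  expect_equal(unname(tab3$alt_fwd[, "tumorA"]), 20L)
  expect_equal(unname(tab3$alt_rev[, "tumorA"]), 0L)
})
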