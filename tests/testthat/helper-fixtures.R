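# Fixture builders and independent oracles, all constructed in code.

# Small hand-set cohort builder: `obs` is a named list sample -> list(role,
# depth, alt, fwd, rev) of parallel vectors (one element per variant).
make_table <- function(obs, in_dbsnp = NULL, in_cosmic = NULL,
                       nonsynonymous = NULL, genes = NULL) {
  n <- length(obs[[1L]]$depth)
  orf <- function(x, d) if (is.null(x)) rep(d, n) else x
  variants <- data.frame(
    chrom = "chr1", pos = 100L + seq_len(n) * 10L, ref = "A", alt = "T",
    gene = orf(genes, "g"), in_dbsnp = orf(in_dbsnp, FALSE),
    in_cosmic = orf(in_cosmic, FALSE),
    nonsynonymous = orf(nonsynonymous, TRUE))
  grab <- function(f) {
    m <- vapply(obs, function(o) as.integer(o[[f]]), integer(n))
    if (n == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(obs)))
    m
  }
  variant_table(variants, grab("depth"), grab("alt"), grab("fwd"),
                grab("rev"), vapply(obs, `[[`, "", "role"))
}

# obs entry shorthand
ob <- function(role, depth, alt, fwd = NULL, rev = NULL) {
  if (is.null(fwd)) { fwd <- alt %/% 2L; rev <- alt - fwd }
  list(role = role, depth = depth, alt = alt, fwd = fwd, rev = rev)
}

# Random cohort for filter-oracle and property tests (4 samples).
random_table <- function(n_variants, seed) {
  set.seed(seed)
  n <- n_variants
  mk <- function(role, dmax) {
    depth <- sample.int(dmax, n, replace = TRUE)
    alt <- rbinom(n, depth, runif(n, 0, 0.4))
    fwd <- rbinom(n, alt, 0.5)
    list(role = role, depth = depth, alt = alt, fwd = fwd, rev = alt - fwd)
  }
  make_table(
    list(nrm = mk("normal", 60L), tum = mk("tumor", 200L),
         met = mk("metastasis", 200L), pls = mk("plasma", 600L)),
    in_dbsnp = runif(n) < 0.2, in_cosmic = runif(n) < 0.1,
    nonsynonymous = runif(n) < 0.7)
}

# Independent, deliberately naive re-implementation of the filter cascade:
# scalar, rule-by-rule, no shared code with the package internals.
naive_classify <- function(tab, i, sid, cfg) {
  role <- cfexome::sample_roles(tab)[[sid]]
  nid <- names(which(cfexome::sample_roles(tab) == "normal"))
  d <- tab$depth[i, sid]; a <- tab$alt[i, sid]
  f <- tab$alt_fwd[i, sid]; r <- tab$alt_rev[i, sid]
  nd <- tab$depth[i, nid]; na_ <- tab$alt[i, nid]
  ann <- tab$variants[i, ]
  ok <- TRUE
  if (cfg$dbsnp_excludes_unless_cosmic && ann$in_dbsnp && !ann$in_cosmic)
    ok <- FALSE
  if (d < cfg$min_depth_case) ok <- FALSE
  if (nd < cfg$min_depth_normal) ok <- FALSE
  if (a < cfg$min_alt_reads) ok <- FALSE
  thr <- if (role == "plasma") cfg$min_vaf_plasma else cfg$min_vaf_tumor
  v <- if (d > 0) a / d else 0
  if (v < thr) ok <- FALSE
  if (role == "plasma") {
    if (na_ > cfg$max_normal_alt_reads) ok <- FALSE
    if (cfg$require_both_strands_plasma && (f < 1 || r < 1)) ok <- FALSE
  }
  ok
}

naive_apply_filters <- function(tab, cfg) {
  roles <- cfexome::sample_roles(tab)
  keys <- cfexome::variant_keys(tab)
  out <- list()
  for (sid in names(roles)[roles != "normal"]) {
    called <- logical(length(keys))
    for (i in seq_along(keys)) called[i] <- naive_classify(tab, i, sid, cfg)
    out[[sid]] <- keys[called]
  }
  out
}

# Brute-force small parsimony: minimum over all 0/1 assignments to internal
# nodes of the number of state changes along the edges.
brute_force_length <- function(edges, n_tip, tip_states) {
  internal <- setdiff(unique(as.vector(edges)), seq_len(n_tip))
  K <- ncol(tip_states)
  total <- 0L
  for (k in seq_len(K)) {
    best <- Inf
    for (code in 0:(2^length(internal) - 1L)) {
      st <- integer(max(edges))
      st[seq_len(n_tip)] <- tip_states[, k]
      bits <- as.integer(intToBits(code))[seq_along(internal)]
      st[internal] <- bits
      changes <- sum(st[edges[, 1L]] != st[edges[, 2L]])
      if (changes < best) best <- changes
    }
    total <- total + best
  }
  total
}

# Invoke the installed CLI front-end in a fresh R process.
run_cli <- function(...) {
  cli_path <- system.file("cli", "ctdna.R", package = "cfexome")
  out <- tempfile(); err <- tempfile()
  on.exit(unlink(c(out, err)), add = TRUE)
  status <- withr::with_envvar(
    c(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep)),
    system2(file.path(R.home("bin"), "Rscript"), c(cli_path, ...),
            stdout = out, stderr = err))
  list(status = status, stdout = readLines(out), stderr = readLines(err))
}

# Minimal VCF fixture writer (plain text), with DP/AD and optional ADF/ADR.
write_vcf_fixture <- function(path, records, samples, strand = TRUE) {
  fmt <- if (strand) "DP:AD:ADF:ADR" else "DP:AD"
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depth">',
    if (strand)
      c('##FORMAT=<ID=ADF,Number=R,Type=Integer,Description="Fwd allele depth">',
        '##FORMAT=<ID=ADR,Number=R,Type=Integer,Description="Rev allele depth">'),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(records, function(r)
    paste(c(r$chrom, r$pos, r$id, r$ref, r$alt, ".", "PASS", r$info, fmt,
            r$gt), collapse = "\t"), character(1))
  writeLines(c(hdr, body), path)
  path
}
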