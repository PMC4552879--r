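# Multi-sample variant container: a data frame of variant annotations plus
# aligned read-count matrices (variants x samples). Read counts are inputs;
# VAF is always derived as alt/depth, never stored.

#' Construct a multi-sample variant table
#'
#' A `variant_table` holds per-site read evidence for a cohort of samples
#' (one matched normal plus any number of tumor, metastasis and plasma
#' samples) together with variant annotations. Coordinates are 1-based,
#' fully closed, as in VCF. The variant allele fraction (VAF) is never
#' stored; it is derived as `alt_count / depth` on demand via [vaf()].
#'
#' @param variants data frame with columns `chrom`, `pos` (1-based integer),
#'   `ref`, `alt`, `gene`, and logicals `in_dbsnp`, `in_cosmic`,
#'   `nonsynonymous`. `(chrom, pos, ref, alt)` must be unique.
#' @param depth,alt,alt_fwd,alt_rev integer matrices, one row per variant and
#'   one column per sample (column names are sample ids). `alt_fwd + alt_rev`
#'   must equal `alt` and `alt <= depth` everywhere.
#' @param roles named character vector mapping every sample id to a role in
#'   `normal`, `tumor`, `metastasis`, `plasma`; exactly one sample must be
#'   the normal.
#' @return An object of class `variant_table`.
#' @seealso [read_variant_table()], [read_vcf()], [write_variant_table()]
#' @examples
#' tab <- variant_table(
#'   variants = data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
#'                         gene = "TP53", in_dbsnp = FALSE, in_cosmic = TRUE,
#'                         nonsynonymous = TRUE),
#'   depth   = cbind(normal = 60L, tumor = 100L),
#'   alt     = cbind(normal = 0L,  tumor = 15L),
#'   alt_fwd = cbind(normal = 0L,  tumor = 8L),
#'   alt_rev = cbind(normal = 0L,  tumor = 7L),
#'   roles   = c(normal = "normal", tumor = "tumor"))
#' vaf(tab, "tumor")
#' @export
variant_table <- function(variants, depth, alt, alt_fwd, alt_rev, roles) {
  as_mat <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    m
  }
  x <- structure(
    list(variants = as.data.frame(variants),
         depth = as_mat(depth), alt = as_mat(alt),
         alt_fwd = as_mat(alt_fwd), alt_rev = as_mat(alt_rev),
         roles = roles),
    class = "variant_table")
  validate_variant_table(x)
}

#' Validate a variant table's invariants
#'
#' Checks matrix conformity, role declarations (exactly one normal), count
#' invariants (`alt_fwd + alt_rev == alt_count`, `alt_count <= depth`,
#' non-negativity) and uniqueness of `(chrom, pos, ref, alt)` keys.
#'
#' @param x a [variant_table()].
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_variant_table <- function(x) {
  stopifnot(inherits(x, "variant_table"))
  req <- c("chrom", "pos", "ref", "alt", "gene",
           "in_dbsnp", "in_cosmic", "nonsynonymous")
  miss <- setdiff(req, names(x$variants))
  if (length(miss))
    stop("variant_table: missing annotation column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  ids <- colnames(x$depth)
  if (is.null(ids) || anyDuplicated(ids))
    stop("variant_table: depth matrix must have unique sample id columns",
         call. = FALSE)
  for (nm in c("alt", "alt_fwd", "alt_rev")) {
    m <- x[[nm]]
    if (!identical(dim(m), dim(x$depth)) || !identical(colnames(m), ids))
      stop("variant_table: matrix '", nm,
           "' does not conform to the depth matrix", call. = FALSE)
  }
  if (nrow(x$depth) != nrow(x$variants))
    stop("variant_table: count matrices and variant annotations disagree on ",
         "the number of variants", call. = FALSE)
  if (!setequal(names(x$roles), ids) || anyDuplicated(names(x$roles)))
    stop("variant_table: 'roles' must name every sample exactly once",
         call. = FALSE)
  x$roles <- x$roles[ids]
  bad_role <- setdiff(unique(x$roles), .valid_roles)
  if (length(bad_role))
    stop("variant_table: unknown role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  if (sum(x$roles == "normal") != 1L)
    stop("variant_table: cohort must contain exactly one normal sample",
         call. = FALSE)
  if (any(x$depth < 0L) || any(x$alt < 0L) ||
      any(x$alt_fwd < 0L) || any(x$alt_rev < 0L))
    stop("variant_table: read counts must be non-negative", call. = FALSE)
  bad <- which(x$alt_fwd + x$alt_rev != x$alt, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "variant_table: alt_fwd + alt_rev != alt_count at variant %d, sample '%s'",
      bad[1, 1], ids[bad[1, 2]]), call. = FALSE)
  bad <- which(x$alt > x$depth, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "variant_table: alt_count > depth at variant %d, sample '%s'",
      bad[1, 1], ids[bad[1, 2]]), call. = FALSE)
  if (anyDuplicated(variant_keys(x)))
    stop("variant_table: duplicated (chrom, pos, ref, alt) keys", call. = FALSE)
  invisible(x)
}

#' Variant keys
#'
#' Canonical `chrom:pos:ref:alt` identifiers, unique within a cohort.
#'
#' @param x a [variant_table()].
#' @return Character vector, one key per variant.
#' @export
variant_keys <- function(x) {
  with(x$variants, paste(chrom, pos, ref, alt, sep = ":"))
}

#' Sample ids and roles of a variant table
#'
#' @param x a [variant_table()].
#' @return `sample_ids()`: character vector of sample ids; `sample_roles()`:
#'   named character vector of roles keyed by sample id.
#' @export
sample_ids <- function(x) colnames(x$depth)

#' @rdname sample_ids
#' @export
sample_roles <- function(x) x$roles[colnames(x$depth)]

#' Number of variants in a table
#' @param x a [variant_table()].
#' @return Integer count.
#' @export
n_variants <- function(x) nrow(x$variants)

#' Variant allele fraction for one sample
#'
#' VAF is defined against total sequencing depth at the site:
#' `alt_count / depth` (0 where depth is 0).
#'
#' @param x a [variant_table()].
#' @param sample_id one of `sample_ids(x)`.
#' @return Numeric vector of VAFs, named by variant key.
#' @export
vaf <- function(x, sample_id) {
  .check_sample(x, sample_id)
  d <- x$depth[, sample_id]
  a <- x$alt[, sample_id]
  setNames(ifelse(d > 0L, a / d, 0), variant_keys(x))
}

.check_sample <- function(x, sample_id) {
  if (length(sample_id) != 1L || !sample_id %in% sample_ids(x))
    stop("unknown sample id: ", sample_id, call. = FALSE)
  invisible(sample_id)
}

.normal_id <- function(x) names(x$roles)[x$roles == "normal"][1L]

#' @export
print.variant_table <- function(x, ...) {
  roles <- sample_roles(x)
  cat(sprintf("variant_table: %d variant(s) x %d sample(s)\n",
              n_variants(x), length(roles)))
  cat("samples:", paste(sprintf("%s[%s]", names(roles), roles),
                        collapse = ", "), "\n")
  if (n_variants(x)) {
    cat("first variants:\n")
    print(utils::head(x$variants[, c("chrom", "pos", "ref", "alt", "gene")], 5L))
  }
  invisible(x)
}

#' Subset a variant table by variant
#'
#' @param x a [variant_table()].
#' @param i integer, logical or key-character index over variants.
#' @return A `variant_table` restricted to the selected variants.
#' @export
subset_variants <- function(x, i) {
  if (is.character(i)) {
    idx <- match(i, variant_keys(x))
    if (anyNA(idx))
      stop("unknown variant key(s): ", paste(i[is.na(idx)], collapse = ", "),
           call. = FALSE)
    i <- idx
  }
  variant_table(x$variants[i, , drop = FALSE],
                x$depth[i, , drop = FALSE], x$alt[i, , drop = FALSE],
                x$alt_fwd[i, , drop = FALSE], x$alt_rev[i, , drop = FALSE],
                x$roles)
}

# ---------------------------------------------------------------------------
# Tabular (TSV) serialization.
# Fixed columns: chrom pos ref alt gene in_dbsnp in_cosmic nonsynonymous,
# then per sample: <id>:<role>:depth <id>:<role>:alt <id>:<role>:alt_fwd
# <id>:<role>:alt_rev. Booleans serialized as 0/1.

.count_fields <- c("depth", "alt", "alt_fwd", "alt_rev")

#' Write a variant table to TSV
#'
#' The format is re-readable by [read_variant_table()] with equality: fixed
#' annotation columns then four read-count columns per sample, headed
#' `<sample>:<role>:<field>`; booleans are serialized as 0/1.
#'
#' @param table a [variant_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(table, path) {
  validate_variant_table(table)
  out <- table$variants[, c("chrom", "pos", "ref", "alt", "gene"), drop = FALSE]
  for (b in c("in_dbsnp", "in_cosmic", "nonsynonymous"))
    out[[b]] <- as.integer(table$variants[[b]])
  roles <- sample_roles(table)
  for (id in names(roles)) {
    for (f in .count_fields)
      out[[paste(id, roles[[id]], f, sep = ":")]] <- table[[f]][, id]
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("write_variant_table: cannot write '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a variant table from TSV
#'
#' Parses the tabular variant format written by [write_variant_table()].
#' Sample columns are declared in the header as `<sample>:<role>:<field>`
#' with role in `normal`/`tumor`/`metastasis`/`plasma` and field in `depth`,
#' `alt`, `alt_fwd`, `alt_rev`. Malformed rows raise a parse error naming the
#' offending line; count-invariant violations raise validation errors.
#'
#' @param path path to a TSV file.
#' @return A [variant_table()].
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path))
    stop("read_variant_table: no such file: ", path, call. = FALSE)
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", blank.lines.skip = FALSE)
  fixed <- c("chrom", "pos", "ref", "alt", "gene",
             "in_dbsnp", "in_cosmic", "nonsynonymous")
  miss <- setdiff(fixed, names(raw))
  if (length(miss))
    stop("read_variant_table: header lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  samp_cols <- setdiff(names(raw), fixed)
  m <- regmatches(samp_cols,
                  regexec("^(.+):(normal|tumor|metastasis|plasma):(depth|alt|alt_fwd|alt_rev)$",
                          samp_cols))
  bad <- samp_cols[lengths(m) == 0L]
  if (length(bad))
    stop("read_variant_table: unrecognized sample column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  info <- do.call(rbind, lapply(m, function(g)
    data.frame(id = g[2], role = g[3], field = g[4])))
  roles <- tapply(info$role, info$id, unique)
  if (any(lengths(roles) > 1L))
    stop("read_variant_table: conflicting roles declared for sample(s): ",
         paste(names(roles)[lengths(roles) > 1L], collapse = ", "),
         call. = FALSE)
  ids <- unique(info$id)
  for (id in ids) {
    have <- info$field[info$id == id]
    lack <- setdiff(.count_fields, have)
    if (length(lack))
      stop("read_variant_table: sample '", id, "' lacks column(s): ",
           paste(lack, collapse = ", "), call. = FALSE)
  }
  roles <- vapply(roles, `[[`, "", 1L)[ids]

  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) | (what == "int" & v != floor(v)))
    if (length(bad))
      stop(sprintf("read_variant_table: parse error at line %d, column '%s'",
                   bad[1] + 1L, col), call. = FALSE)   # +1 for header line
    v
  }
  n <- nrow(raw)
  variants <- data.frame(
    chrom = raw$chrom, pos = as.integer(num("pos", "int")),
    ref = raw$ref, alt = raw$alt, gene = raw$gene,
    in_dbsnp = num("in_dbsnp", "int") > 0,
    in_cosmic = num("in_cosmic", "int") > 0,
    nonsynonymous = num("nonsynonymous", "int") > 0)
  mats <- lapply(.count_fields, function(f) {
    mm <- matrix(0L, nrow = n, ncol = length(ids),
                 dimnames = list(NULL, ids))
    for (id in ids)
      mm[, id] <- as.integer(num(paste(id, roles[[id]], f, sep = ":"), "int"))
    mm
  })
  names(mats) <- .count_fields
  # per-row invariant diagnostics with line numbers before full validation
  bad <- which(mats$alt_fwd + mats$alt_rev != mats$alt, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "read_variant_table: alt_fwd + alt_rev != alt at line %d, sample '%s'",
      bad[1, 1] + 1L, ids[bad[1, 2]]), call. = FALSE)
  bad <- which(mats$alt > mats$depth, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "read_variant_table: alt_count > depth at line %d, sample '%s'",
      bad[1, 1] + 1L, ids[bad[1, 2]]), call. = FALSE)
  variant_table(variants, mats$depth, mats$alt, mats$alt_fwd, mats$alt_rev,
                roles)
}

#' Test two variant tables for equality
#'
#' @param a,b [variant_table()] objects.
#' @return `TRUE` if annotations, counts, sample ids and roles are all equal.
#' @export
variant_tables_equal <- function(a, b) {
  isTRUE(all.equal(a$variants, b$variants, check.attributes = FALSE)) &&
    identical(sample_ids(a), sample_ids(b)) &&
    identical(as.vector(sample_roles(a)), as.vector(sample_roles(b))) &&
    all(vapply(.count_fields,
               function(f) identical(unname(a[[f]]), unname(b[[f]])),
               logical(1)))
}
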