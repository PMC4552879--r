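# VCF ingestion (muTect-style per-site counts). We consume per-sample total
# depth and allele depth; strand-split alt counts come from declared
# per-sample fields (e.g. samtools ADF/ADR) or default to (alt, 0) with a
# warning. No VCF writing.

#' Read a VCF into a variant table
#'
#' Converts a VCF 4.x file with per-sample total-depth and allele-depth
#' fields into a [variant_table()]. Biallelic records convert 1:1;
#' multiallelic records are decomposed into one variant per alt allele
#' (per-alt allele depths of the other alts are ignored). Annotations are
#' taken from the record: `in_dbsnp` when the ID column carries an `rs`
#' identifier, `in_cosmic` when the ID or INFO mentions `COSM`/`COSMIC`,
#' `nonsynonymous` from a `NONSYN` INFO flag, `gene` from a `GENE=` INFO
#' entry.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param role_map named character vector mapping VCF sample names to roles
#'   (`normal`, `tumor`, `metastasis`, `plasma`). Only mapped samples are
#'   imported; a mapped sample absent from the VCF is a configuration error.
#' @param depth_field,ad_field per-sample FORMAT keys for total depth and
#'   allele depth (defaults `DP` and `AD`, with `AD = ref,alt1,alt2,...`).
#' @param strand_fields optional length-2 named character vector
#'   `c(fwd = ..., rev = ...)` of FORMAT keys holding per-allele
#'   forward/reverse allele depths (e.g. `c(fwd = "ADF", rev = "ADR")`).
#'   When `NULL`, strand counts default to `(alt_count, 0)` and the returned
#'   table carries attribute `strand_imputed = TRUE` (with a warning):
#'   strand-balance filtering is then uninformative.
#' @return A [variant_table()].
#' @export
read_vcf <- function(path, role_map, depth_field = "DP", ad_field = "AD",
                     strand_fields = NULL) {
  if (!file.exists(path))
    stop("read_vcf: no such file: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  vcf_samples <- colnames(v@gt)[-1L]
  missing_s <- setdiff(names(role_map), vcf_samples)
  if (length(missing_s))
    stop("read_vcf: sample(s) in role_map absent from VCF: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  need <- c(depth_field, ad_field,
            if (!is.null(strand_fields)) unname(strand_fields))
  lack <- setdiff(need, fmt_keys)
  if (length(lack))
    stop("read_vcf: required per-sample field(s) missing from FORMAT: ",
         paste(lack, collapse = ", "), call. = FALSE)

  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ids <- names(role_map)
  get_fld <- function(key)
    vcfR::extract.gt(v, element = key)[, ids, drop = FALSE]
  dp <- get_fld(depth_field)
  ad <- get_fld(ad_field)
  adf <- if (!is.null(strand_fields)) get_fld(strand_fields[["fwd"]])
  adr <- if (!is.null(strand_fields)) get_fld(strand_fields[["rev"]])

  nth <- function(str, j) {  # j-th comma-separated integer, NA-safe
    parts <- strsplit(ifelse(is.na(str), "", str), ",", fixed = TRUE)
    vapply(parts, function(p)
      if (length(p) >= j) suppressWarnings(as.integer(p[j])) else NA_integer_,
      integer(1))
  }

  rows <- list(); k <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    info <- if (is.na(fix$INFO[i])) "" else fix$INFO[i]
    id_col <- if (is.na(fix$ID[i])) "." else fix$ID[i]
    gene <- if (grepl("(^|;)GENE=", info))
      sub(".*GENE=([^;]+).*", "\\1", info) else "."
    ann <- list(
      in_dbsnp = grepl("(^|;)rs[0-9]+", id_col) || grepl("^rs[0-9]+", id_col),
      in_cosmic = grepl("COSM", id_col) || grepl("(^|;)COSMIC(;|$|=)", info),
      nonsynonymous = grepl("(^|;)NONSYN(;|$)", info))
    for (j in seq_along(alts)) {
      k <- k + 1L
      depth_i <- suppressWarnings(as.integer(dp[i, ]))
      alt_i <- nth(ad[i, ], j + 1L)
      if (anyNA(alt_i) || anyNA(depth_i))
        stop(sprintf(
          "read_vcf: missing %s/%s value at record %s:%s for a mapped sample",
          depth_field, ad_field, fix$CHROM[i], fix$POS[i]), call. = FALSE)
      if (is.null(strand_fields)) {
        fwd_i <- alt_i; rev_i <- rep(0L, length(alt_i))
      } else {
        fwd_i <- nth(adf[i, ], j + 1L)
        rev_i <- nth(adr[i, ], j + 1L)
      }
      rows[[k]] <- list(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[j], gene = gene, ann = ann,
        depth = depth_i, alt_count = alt_i, fwd = fwd_i, rev = rev_i)
    }
  }
  if (!k) stop("read_vcf: no records in ", path, call. = FALSE)

  variants <- data.frame(
    chrom = vapply(rows, `[[`, "", "chrom"),
    pos = vapply(rows, `[[`, 0L, "pos"),
    ref = vapply(rows, `[[`, "", "ref"),
    alt = vapply(rows, `[[`, "", "alt"),
    gene = vapply(rows, `[[`, "", "gene"),
    in_dbsnp = vapply(rows, function(r) r$ann$in_dbsnp, logical(1)),
    in_cosmic = vapply(rows, function(r) r$ann$in_cosmic, logical(1)),
    nonsynonymous = vapply(rows, function(r) r$ann$nonsynonymous, logical(1)))
  pull <- function(f) {
    m <- do.call(rbind, lapply(rows, `[[`, f))
    colnames(m) <- ids
    m
  }
  tab <- variant_table(variants, pull("depth"), pull("alt_count"),
                       pull("fwd"), pull("rev"), role_map)
  if (is.null(strand_fields)) {
    warning("read_vcf: no strand fields declared; alt_fwd/alt_rev imputed ",
            "as (alt_count, 0)", call. = FALSE)
    attr(tab, "strand_imputed") <- TRUE
  }
  tab
}
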