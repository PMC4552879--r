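# ctDNA summary metrics: mean VAF, tumor fraction, concordance between
# samples, VAF correlation, longitudinal tracking, validation and yield
# accounting.

#' Mean variant allele fraction over a call set
#'
#' Arithmetic mean of `alt_count / depth` across the given variants in one
#' sample. This is the quantity doubled by [estimate_tumor_fraction()].
#'
#' @param table a [variant_table()].
#' @param calls non-empty character vector of variant keys.
#' @param sample_id sample in which to measure the VAFs.
#' @return Mean VAF (fraction in \[0, 1\]).
#' @export
mean_vaf <- function(table, calls, sample_id) {
  validate_variant_table(table)
  .check_sample(table, sample_id)
  if (!length(calls))
    stop("mean_vaf: empty call set", call. = FALSE)
  v <- vaf(table, sample_id)
  miss <- setdiff(calls, names(v))
  if (length(miss))
    stop("mean_vaf: variant(s) not in table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  mean(v[calls])
}

#' Estimate the tumor-derived fraction of cfDNA
#'
#' Under the assumption that the averaged mutations are clonal and
#' heterozygous in a diploid tumor genome, each tumor-derived DNA molecule
#' carries the variant on one of its two alleles, so the tumor fraction is
#' twice the mean VAF, clipped at 1. Copy-number alterations and loss of
#' heterozygosity are deliberately ignored.
#'
#' @param mean_vaf mean clonal VAF in \[0, 1\] (see [mean_vaf()]).
#' @return Estimated tumor fraction in \[0, 1\]: `min(2 * mean_vaf, 1)`.
#' @examples
#' estimate_tumor_fraction(0.037)  # 0.074
#' estimate_tumor_fraction(0.14)   # 0.28
#' @export
estimate_tumor_fraction <- function(mean_vaf) {
  if (!is.numeric(mean_vaf) || anyNA(mean_vaf) ||
      any(mean_vaf < 0) || any(mean_vaf > 1))
    stop("estimate_tumor_fraction: mean_vaf must lie in [0, 1]", call. = FALSE)
  pmin(2 * mean_vaf, 1)
}

#' Report a fraction as a percentage, rounded half away from zero
#'
#' @param x fraction(s).
#' @param digits decimal places kept (0 for whole-percent rates).
#' @return `100 * x` rounded half away from zero to `digits` places.
#' @examples
#' percent(6 / 14)        # 43
#' percent(0.074, 1)      # 7.4
#' @export
percent <- function(x, digits = 0) {
  p <- 100 * x
  s <- 10^digits
  sign(p) * floor(abs(p) * s + 0.5) / s
}

#' Concordance of somatic calls between two samples
#'
#' Partitions a reference call set against the calls obtained in a query
#' sample (classified with its own role's rules): variants called in both
#' (`shared`), called only in the reference (`reference_only`) and called
#' only in the query (`query_only`). Query-unique variants that do have at
#' least one supporting read in the reference sample but sit below the
#' reference's VAF calling threshold are additionally reported as
#' `query_only_subthreshold_in_reference` (a subset of `query_only`) —
#' mutations missed in the reference solely for want of allele fraction.
#'
#' @param table a [variant_table()].
#' @param reference_calls character vector of variant keys called in the
#'   reference sample.
#' @param reference_sample_id,query_sample_id non-normal samples in `table`.
#' @param cfg a [filter_config()]; supplies the query-role rules and the
#'   reference role's VAF threshold for the subthreshold category.
#' @return An object of class `concordance_summary` with the four key sets
#'   and their sizes.
#' @export
concordance <- function(table, reference_calls, reference_sample_id,
                        query_sample_id, cfg = filter_config()) {
  validate_variant_table(table)
  .check_sample(table, reference_sample_id)
  .check_sample(table, query_sample_id)
  keys <- variant_keys(table)
  miss <- setdiff(reference_calls, keys)
  if (length(miss))
    stop("concordance: reference call(s) not in table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  query_calls <- apply_filters(table, cfg)$calls[[query_sample_id]]
  if (is.null(query_calls))
    stop("concordance: query sample must be non-normal", call. = FALSE)
  shared <- intersect(reference_calls, query_calls)
  ref_only <- setdiff(reference_calls, query_calls)
  query_only <- setdiff(query_calls, reference_calls)
  ref_role <- sample_roles(table)[[reference_sample_id]]
  if (!ref_role %in% .case_roles)
    stop("concordance: reference sample must be non-normal", call. = FALSE)
  ref_thresh <- if (ref_role == "plasma") cfg$min_vaf_plasma else
    cfg$min_vaf_tumor
  ref_vaf <- vaf(table, reference_sample_id)
  ref_alt <- setNames(table$alt[, reference_sample_id], keys)
  sub <- query_only[ref_alt[query_only] >= 1L &
                      ref_vaf[query_only] < ref_thresh]
  structure(list(shared = shared, reference_only = ref_only,
                 query_only = query_only,
                 query_only_subthreshold_in_reference = sub,
                 reference_sample_id = reference_sample_id,
                 query_sample_id = query_sample_id),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("concordance %s (reference) vs %s (query):\n",
              x$reference_sample_id, x$query_sample_id))
  cat(sprintf("  shared                     %d\n", length(x$shared)))
  cat(sprintf("  reference only             %d\n", length(x$reference_only)))
  cat(sprintf("  query only                 %d\n", length(x$query_only)))
  cat(sprintf("    of which subthreshold in reference: %d\n",
              length(x$query_only_subthreshold_in_reference)))
  invisible(x)
}

#' Pearson correlation of VAFs between two samples
#'
#' @param table a [variant_table()].
#' @param sample_a,sample_b samples whose per-variant VAFs are paired.
#' @param variants optional character vector of variant keys (default: all
#'   variants in the table). At least 3 points with non-zero variance in
#'   both samples are required.
#' @return Pearson correlation coefficient.
#' @export
vaf_correlation <- function(table, sample_a, sample_b, variants = NULL) {
  validate_variant_table(table)
  .check_sample(table, sample_a)
  .check_sample(table, sample_b)
  va <- vaf(table, sample_a)
  vb <- vaf(table, sample_b)
  if (!is.null(variants)) {
    miss <- setdiff(variants, names(va))
    if (length(miss))
      stop("vaf_correlation: variant(s) not in table: ",
           paste(miss, collapse = ", "), call. = FALSE)
    va <- va[variants]; vb <- vb[variants]
  }
  if (length(va) < 3L)
    stop("vaf_correlation: need at least 3 paired observations", call. = FALSE)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("vaf_correlation: zero variance in one sample", call. = FALSE)
  cor(va, vb, method = "pearson")
}

#' Orthogonal validation rate
#'
#' Fraction of re-sequenced candidate mutations that confirmed, excluding
#' assays that produced no sequence from the denominator.
#'
#' @param confirmed,failed,not_sequenced non-negative counts of validation
#'   outcomes; `confirmed + failed` must be at least 1.
#' @return `confirmed / (confirmed + failed)`.
#' @examples
#' percent(validation_rate(6, 8, 1))  # 43
#' @export
validation_rate <- function(confirmed, failed, not_sequenced = 0) {
  counts <- c(confirmed, failed, not_sequenced)
  if (anyNA(counts) || any(counts < 0))
    stop("validation_rate: counts must be non-negative", call. = FALSE)
  if (confirmed + failed < 1)
    stop("validation_rate: no sequenced outcomes (confirmed + failed == 0)",
         call. = FALSE)
  confirmed / (confirmed + failed)
}

#' Total cfDNA yield from a plasma extraction
#'
#' @param volume_extracted_ml plasma volume extracted (ml).
#' @param concentration_ng_per_ml cfDNA concentration (ng per ml plasma).
#' @return Total cfDNA in nanograms.
#' @examples
#' plasma_yield(25, 63)  # 1575 ng
#' @export
plasma_yield <- function(volume_extracted_ml, concentration_ng_per_ml) {
  if (anyNA(c(volume_extracted_ml, concentration_ng_per_ml)) ||
      any(c(volume_extracted_ml, concentration_ng_per_ml) < 0))
    stop("plasma_yield: inputs must be non-negative", call. = FALSE)
  volume_extracted_ml * concentration_ng_per_ml
}

#' Compare tracked mutations between two plasma timepoints
#'
#' For a set of mutations tracked across serial plasma draws (e.g. before
#' and during therapy), reports the paired VAFs per variant, the mean VAF
#' per timepoint over sites with at least one variant-supporting read, and
#' the count of sites with no detectable variant reads at each timepoint.
#'
#' @param table a [variant_table()] containing both plasma samples.
#' @param pre_sample_id,during_sample_id plasma samples at the two
#'   timepoints.
#' @param tracked character vector of variant keys tracked at both
#'   timepoints; every key must be present in the table.
#' @return An object of class `longitudinal_summary`: list with
#'   `per_variant` (data frame: `variant`, `alt_pre`, `alt_during`,
#'   `vaf_pre`, `vaf_during`), `mean_vaf_detected` (named numeric, `NA` for
#'   a timepoint with no detected site) and `n_zero` (named integer counts
#'   of undetected sites).
#' @export
longitudinal_compare <- function(table, pre_sample_id, during_sample_id,
                                 tracked) {
  validate_variant_table(table)
  .check_sample(table, pre_sample_id)
  .check_sample(table, during_sample_id)
  keys <- variant_keys(table)
  miss <- setdiff(tracked, keys)
  if (length(miss))
    stop("longitudinal_compare: tracked variant(s) missing from table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!length(tracked))
    stop("longitudinal_compare: empty tracked set", call. = FALSE)
  i <- match(tracked, keys)
  alt_pre <- table$alt[i, pre_sample_id]
  alt_during <- table$alt[i, during_sample_id]
  vaf_pre <- vaf(table, pre_sample_id)[i]
  vaf_during <- vaf(table, during_sample_id)[i]
  per_variant <- data.frame(
    variant = tracked, alt_pre = alt_pre, alt_during = alt_during,
    vaf_pre = unname(vaf_pre), vaf_during = unname(vaf_during))
  mean_det <- function(v, a) if (any(a >= 1L)) mean(v[a >= 1L]) else NA_real_
  structure(list(
    per_variant = per_variant,
    mean_vaf_detected = c(pre = mean_det(vaf_pre, alt_pre),
                          during = mean_det(vaf_during, alt_during)),
    n_zero = c(pre = sum(alt_pre == 0L), during = sum(alt_during == 0L))),
    class = "longitudinal_summary")
}

#' @export
print.longitudinal_summary <- function(x, ...) {
  n <- nrow(x$per_variant)
  cat(sprintf("longitudinal_summary: %d tracked mutation(s)\n", n))
  cat(sprintf("  mean VAF (detected sites): pre %s, during %s\n",
              format(x$mean_vaf_detected[["pre"]], digits = 3),
              format(x$mean_vaf_detected[["during"]], digits = 3)))
  cat(sprintf("  undetected sites: pre %d, during %d\n",
              x$n_zero[["pre"]], x$n_zero[["during"]]))
  invisible(x)
}
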