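# Matched-normal somatic filter cascade. Rules, in fixed audit order:
#   germline_db   variant in dbSNP and not rescued by COSMIC membership
#   depth_case    < min depth in the sample being classified
#   depth_normal  < min depth in the matched normal
#   alt_support   fewer than min_alt_reads variant-supporting reads
#   vaf           VAF below the role-specific threshold (tumor vs plasma)
# plasma-role samples only (cfDNA extra filters):
#   normal_contamination  matched normal has > max_normal_alt_reads alt reads
#   strand                variant reads on only one sequencing strand
# All rules are conjunctive; every failing rule is reported, not just the
# first. Comparisons are inclusive at the boundary (VAF exactly at the
# threshold passes).

.filter_rule_order <- c("germline_db", "depth_case", "depth_normal",
                        "alt_support", "vaf", "normal_contamination", "strand")

#' Somatic filter thresholds
#'
#' Thresholds of the somatic calling cascade applied on top of candidate
#' variants from a paired caller. Defaults follow common tumor/plasma exome
#' practice: >= 30x depth in the case sample and >= 10x in the matched
#' normal, VAF >= 10% for tissue (tumor/metastasis) and >= 1.5% for plasma,
#' >= 2 variant-supporting reads, dbSNP exclusion with COSMIC rescue, and
#' for plasma additionally <= 1 supporting read in the normal and
#' variant reads on both strands.
#'
#' @param min_depth_case minimum depth in the sample being classified (reads).
#' @param min_depth_normal minimum depth in the matched normal (reads).
#' @param min_vaf_tumor VAF threshold for tumor/metastasis samples (fraction).
#' @param min_vaf_plasma VAF threshold for plasma samples (fraction).
#' @param min_alt_reads minimum variant-supporting reads in the case sample.
#' @param max_normal_alt_reads maximum tolerated alt reads in the normal
#'   (plasma calls only); more than this many fails `normal_contamination`.
#' @param require_both_strands_plasma require >= 1 alt read on each strand
#'   for plasma calls.
#' @param dbsnp_excludes_unless_cosmic drop dbSNP variants unless also in
#'   COSMIC.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_depth_case = 30L, min_depth_normal = 10L,
                          min_vaf_tumor = 0.10, min_vaf_plasma = 0.015,
                          min_alt_reads = 2L, max_normal_alt_reads = 1L,
                          require_both_strands_plasma = TRUE,
                          dbsnp_excludes_unless_cosmic = TRUE) {
  cfg <- list(min_depth_case = as.integer(min_depth_case),
              min_depth_normal = as.integer(min_depth_normal),
              min_vaf_tumor = as.numeric(min_vaf_tumor),
              min_vaf_plasma = as.numeric(min_vaf_plasma),
              min_alt_reads = as.integer(min_alt_reads),
              max_normal_alt_reads = as.integer(max_normal_alt_reads),
              require_both_strands_plasma = isTRUE(require_both_strands_plasma),
              dbsnp_excludes_unless_cosmic = isTRUE(dbsnp_excludes_unless_cosmic))
  num <- unlist(cfg[1:6])
  if (any(num < 0)) stop("filter_config: thresholds must be >= 0", call. = FALSE)
  if (cfg$min_vaf_tumor > 1 || cfg$min_vaf_plasma > 1)
    stop("filter_config: VAF thresholds must lie in [0, 1]", call. = FALSE)
  structure(cfg, class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("filter_config:\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read or write a filter configuration as YAML
#'
#' The YAML keys mirror the [filter_config()] argument names exactly.
#'
#' @param path a YAML file path.
#' @param cfg a [filter_config()] (for writing).
#' @return `read_filter_config()` returns a `filter_config`;
#'   `write_filter_config()` returns `path` invisibly.
#' @export
read_filter_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(filter_config)))
  if (length(unknown))
    stop("read_filter_config: unknown field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(filter_config, vals)
}

#' @rdname read_filter_config
#' @export
write_filter_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "filter_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Vectorized rule engine shared by classify_variant(), apply_filters() and
# the Monte-Carlo power model, so every caller exercises the same code path.
# `role` is scalar; the remaining arguments are parallel vectors.
.eval_rules <- function(role, depth, alt, alt_fwd, alt_rev,
                        normal_depth, normal_alt, in_dbsnp, in_cosmic, cfg) {
  stopifnot(role %in% .case_roles)
  n <- length(depth)
  vafs <- ifelse(depth > 0L, alt / depth, 0)
  vaf_min <- if (role == "plasma") cfg$min_vaf_plasma else cfg$min_vaf_tumor
  is_plasma <- role == "plasma"
  fail <- cbind(
    germline_db = cfg$dbsnp_excludes_unless_cosmic & in_dbsnp & !in_cosmic,
    depth_case = depth < cfg$min_depth_case,
    depth_normal = normal_depth < cfg$min_depth_normal,
    alt_support = alt < cfg$min_alt_reads,
    vaf = vafs < vaf_min,
    normal_contamination =
      if (is_plasma) normal_alt > cfg$max_normal_alt_reads else rep(FALSE, n),
    strand =
      if (is_plasma && cfg$require_both_strands_plasma)
        alt_fwd < 1L | alt_rev < 1L else rep(FALSE, n))
  list(called = rowSums(fail) == 0L, fail = fail)
}

#' Classify one variant in one sample
#'
#' Applies the full somatic filter cascade to a single variant observation.
#' Tissue samples (roles `tumor`, `metastasis`) use `min_vaf_tumor` and
#' rules `germline_db`/`depth_case`/`depth_normal`/`alt_support`/`vaf`;
#' plasma samples use `min_vaf_plasma` and additionally the
#' `normal_contamination` and `strand` rules. All failing rules are
#' reported.
#'
#' @param table a [variant_table()].
#' @param variant a variant key (`chrom:pos:ref:alt`) or row index.
#' @param sample_id a non-normal sample id in the table.
#' @param cfg a [filter_config()].
#' @return An object of class `filter_decision`: list with `sample_id`,
#'   `called` (logical) and `failed_rules` (character, empty iff called).
#' @examples
#' tab <- simulate_cohort(preset_scenario("patient1"))$table
#' classify_variant(tab, 1L, "plasma", filter_config())
#' @export
classify_variant <- function(table, variant, sample_id, cfg = filter_config()) {
  validate_variant_table(table)
  stopifnot(inherits(cfg, "filter_config"))
  .check_sample(table, sample_id)
  role <- sample_roles(table)[[sample_id]]
  if (!role %in% .case_roles)
    stop("classify_variant: sample '", sample_id,
         "' has role '", role, "'; need tumor, metastasis or plasma",
         call. = FALSE)
  if (is.character(variant)) {
    i <- match(variant, variant_keys(table))
    if (is.na(i)) stop("classify_variant: unknown variant key: ", variant,
                       call. = FALSE)
  } else i <- as.integer(variant)
  if (is.na(i) || i < 1L || i > n_variants(table))
    stop("classify_variant: variant index out of range", call. = FALSE)
  nid <- .normal_id(table)
  if (is.na(table$depth[i, sample_id]) || is.na(table$depth[i, nid]))
    stop("classify_variant: missing observation at variant ", i, call. = FALSE)
  res <- .eval_rules(role,
                     depth = table$depth[i, sample_id],
                     alt = table$alt[i, sample_id],
                     alt_fwd = table$alt_fwd[i, sample_id],
                     alt_rev = table$alt_rev[i, sample_id],
                     normal_depth = table$depth[i, nid],
                     normal_alt = table$alt[i, nid],
                     in_dbsnp = table$variants$in_dbsnp[i],
                     in_cosmic = table$variants$in_cosmic[i],
                     cfg = cfg)
  structure(list(sample_id = sample_id,
                 variant = variant_keys(table)[i],
                 called = unname(res$called),
                 failed_rules = colnames(res$fail)[res$fail[1L, ]]),
            class = "filter_decision")
}

#' @export
print.filter_decision <- function(x, ...) {
  cat(sprintf("%s @ %s: %s%s\n", x$sample_id, x$variant,
              if (x$called) "CALLED" else "filtered",
              if (length(x$failed_rules))
                paste0(" [", paste(x$failed_rules, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Apply the somatic filter cascade to a whole cohort
#'
#' Classifies every variant in every non-normal sample and returns the
#' per-sample call sets plus a complete audit table (one row per variant and
#' non-normal sample, all failing rules listed).
#'
#' @param table a [variant_table()] with exactly one normal sample.
#' @param cfg a [filter_config()].
#' @return An object of class `somatic_calls`: list with
#'   \describe{
#'     \item{calls}{named list, one character vector of called variant keys
#'       per non-normal sample;}
#'     \item{audit}{data frame with columns `variant`, `chrom`, `pos`,
#'       `ref`, `alt`, `sample_id`, `role`, `called`, `failed_rules`;}
#'     \item{config}{the `filter_config` used.}
#'   }
#' @examples
#' coh <- simulate_cohort(preset_scenario("patient1"))
#' calls <- apply_filters(coh$table, filter_config())
#' lengths(calls$calls)
#' @export
apply_filters <- function(table, cfg = filter_config()) {
  validate_variant_table(table)
  stopifnot(inherits(cfg, "filter_config"))
  roles <- sample_roles(table)
  nid <- .normal_id(table)
  case_ids <- names(roles)[roles != "normal"]
  keys <- variant_keys(table)
  calls <- list()
  audits <- list()
  for (id in case_ids) {
    res <- tryCatch(
      .eval_rules(roles[[id]],
                  depth = table$depth[, id], alt = table$alt[, id],
                  alt_fwd = table$alt_fwd[, id], alt_rev = table$alt_rev[, id],
                  normal_depth = table$depth[, nid],
                  normal_alt = table$alt[, nid],
                  in_dbsnp = table$variants$in_dbsnp,
                  in_cosmic = table$variants$in_cosmic, cfg = cfg),
      error = function(e)
        stop("apply_filters: sample '", id, "': ", conditionMessage(e),
             call. = FALSE))
    calls[[id]] <- keys[res$called]
    failed <- if (!nrow(res$fail)) character(0) else
      apply(res$fail, 1L, function(f)
      paste(.filter_rule_order[.filter_rule_order %in% colnames(res$fail)[f]],
            collapse = ","))
    audits[[id]] <- data.frame(
      variant = keys, chrom = table$variants$chrom, pos = table$variants$pos,
      ref = table$variants$ref, alt = table$variants$alt,
      sample_id = rep(id, length(keys)), role = rep(roles[[id]], length(keys)),
      called = res$called, failed_rules = failed)
  }
  audit <- if (length(audits)) do.call(rbind, audits) else
    data.frame(variant = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), sample_id = character(),
               role = character(), called = logical(),
               failed_rules = character())
  rownames(audit) <- NULL
  structure(list(calls = calls, audit = audit, config = cfg),
            class = "somatic_calls")
}

#' @export
print.somatic_calls <- function(x, ...) {
  cat("somatic_calls:\n")
  if (!length(x$calls)) {
    cat("  (no case samples)\n")
    return(invisible(x))
  }
  for (id in names(x$calls))
    cat(sprintf("  %-12s %d called\n", id, length(x$calls[[id]])))
  invisible(x)
}
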