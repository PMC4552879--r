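# End-to-end demonstration pipeline on a preset cohort: simulate, filter,
# summarise, tree, power. Deterministic given the seed; the CLI front-end
# (inst/cli/ctdna.R) wraps this and the other exported entry points.

#' Run the full pipeline on a preset cohort
#'
#' Simulates a preset scenario, applies the somatic filter cascade,
#' estimates the plasma tumor fraction, computes tissue/plasma concordance
#' and VAF correlations, builds the maximum-parsimony sample tree (cohorts
#' with at least two non-normal samples), evaluates detection power at the
#' plasma depth, and — for the metastatic breast-cancer-like preset — adds
#' a during-treatment plasma draw and the longitudinal comparison. All
#' thresholds used are echoed into the report.
#'
#' @param preset `"patient1"` or `"patient2"` (see [preset_scenario()]).
#' @param seed integer seed controlling every random draw.
#' @param cfg a [filter_config()].
#' @return An object of class `ctdna_report` (a named list of results) with
#'   a formatted print method. Identical seeds yield identical reports.
#' @examples
#' run_demo("patient1", seed = 7)
#' @export
run_demo <- function(preset = c("patient1", "patient2"), seed = 7L,
                     cfg = filter_config()) {
  preset <- match.arg(preset)
  scen <- preset_scenario(preset, seed = seed)
  coh <- simulate_cohort(scen)
  calls <- apply_filters(coh$table, cfg)
  roles <- sample_roles(coh$table)
  plasma_id <- names(roles)[roles == "plasma"][1L]
  tissue_ids <- names(roles)[roles %in% c("tumor", "metastasis")]

  plasma_calls <- calls$calls[[plasma_id]]
  tf <- if (length(plasma_calls)) {
    mv <- mean_vaf(coh$table, plasma_calls, plasma_id)
    list(mean_vaf = mv, tumor_fraction = estimate_tumor_fraction(mv))
  } else list(mean_vaf = NA_real_, tumor_fraction = NA_real_)

  conc <- lapply(setNames(tissue_ids, tissue_ids), function(tid)
    concordance(coh$table, calls$calls[[tid]], tid, plasma_id, cfg))

  joint <- Reduce(union, calls$calls)   # common site set for all correlations
  cors <- lapply(setNames(tissue_ids, tissue_ids), function(tid) {
    if (length(joint) >= 3L)
      tryCatch(vaf_correlation(coh$table, plasma_id, tid, joint),
               error = function(e) NA_real_)
    else NA_real_
  })

  tree <- if (length(calls$calls) >= 2L) {
    mm <- tryCatch(
      build_mutation_matrix(calls$calls, coh$table, nonsynonymous_only = TRUE),
      error = function(e) NULL)
    if (!is.null(mm) && length(mm$samples) >= 3L) best_tree(mm) else NULL
  } else NULL

  power <- detection_probability(
    depth = as.integer(scen$samples[[plasma_id]]$depth_mean),
    true_vaf = scen$tumor_fraction_plasma / 2,
    error_rate = scen$error_rate, cfg = cfg)

  longitudinal <- NULL
  if (preset == "patient2" && length(plasma_calls) >= 1L) {
    coh2 <- simulate_treatment_response(coh, during_tumor_fraction = 8e-4,
                                        seed = seed + 1L)
    tracked <- plasma_calls[seq_len(min(8L, length(plasma_calls)))]
    longitudinal <- longitudinal_compare(coh2$table, plasma_id, "plasma_t2",
                                         tracked)
  }

  structure(list(
    preset = preset, seed = as.integer(seed),
    filter_config = cfg, scenario = scen,
    n_variants = n_variants(coh$table),
    calls_per_sample = lengths(calls$calls),
    plasma_sample = plasma_id,
    plasma_mean_vaf = tf$mean_vaf,
    tumor_fraction_estimate = tf$tumor_fraction,
    tumor_fraction_truth = scen$tumor_fraction_plasma,
    concordance = conc,
    vaf_correlation_with_plasma = unlist(cors),
    tree = tree,
    power_at_plasma_depth = power,
    longitudinal = longitudinal),
    class = "ctdna_report")
}

#' @export
print.ctdna_report <- function(x, ...) {
  cat(sprintf("ctDNA pipeline report — preset %s, seed %d\n",
              x$preset, x$seed))
  cat(sprintf("  sites simulated: %d; calls: %s\n", x$n_variants,
              paste(sprintf("%s=%d", names(x$calls_per_sample),
                            x$calls_per_sample), collapse = ", ")))
  cat(sprintf("  plasma mean VAF %.4f -> tumor fraction %.4f (truth %.4f)\n",
              x$plasma_mean_vaf, x$tumor_fraction_estimate,
              x$tumor_fraction_truth))
  for (tid in names(x$concordance)) {
    cc <- x$concordance[[tid]]
    cat(sprintf(
      "  %s vs plasma: shared %d, %s-only %d, plasma-only %d (subthreshold %d)\n",
      tid, length(cc$shared), tid, length(cc$reference_only),
      length(cc$query_only),
      length(cc$query_only_subthreshold_in_reference)))
  }
  if (length(x$vaf_correlation_with_plasma))
    cat("  VAF correlation with plasma:",
        paste(sprintf("%s=%.3f", names(x$vaf_correlation_with_plasma),
                      x$vaf_correlation_with_plasma), collapse = ", "), "\n")
  if (!is.null(x$tree))
    cat(sprintf("  parsimony tree (%d mutations): %s\n",
                x$tree$total_length, x$tree$newick))
  cat(sprintf("  detection power at plasma depth: %.4f\n",
              x$power_at_plasma_depth))
  if (!is.null(x$longitudinal)) {
    lg <- x$longitudinal
    cat(sprintf(
      "  longitudinal: pre mean VAF %.4f, during %s; undetected during: %d/%d\n",
      lg$mean_vaf_detected[["pre"]],
      ifelse(is.na(lg$mean_vaf_detected[["during"]]), "none detected",
             sprintf("%.5f", lg$mean_vaf_detected[["during"]])),
      lg$n_zero[["during"]], nrow(lg$per_variant)))
  }
  cat(sprintf(
    "  thresholds: case depth>=%d, normal depth>=%d, VAF>=%.3f (tissue) / %.3f (plasma), alt reads>=%d\n",
    x$filter_config$min_depth_case, x$filter_config$min_depth_normal,
    x$filter_config$min_vaf_tumor, x$filter_config$min_vaf_plasma,
    x$filter_config$min_alt_reads))
  invisible(x)
}
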