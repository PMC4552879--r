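# Cohort simulator with known clonal truth. Mutations belong to three
# clonal sets: trunk (all tumor clones), primary-private and
# metastasis-private. Tissue samples observe their clone at the tissue
# tumor purity; plasma observes a mixture of the two clones diluted to the
# plasma tumor fraction. Sites are diploid heterozygous, so the true VAF of
# a carried mutation is half the carrying tumor content. Null (non-mutant)
# sites measure the specificity of the downstream filter cascade.

#' Simulation scenario configuration
#'
#' Defines the generative truth of a multi-sample cohort: clone structure,
#' per-sample depth model, tumor content, error rates and seed.
#'
#' @param n_trunk number of clonal mutations shared by all tumor clones.
#' @param n_primary_private,n_met_private mutations private to the primary
#'   or metastasis clone.
#' @param samples named list describing the samples to generate; each
#'   element is `list(role =, depth_mean =, depth_size =)` with role in
#'   `normal`/`tumor`/`metastasis`/`plasma`. Depths are drawn
#'   negative-binomial with the given mean and dispersion (`size`), since
#'   real per-site exome depths are strongly overdispersed.
#' @param plasma_composition mixture weights `c(primary =, met =)` over the
#'   two clones within the tumor-derived compartment of plasma; must sum
#'   to 1.
#' @param tumor_fraction_plasma fraction of plasma cfDNA of tumor origin.
#' @param tumor_purity_tissue named vector of tumor purities for each
#'   tissue (tumor/metastasis-role) sample.
#' @param error_rate per-read substitution probability toward the alt
#'   allele in case samples.
#' @param n_null_sites non-mutant candidate sites (true VAF 0 everywhere).
#' @param normal_alt_rate per-read rate of trace alt reads in the matched
#'   normal.
#' @param frac_nonsynonymous fraction of mutations annotated
#'   nonsynonymous.
#' @param primary_marker_gene,met_marker_gene optional gene labels for a
#'   designated high-interest marker: the first primary-private (resp.
#'   metastasis-private) mutation is given this label and COSMIC
#'   membership, mimicking an actionable hotspot.
#' @param seed integer seed for [simulate_cohort()].
#' @return An object of class `scenario_config`.
#' @seealso [preset_scenario()] for ready-made two-patient scenarios.
#' @export
scenario_config <- function(n_trunk, n_primary_private = 0L,
                            n_met_private = 0L,
                            samples,
                            plasma_composition = c(primary = 1, met = 0),
                            tumor_fraction_plasma,
                            tumor_purity_tissue = NULL,
                            error_rate = 1e-3,
                            n_null_sites = 0L,
                            normal_alt_rate = 0,
                            frac_nonsynonymous = 1,
                            primary_marker_gene = NULL,
                            met_marker_gene = NULL,
                            seed = 1L) {
  cfg <- structure(as.list(environment()), class = "scenario_config")
  validate_scenario_config(cfg)
}

#' Validate a scenario configuration
#'
#' @param cfg a [scenario_config()].
#' @return `cfg` invisibly, or an error listing the offending fields.
#' @export
validate_scenario_config <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  bad <- character(0)
  chk <- function(ok, field) if (!isTRUE(all(ok))) bad <<- c(bad, field)
  chk(cfg$n_trunk >= 0 && cfg$n_primary_private >= 0 &&
        cfg$n_met_private >= 0 && cfg$n_null_sites >= 0, "mutation counts")
  chk(cfg$n_trunk + cfg$n_primary_private + cfg$n_met_private +
        cfg$n_null_sites > 0, "at least one site")
  chk(is.list(cfg$samples) && length(names(cfg$samples)) ==
        length(cfg$samples), "samples")
  roles <- vapply(cfg$samples, `[[`, "", "role")
  chk(all(roles %in% .valid_roles), "samples$role")
  chk(sum(roles == "normal") == 1, "exactly one normal sample")
  chk(all(vapply(cfg$samples, function(s)
    s$depth_mean > 0 && s$depth_size > 0, logical(1))), "depth model")
  chk(setequal(names(cfg$plasma_composition), c("primary", "met")) &&
        abs(sum(cfg$plasma_composition) - 1) < 1e-8 &&
        all(cfg$plasma_composition >= 0), "plasma_composition")
  frac_ok <- function(x) all(x >= 0 & x <= 1)
  chk(frac_ok(cfg$tumor_fraction_plasma), "tumor_fraction_plasma")
  tissue <- names(roles)[roles %in% c("tumor", "metastasis")]
  if (length(tissue)) {
    chk(!is.null(cfg$tumor_purity_tissue) &&
          all(tissue %in% names(cfg$tumor_purity_tissue)) &&
          frac_ok(cfg$tumor_purity_tissue), "tumor_purity_tissue")
  }
  chk(frac_ok(cfg$error_rate) && frac_ok(cfg$normal_alt_rate) &&
        frac_ok(cfg$frac_nonsynonymous),
      "rates")
  if (length(bad))
    stop("scenario_config: invalid field(s): ", paste(bad, collapse = "; "),
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  roles <- vapply(x$samples, `[[`, "", "role")
  cat(sprintf(
    "scenario_config: trunk %d, primary-private %d, met-private %d, null %d\n",
    x$n_trunk, x$n_primary_private, x$n_met_private, x$n_null_sites))
  cat(sprintf("  samples: %s\n",
              paste(sprintf("%s[%s, %gx]", names(roles), roles,
                            vapply(x$samples, `[[`, 0, "depth_mean")),
                    collapse = ", ")))
  cat(sprintf("  plasma tumor fraction %.3f (primary %.2f / met %.2f), error %g\n",
              x$tumor_fraction_plasma, x$plasma_composition[["primary"]],
              x$plasma_composition[["met"]], x$error_rate))
  invisible(x)
}

#' Ready-made scenarios for the two study patients
#'
#' `patient1`: a sarcoma-like cohort — 48 trunk mutations shared by primary
#' tumor and plasma, 1 primary-private mutation, plasma composed of the
#' primary clone at tumor fraction 0.074, plasma depth ~524x, tissue depth
#' ~118x, normal ~226x.
#'
#' `patient2`: a breast-cancer-like cohort with a sequenced metastasis —
#' 30 trunk, 9 primary-private (the first labelled as a PIK3CA-like
#' hotspot, absent from metastasis and plasma), 9 metastasis-private (the
#' first labelled as an ESR1-like resistance mutation, present in plasma),
#' plasma composed of the metastasis clone at tumor fraction 0.28, plasma
#' depth ~309x.
#'
#' @param name `"patient1"` or `"patient2"`.
#' @param seed overrides the preset's default seed when given.
#' @return A [scenario_config()].
#' @export
preset_scenario <- function(name = c("patient1", "patient2"), seed = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    patient1 = scenario_config(
      n_trunk = 48L, n_primary_private = 1L, n_met_private = 0L,
      samples = list(
        normal = list(role = "normal", depth_mean = 226, depth_size = 8),
        primary = list(role = "tumor", depth_mean = 118, depth_size = 8),
        plasma = list(role = "plasma", depth_mean = 524, depth_size = 8)),
      plasma_composition = c(primary = 1, met = 0),
      tumor_fraction_plasma = 0.074,
      tumor_purity_tissue = c(primary = 0.7),
      error_rate = 1e-3, n_null_sites = 200L, normal_alt_rate = 2e-4,
      frac_nonsynonymous = 0.85, seed = 101L),
    patient2 = scenario_config(
      n_trunk = 30L, n_primary_private = 9L, n_met_private = 9L,
      samples = list(
        normal = list(role = "normal", depth_mean = 201, depth_size = 8),
        primary = list(role = "tumor", depth_mean = 118, depth_size = 8),
        met = list(role = "metastasis", depth_mean = 183, depth_size = 8),
        plasma = list(role = "plasma", depth_mean = 309, depth_size = 8)),
      plasma_composition = c(primary = 0, met = 1),
      tumor_fraction_plasma = 0.28,
      tumor_purity_tissue = c(primary = 0.7, met = 0.7),
      error_rate = 1e-3, n_null_sites = 200L, normal_alt_rate = 2e-4,
      frac_nonsynonymous = 1,
      primary_marker_gene = "PIK3CA_H1047R_like",
      met_marker_gene = "ESR1_D538G_like",
      seed = 202L))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

# true VAF of each (site, sample) from clone membership and sample content
.true_vaf_matrix <- function(cfg, clones, sample_ids) {
  roles <- vapply(cfg$samples, `[[`, "", "role")
  carried <- cbind(primary = clones %in% c("trunk", "primary_private"),
                   met = clones %in% c("trunk", "met_private"))
  tv <- matrix(0, nrow = length(clones), ncol = length(sample_ids),
               dimnames = list(NULL, sample_ids))
  for (id in sample_ids) {
    role <- roles[[id]]
    if (role == "normal") next
    if (role %in% c("tumor", "metastasis")) {
      clone <- if (role == "tumor") "primary" else "met"
      tv[, id] <- carried[, clone] * cfg$tumor_purity_tissue[[id]] / 2
    } else {  # plasma: clone mixture diluted to the plasma tumor fraction
      w <- cfg$plasma_composition
      content <- carried[, "primary"] * w[["primary"]] +
        carried[, "met"] * w[["met"]]
      tv[, id] <- content * cfg$tumor_fraction_plasma / 2
    }
  }
  tv
}

.draw_sample_counts <- function(cfg, id, tv_col, n) {
  s <- cfg$samples[[id]]
  depth <- rnbinom(n, mu = s$depth_mean, size = s$depth_size)
  role <- s$role
  p <- if (role == "normal") rep(cfg$normal_alt_rate, n) else
    pmin(1, tv_col + (1 - tv_col) * cfg$error_rate)
  alt <- rbinom(n, depth, p)
  fwd <- rbinom(n, alt, 0.5)
  list(depth = as.integer(depth), alt = as.integer(alt),
       fwd = as.integer(fwd), rev = as.integer(alt - fwd))
}

#' Simulate a multi-sample read-count cohort with known truth
#'
#' Draws per-site, per-sample read counts under the scenario's generative
#' model: overdispersed (negative binomial) depths, binomial alt counts at
#' probability `true_vaf + (1 - true_vaf) * error_rate`, fair binomial
#' strand splits, and trace alt reads in the matched normal. The expected
#' observed VAF of a trunk site in plasma is `tumor_fraction_plasma / 2`.
#' Fully reproducible under `cfg$seed`.
#'
#' @param cfg a [scenario_config()].
#' @return An object of class `ctdna_cohort`: list with
#'   \describe{
#'     \item{table}{the simulated [variant_table()];}
#'     \item{truth}{data frame with `variant`, `gene`, `clone` (one of
#'       `trunk`, `primary_private`, `met_private`, `null`) and one
#'       `true_vaf_<sample>` column per sample;}
#'     \item{config}{the scenario.}
#'   }
#' @examples
#' coh <- simulate_cohort(preset_scenario("patient1"))
#' coh$table
#' @export
simulate_cohort <- function(cfg) {
  validate_scenario_config(cfg)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(cfg$seed))
  clones <- rep(c("trunk", "primary_private", "met_private", "null"),
                times = c(cfg$n_trunk, cfg$n_primary_private,
                          cfg$n_met_private, cfg$n_null_sites))
  n <- length(clones)
  idx_in_clone <- stats::ave(seq_len(n), clones, FUN = seq_along)
  gene <- sprintf("%s_%03d", toupper(sub("_private", "", clones)),
                  idx_in_clone)
  in_cosmic <- rep(FALSE, n)
  if (!is.null(cfg$primary_marker_gene) && cfg$n_primary_private > 0) {
    i <- which(clones == "primary_private")[1L]
    gene[i] <- cfg$primary_marker_gene
    in_cosmic[i] <- TRUE
  }
  if (!is.null(cfg$met_marker_gene) && cfg$n_met_private > 0) {
    i <- which(clones == "met_private")[1L]
    gene[i] <- cfg$met_marker_gene
    in_cosmic[i] <- TRUE
  }
  nonsyn <- rbinom(n, 1L, cfg$frac_nonsynonymous) == 1L
  nonsyn[in_cosmic] <- TRUE                       # hotspots are coding
  variants <- data.frame(
    chrom = "chr1", pos = 1000000L + seq_len(n) * 1000L,
    ref = "A", alt = "T", gene = gene,
    in_dbsnp = FALSE, in_cosmic = in_cosmic, nonsynonymous = nonsyn)
  ids <- names(cfg$samples)
  tv <- .true_vaf_matrix(cfg, clones, ids)
  mats <- list(depth = NULL, alt = NULL, alt_fwd = NULL, alt_rev = NULL)
  for (id in ids) {
    d <- .draw_sample_counts(cfg, id, tv[, id], n)
    mats$depth <- cbind(mats$depth, d$depth)
    mats$alt <- cbind(mats$alt, d$alt)
    mats$alt_fwd <- cbind(mats$alt_fwd, d$fwd)
    mats$alt_rev <- cbind(mats$alt_rev, d$rev)
  }
  for (f in names(mats)) colnames(mats[[f]]) <- ids
  roles <- vapply(cfg$samples, `[[`, "", "role")
  table <- variant_table(variants, mats$depth, mats$alt, mats$alt_fwd,
                         mats$alt_rev, roles)
  truth <- data.frame(variant = variant_keys(table), gene = gene,
                      clone = clones)
  for (id in ids) truth[[paste0("true_vaf_", id)]] <- tv[, id]
  structure(list(table = table, truth = truth, config = cfg),
            class = "ctdna_cohort")
}

#' @export
print.ctdna_cohort <- function(x, ...) {
  cat("ctdna_cohort:\n")
  print(x$table)
  cat("clones:", paste(sprintf("%s=%d", names(table(x$truth$clone)),
                               as.integer(table(x$truth$clone))),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Append a second plasma timepoint at a new tumor fraction
#'
#' Re-draws plasma observations for every site of an existing cohort at a
#' (typically reduced) tumor fraction, modelling a treatment-response blood
#' draw: same mutation truth, same plasma depth model and clone mixture,
#' new tumor content.
#'
#' @param cohort a `ctdna_cohort` from [simulate_cohort()].
#' @param during_tumor_fraction tumor fraction of the new plasma sample;
#'   if it exceeds the original plasma tumor fraction a warning notes the
#'   progression (which is legal).
#' @param seed integer seed for the new draws.
#' @param sample_id name for the appended plasma sample.
#' @return The cohort with the extra plasma sample appended to `table` and
#'   `truth`.
#' @export
simulate_treatment_response <- function(cohort, during_tumor_fraction,
                                        seed = 1L, sample_id = "plasma_t2") {
  stopifnot(inherits(cohort, "ctdna_cohort"))
  cfg <- cohort$config
  roles <- vapply(cfg$samples, `[[`, "", "role")
  pre_id <- names(roles)[roles == "plasma"][1L]
  if (is.na(pre_id))
    stop("simulate_treatment_response: cohort has no plasma sample",
         call. = FALSE)
  if (sample_id %in% sample_ids(cohort$table))
    stop("simulate_treatment_response: sample id '", sample_id,
         "' already present", call. = FALSE)
  if (during_tumor_fraction < 0 || during_tumor_fraction > 1)
    stop("simulate_treatment_response: tumor fraction must lie in [0, 1]",
         call. = FALSE)
  if (during_tumor_fraction > cfg$tumor_fraction_plasma)
    warning("during-treatment tumor fraction exceeds the pre-treatment one ",
            "(progression)", call. = FALSE)
  cfg2 <- cfg
  cfg2$tumor_fraction_plasma <- during_tumor_fraction
  cfg2$samples[[sample_id]] <- cfg$samples[[pre_id]]
  tv <- .true_vaf_matrix(cfg2, cohort$truth$clone, sample_id)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  d <- .draw_sample_counts(cfg2, sample_id, tv[, sample_id],
                           nrow(cohort$truth))
  tab <- cohort$table
  tab <- variant_table(
    tab$variants,
    cbind(tab$depth, matrix(d$depth, dimnames = list(NULL, sample_id))),
    cbind(tab$alt, matrix(d$alt, dimnames = list(NULL, sample_id))),
    cbind(tab$alt_fwd, matrix(d$fwd, dimnames = list(NULL, sample_id))),
    cbind(tab$alt_rev, matrix(d$rev, dimnames = list(NULL, sample_id))),
    c(tab$roles, setNames("plasma", sample_id)))
  cohort$table <- tab
  cohort$truth[[paste0("true_vaf_", sample_id)]] <- tv[, sample_id]
  cohort$during_config <- cfg2
  cohort
}
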