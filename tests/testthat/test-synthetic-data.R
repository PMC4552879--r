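# Cohort simulator: reproducibility, expectations, preset scenario logic.

test_that("simulation is reproducible and respects degenerate settings", {
  cfg <- preset_scenario("patient1")
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_true(variant_tables_equal(a$table, b$table))
  expect_identical(a$truth, b$truth)

  # zero tumor fraction and zero error: plasma is read-silent
  cfg0 <- scenario_config(
    n_trunk = 20L, samples = list(
      normal = list(role = "normal", depth_mean = 100, depth_size = 8),
      primary = list(role = "tumor", depth_mean = 100, depth_size = 8),
      plasma = list(role = "plasma", depth_mean = 300, depth_size = 8)),
    tumor_fraction_plasma = 0, tumor_purity_tissue = c(primary = 0.7),
    error_rate = 0, normal_alt_rate = 0, seed = 5L)
  coh0 <- simulate_cohort(cfg0)
  expect_true(all(coh0$table$alt[, "plasma"] == 0L))
})

test_that("plasma trunk VAF matches the tumor-fraction arithmetic", {
  # trunk sites in plasma have expected VAF = TF / 2; patient1 preset:
  # 48 trunk sites at TF 0.074 and depth ~524 -> mean observed VAF ~ 0.037
  cfg <- preset_scenario("patient1", seed = 31L)
  coh <- simulate_cohort(cfg)
  trunk <- coh$truth$clone == "trunk"
  expect_equal(unique(coh$truth$true_vaf_plasma[trunk]), 0.074 / 2)
  obs <- mean(vaf(coh$table, "plasma")[trunk])
  p <- 0.037 + (1 - 0.037) * cfg$error_rate
  se3 <- 3 * sqrt(p * (1 - p) / (48 * 524))
  expect_lt(abs(obs - p), se3 + 0.002)   # small depth-dispersion allowance
})

test_that("presets encode the two patients' study conditions", {
  p1 <- preset_scenario("patient1")
  expect_equal(p1$tumor_fraction_plasma, 0.074)
  expect_equal(p1$n_trunk, 48L)
  expect_equal(p1$samples$plasma$depth_mean, 524)
  expect_silent(validate_scenario_config(p1))

  p2 <- preset_scenario("patient2")
  expect_equal(p2$tumor_fraction_plasma, 0.28)
  expect_equal(p2$samples$plasma$depth_mean, 309)
  expect_equal(unname(p2$plasma_composition["met"]), 1)
  expect_silent(validate_scenario_config(p2))
  expect_error(preset_scenario("patient9"))
  # invalid configs name the offending fields
  bad <- p1
  bad$tumor_fraction_plasma <- 1.5
  expect_error(validate_scenario_config(bad), "tumor_fraction_plasma")
})

test_that("primary-only and met-private markers behave like the scenario", {
  # PIK3CA-like: clonal in the primary, absent from metastasis and plasma;
  # ESR1-like: in the metastasis clone, hence also in plasma
  cfg <- preset_scenario("patient2")
  cfg$error_rate <- 1e-4
  n_seeds <- 10L
  prim_called <- met_mark_called <- 0L
  for (s in seq_len(n_seeds)) {
    cfg$seed <- 7000L + s
    coh <- simulate_cohort(cfg)
    calls <- apply_filters(coh$table)
    pk <- coh$truth$variant[coh$truth$gene == "PIK3CA_H1047R_like"]
    es <- coh$truth$variant[coh$truth$gene == "ESR1_D538G_like"]
    expect_false(pk %in% calls$calls$plasma)
    expect_false(pk %in% calls$calls$met)
    prim_called <- prim_called + (pk %in% calls$calls$primary)
    met_mark_called <- met_mark_called +
      (es %in% calls$calls$met && es %in% calls$calls$plasma)
  }
  expect_gte(prim_called, 0.8 * n_seeds)
  expect_gte(met_mark_called, 0.8 * n_seeds)
})

test_that("treatment response re-draws plasma at the new tumor fraction", {
  cfg <- preset_scenario("patient2", seed = 55L)
  coh <- simulate_cohort(cfg)
  # zero during-treatment fraction and zero error: all tracked sites silent
  cfg0 <- cfg
  cfg0$error_rate <- 0
  coh0 <- simulate_cohort(cfg0)
  coh0$config$error_rate <- 0
  r0 <- simulate_treatment_response(coh0, 0, seed = 1L)
  tracked <- r0$truth$variant[r0$truth$clone != "null"][1:8]
  lg <- longitudinal_compare(r0$table, "plasma", "plasma_t2", tracked)
  expect_equal(lg$n_zero[["during"]], 8L)
  expect_true(is.na(lg$mean_vaf_detected[["during"]]))

  # during = pre: trunk mean VAF within 3 SE of the pre sample's
  r_same <- simulate_treatment_response(coh, cfg$tumor_fraction_plasma,
                                        seed = 2L)
  trunk <- r_same$truth$clone == "trunk"
  m_pre <- mean(vaf(r_same$table, "plasma")[trunk])
  m_during <- mean(vaf(r_same$table, "plasma_t2")[trunk])
  p <- cfg$tumor_fraction_plasma / 2
  se <- sqrt(2 * p * (1 - p) / (sum(trunk) * 309))
  expect_lt(abs(m_pre - m_during), 3 * se + 0.004)

  # hundredfold dilution scales mean VAF a hundredfold (Monte-Carlo check)
  cfg_many <- cfg
  cfg_many$n_trunk <- 200L
  cfg_many$n_null_sites <- 0L
  cfg_many$error_rate <- 0
  coh_many <- simulate_cohort(cfg_many)
  r_dil <- simulate_treatment_response(coh_many,
                                       cfg$tumor_fraction_plasma / 100,
                                       seed = 3L)
  trunk <- r_dil$truth$clone == "trunk"
  ratio <- mean(vaf(r_dil$table, "plasma")[trunk]) /
    mean(vaf(r_dil$table, "plasma_t2")[trunk])
  expect_gt(ratio, 50)
  expect_lt(ratio, 200)

  # progression warns but is legal
  expect_warning(simulate_treatment_response(coh, 0.9, seed = 4L),
                 "progression")
})

test_that("best_tree on a noise-free preset recovers the clone topology", {
  cfg <- preset_scenario("patient2")
  cfg$error_rate <- 0
  cfg$normal_alt_rate <- 0
  cfg$n_null_sites <- 0L
  cfg$seed <- 77L
  coh <- simulate_cohort(cfg)
  # characters straight from the generating truth (no read-sampling dropout)
  tv <- function(id) coh$truth$variant[coh$truth[[paste0("true_vaf_", id)]] > 0]
  mm <- build_mutation_matrix(
    list(primary = tv("primary"), met = tv("met"), plasma = tv("plasma")),
    coh$table)
  tr <- best_tree(mm)
  # plasma carries the metastasis clone: sisters in the tree
  expect_match(tr$newick, "\\(met:[0-9]+,plasma:[0-9]+\\)")
  # homoplasy-free: total length = number of distinct simulated mutations
  n_mut <- sum(coh$truth$clone != "null")
  expect_equal(tr$total_length, n_mut)
})
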