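# a small-but-nontrivial config reused across generator tests
small_cfg <- function(...) {
  args <- list(n_nodes = 20, n_patients = 5, n_controls = 6,
               planted_component = cbind(1L, 2:5),
               deficit_nodes = 6:8, clinical_node = 6, seed = 1)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

test_that("configuration validation names the offending field", {
  expect_error(simulation_config(base_density = 1.2), "base_density")
  expect_error(simulation_config(edge_removal_prob = -0.1), "edge_removal_prob")
  expect_error(simulation_config(fa_mean = 0.1, fa_sd = 0.08), "fa_mean")
  expect_error(simulation_config(planted_component = cbind(1L, 200L)),
               "planted_component")
  expect_error(simulation_config(planted_component = cbind(3L, 3L)), "self-pairs")
  expect_error(simulation_config(kappa_target = -2), "kappa_target")
  expect_error(simulation_config(clinical_rho = 1), "clinical_rho")
  expect_error(simulation_config(deficit_nodes = 0), "deficit_nodes")
})

test_that("degenerate densities give complete and empty graphs", {
  set.seed(1)
  cfg1 <- simulation_config(n_nodes = 4, base_density = 1, degree_spread = 0,
                            planted_component = matrix(integer(0), 0, 2),
                            deficit_nodes = integer(0), clinical_node = 1)
  m <- generate_control_connectome(cfg1)
  expect_equal(node_degree(m), rep(3L, 4))
  expect_equal(sum(unclass(m)[upper.tri(m)] > 0), 6)
  cfg0 <- simulation_config(n_nodes = 6, base_density = 0, degree_spread = 0,
                            planted_component = matrix(integer(0), 0, 2),
                            deficit_nodes = integer(0), clinical_node = 1)
  m0 <- generate_control_connectome(cfg0)
  expect_equal(node_degree(m0), rep(0L, 6))
})

test_that("mean nodal degree matches the binomial expectation", {
  cfg <- simulation_config(n_nodes = 164, base_density = 0.68,
                           planted_component = matrix(integer(0), 0, 2),
                           deficit_nodes = integer(0), clinical_node = 1)
  set.seed(99)
  reps <- 200
  md <- vapply(seq_len(reps), function(i)
    mean_degree(generate_control_connectome(cfg)), numeric(1))
  expected <- 0.68 * 163
  # per-subject SD of mean degree is small; use the empirical SE
  se <- sd(md) / sqrt(reps)
  expect_lt(abs(mean(md) - expected), max(2 * se, 0.5))
})

test_that("matrices are valid and reproducible bit-identically from the seed", {
  co1 <- simulate_cohort(small_cfg())
  co2 <- simulate_cohort(small_cfg())
  expect_identical(lapply(co1$matrices, unclass), lapply(co2$matrices, unclass))
  expect_identical(co1$clinical, co2$clinical)
  for (m in co1$matrices) {
    w <- unclass(m)
    expect_true(isSymmetric(w))
    expect_equal(diag(w), rep(0, nrow(w)))
    expect_true(all(w >= 0 & w < 1))
  }
  # different seed changes draws
  co3 <- simulate_cohort(small_cfg(seed = 2))
  expect_false(identical(unclass(co1$matrices[[1]]), unclass(co3$matrices[[1]])))
})

test_that("per-subject substreams are stable under cohort resizing", {
  co1 <- simulate_cohort(small_cfg())
  co2 <- simulate_cohort(small_cfg(n_controls = 8))
  expect_identical(unclass(co1$matrices[["control01"]]),
                   unclass(co2$matrices[["control01"]]))
  expect_identical(unclass(co1$matrices[["patient03"]]),
                   unclass(co2$matrices[["patient03"]]))
})

test_that("null effects leave patient matrices untouched by effect application", {
  cfg <- small_cfg(fa_effect = 0, edge_removal_prob = 0)
  set.seed(5)
  m <- generate_control_connectome(cfg)
  set.seed(6)
  m2 <- apply_patient_effects(m, cfg)
  expect_identical(unclass(m2), unclass(m))
})

test_that("edge removal probability 1 isolates deficit nodes", {
  cfg <- small_cfg(edge_removal_prob = 1)
  set.seed(5)
  m <- generate_control_connectome(cfg)
  set.seed(6)
  m2 <- apply_patient_effects(m, cfg)
  expect_equal(node_degree(m2)[6:8], rep(0L, 3))
})

test_that("planted FA effect shifts planted-edge means by fa_effect", {
  cfg <- small_cfg(fa_effect = 0.1, edge_removal_prob = 0)
  idx <- cbind(cfg$planted_component[, 1], cfg$planted_component[, 2])
  diffs <- vapply(1:40, function(s) {
    co <- simulate_cohort(simulation_config(n_nodes = 20, n_patients = 5,
                                            n_controls = 6,
                                            planted_component = cbind(1L, 2:5),
                                            deficit_nodes = 6:8,
                                            clinical_node = 6,
                                            fa_effect = 0.1,
                                            edge_removal_prob = 0,
                                            seed = 400 + s))
    pat <- cohort_subjects(co, "patient")
    ctl <- cohort_subjects(co, "control")
    pm <- mean(vapply(pat, function(id) mean(unclass(co$matrices[[id]])[idx]), numeric(1)))
    cm <- mean(vapply(ctl, function(id) mean(unclass(co$matrices[[id]])[idx]), numeric(1)))
    cm - pm
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 0.1), 0.02)
})

test_that("clinical covariates obey the progression-rate formula and coupling", {
  co <- simulate_cohort(small_cfg())
  cl <- co$clinical
  pats <- cohort_subjects(co, "patient")
  expect_true(all(is.na(cl$alsfrs_r[!cl$subject_id %in% pats])))
  p <- cl[cl$subject_id %in% pats, ]
  expect_true(all(p$alsfrs_r >= 0 & p$alsfrs_r <= 48))
  expect_true(all(p$duration_months > 0))
  rate <- progression_rate(p$alsfrs_r, p$duration_months)
  expect_true(all(rate >= 0))
  # rho = 0 decouples: mean |rho| over replicate cohorts near 0
  rhos <- vapply(1:30, function(s) {
    co0 <- simulate_cohort(small_cfg(clinical_rho = 0, seed = 600 + s))
    cl0 <- co0$clinical[co0$clinical$subject_id %in% cohort_subjects(co0, "patient"), ]
    deg <- vapply(cl0$subject_id, function(id)
      sum(unclass(co0$matrices[[id]])[6, ] > 0), numeric(1))
    spearman_correlation(deg, progression_rate(cl0$alsfrs_r, cl0$duration_months))$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.2)
})

test_that("null-effect cohorts give near-nominal nodal false-positive rates", {
  # exchangeability check on a continuous nodal metric: subjects share the
  # cohort skeleton, so weighted betweenness (driven by the FA weights)
  # carries the between-subject variability
  ps <- unlist(lapply(1:8, function(s) {
    co <- simulate_cohort(null_simulation_config(
      simulation_config(n_nodes = 30, n_patients = 10, n_controls = 10,
                        planted_component = cbind(1L, 2:3), deficit_nodes = 4:5,
                        clinical_node = 4, seed = 700 + s)))
    tbl <- compute_metrics_table(co, metrics = "bc", globals = FALSE)
    nodal_group_comparison(tbl, threshold_scheme(n_tests = 30), "bc")$p
  }))
  expect_lt(abs(mean(ps < 0.05, na.rm = TRUE) - 0.05), 0.035)
})
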