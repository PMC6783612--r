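# tiny cohort with a hand-set edge: subjects share a fixed 5-node skeleton,
# edge (1,2) carries group-specific weights
handmade_cohort <- function(w12_ctrl, w12_pat, n_nodes = 5) {
  base <- edges_to_matrix(n_nodes, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 5)),
                          c(0.5, 0.4, 0.45, 0.5, 0.42))
  mats <- list()
  groups <- character(0)
  for (i in seq_along(w12_pat)) {
    m <- base; m[1, 2] <- m[2, 1] <- w12_pat[i]
    sid <- sprintf("p%02d", i)
    mats[[sid]] <- connectivity_matrix(m, subject_id = sid)
    groups[sid] <- "patient"
  }
  for (i in seq_along(w12_ctrl)) {
    m <- base; m[1, 2] <- m[2, 1] <- w12_ctrl[i]
    sid <- sprintf("c%02d", i)
    mats[[sid]] <- connectivity_matrix(m, subject_id = sid)
    groups[sid] <- "control"
  }
  new_cohort(mats, groups,
             data.frame(subject_id = names(mats), alsfrs_r = NA_real_,
                        duration_months = NA_real_, stringsAsFactors = FALSE),
             paste0("r", seq_len(n_nodes)))
}

test_that("edge statistic matches the pooled-variance t-test", {
  ctrl <- c(0.50, 0.52, 0.48)
  pat <- c(0.20, 0.22, 0.18)
  co <- handmade_cohort(ctrl, pat)
  s <- edge_statistic(co, "t")
  tt <- t.test(ctrl, pat, var.equal = TRUE)
  expect_equal(s[1, 2], unname(tt$statistic), tolerance = 1e-12)
  expect_gt(s[1, 2], 10)  # strongly reduced FA in patients -> large positive t
  # identical groups on an edge: statistic 0 (shared base edges)
  expect_equal(s[2, 3], 0)
  # constant but different groups: infinite statistic, still supra-threshold
  s2 <- edge_statistic(handmade_cohort(c(0.5, 0.5, 0.5), c(0.2, 0.2, 0.2)), "t")
  expect_true(is.infinite(s2[1, 2]) && s2[1, 2] > 0)
})

test_that("the mask rule excludes edges absent in any subject", {
  co <- handmade_cohort(c(0.5, 0.5, 0.48), c(0.3, 0.31, 0.29))
  co$matrices[["c01"]][1, 2] <- co$matrices[["c01"]][2, 1] <- 0
  s <- edge_statistic(co, "t", edge_mask_rule = 1.0)
  expect_true(is.na(s[1, 2]))
  s2 <- edge_statistic(co, "t", edge_mask_rule = 0.5)
  expect_false(is.na(s2[1, 2]))
})

test_that("supra-threshold components are connected subgraphs with extents", {
  stat <- matrix(NA_real_, 6, 6)
  set_edge <- function(i, j, v) stat[i, j] <<- stat[j, i] <<- v
  set_edge(1, 2, 4); set_edge(2, 3, 3.5); set_edge(4, 5, 5); set_edge(5, 6, 1)
  comps <- supra_threshold_components(stat, 3)
  expect_length(comps, 2)
  expect_equal(vapply(comps, `[[`, integer(1), "extent"), c(2L, 1L))
  expect_equal(comps[[1]]$nodes, 1:3)
  # star of 10 supra edges: one component, 11 nodes, extent 10
  star <- matrix(NA_real_, 12, 12)
  for (j in 2:11) star[1, j] <- star[j, 1] <- 4
  cs <- supra_threshold_components(star, 3)
  expect_length(cs, 1)
  expect_equal(cs[[1]]$extent, 10L)
  expect_length(cs[[1]]$nodes, 11)
  # nothing above threshold
  expect_length(supra_threshold_components(stat, 10), 0)
})

test_that("nbs p-values follow the permutation estimator and are reproducible", {
  cfg <- simulation_config(n_nodes = 24, n_patients = 8, n_controls = 8,
                           planted_component = cbind(1L, 2:6),
                           deficit_nodes = integer(0), edge_removal_prob = 0,
                           fa_effect = 0.2, clinical_node = 1, seed = 42)
  co <- simulate_cohort(cfg)
  nc <- nbs_config(n_permutations = 200, seed = 3, primary_threshold = 2.5)
  r1 <- nbs_test(co, nc)
  r2 <- nbs_test(co, nc)
  expect_identical(r1$null_max_extent, r2$null_max_extent)
  expect_identical(vapply(r1$components, `[[`, numeric(1), "p_fwer"),
                   vapply(r2$components, `[[`, numeric(1), "p_fwer"))
  for (c in r1$components) {
    expect_gt(c$p_fwer, 0)
    expect_lte(c$p_fwer, 1)
    expect_equal(c$p_fwer,
                 (1 + sum(r1$null_max_extent >= c$extent)) / (200 + 1))
  }
  # subject order invariance
  co_shuf <- co
  ord <- rev(cohort_subjects(co))
  co_shuf$matrices <- co_shuf$matrices[ord]
  co_shuf$groups <- co_shuf$groups[ord]
  r3 <- nbs_test(co_shuf, nc)
  expect_identical(vapply(r3$components, `[[`, numeric(1), "p_fwer"),
                   vapply(r1$components, `[[`, numeric(1), "p_fwer"))
})

test_that("observed max extent is non-increasing in the primary threshold", {
  cfg <- simulation_config(n_nodes = 24, n_patients = 8, n_controls = 8,
                           planted_component = cbind(1L, 2:6),
                           deficit_nodes = integer(0), edge_removal_prob = 0,
                           fa_effect = 0.15, clinical_node = 1, seed = 13)
  co <- simulate_cohort(cfg)
  ext <- vapply(c(1.5, 2, 2.5, 3, 4), function(thr) {
    s <- edge_statistic(co, "t")
    comps <- supra_threshold_components(s, thr)
    if (length(comps)) comps[[1]]$extent else 0L
  }, integer(1))
  expect_true(all(diff(ext) <= 0))
})

test_that("monte-carlo p agrees with exact enumeration on tiny cohorts", {
  cfg <- simulation_config(n_nodes = 16, n_patients = 5, n_controls = 5,
                           planted_component = cbind(1L, 2:4),
                           deficit_nodes = integer(0), edge_removal_prob = 0,
                           fa_effect = 0.25, clinical_node = 1, seed = 8)
  co <- simulate_cohort(cfg)
  thr <- 2.2
  rex <- nbs_test(co, nbs_config(n_permutations = 100, seed = 1, method = "exact",
                                 primary_threshold = thr))
  rmc <- nbs_test(co, nbs_config(n_permutations = 200, seed = 2,
                                 primary_threshold = thr))
  expect_gt(length(rex$components), 0)
  for (i in seq_along(rex$components)) {
    pe <- rex$components[[i]]$p_fwer
    pm <- rmc$components[[i]]$p_fwer
    se <- sqrt(pe * (1 - pe) / 200)
    expect_lt(abs(pm - pe), 2 * se + 2 / 200)
  }
})

test_that("nbs fa sums total the subject's FA over component edges", {
  co <- handmade_cohort(c(0.5, 0.5), c(0.45, 0.45))
  edges <- rbind(c(1, 2))
  expect_equal(nbs_fa_sum(co$matrices[["c01"]], edges), 0.5)
  # absent edges contribute zero
  edges10 <- rbind(c(1, 2), c(2, 3), c(1, 4))  # (1,4) absent in the skeleton
  expect_equal(nbs_fa_sum(co$matrices[["c01"]], edges10), 0.5 + 0.4)
  expect_error(nbs_fa_sum(co$matrices[["c01"]], matrix(0, 0, 2)), "empty")
  expect_error(nbs_fa_sum(co$matrices[["c01"]], rbind(c(1, 99))), "outside")
})

test_that("planted subnetworks are detected and their FA sums separate groups", {
  cfg <- simulation_config(seed = 77)  # full defaults: 10-edge star, fa_effect 0.15
  co <- simulate_cohort(cfg)
  r <- nbs_test(co, nbs_config(n_permutations = 300, seed = 4))
  sig <- Filter(function(c) isTRUE(c$significant), r$components)
  expect_gt(length(sig), 0)
  planted <- cfg$planted_component
  pk <- paste(pmin(planted[, 1], planted[, 2]), pmax(planted[, 1], planted[, 2]))
  found <- unlist(lapply(sig, function(c)
    paste(pmin(c$edges[, 1], c$edges[, 2]), pmax(c$edges[, 1], c$edges[, 2]))))
  expect_gte(sum(pk %in% found), 8)
  expect_lt(r$fa_sum_test$p.value, 0.05)
  pat <- r$fa_sums$nbs_fa_sum[r$fa_sums$group == "patient"]
  ctl <- r$fa_sums$nbs_fa_sum[r$fa_sums$group == "control"]
  expect_lt(mean(pat), mean(ctl))
})

test_that("tiny cohorts demand exact enumeration and configs validate", {
  co <- handmade_cohort(c(0.5, 0.52), c(0.2, 0.22))
  expect_error(nbs_test(co, nbs_config(n_permutations = 500, seed = 1)), "exact")
  expect_error(nbs_config(n_permutations = 50), "100")
  expect_error(nbs_config(alpha = 1.2), "alpha")
  expect_error(nbs_config(primary_threshold = -1), "positive")
})
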