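test_that("node degree counts strictly positive off-diagonal weights", {
  # star on 5 nodes
  star <- edges_to_matrix(5, cbind(1, 2:5))
  expect_equal(node_degree(star), c(4L, 1L, 1L, 1L, 1L))
  # empty graph
  expect_equal(node_degree(matrix(0, 4, 4)), rep(0L, 4))
  # weighted edges {1-2, 1-3, 3-4}
  g <- edges_to_matrix(4, rbind(c(1, 2), c(1, 3), c(3, 4)), c(0.3, 0.6, 0.2))
  expect_equal(node_degree(g), c(2L, 1L, 2L, 1L))
  expect_equal(mean_degree(g), 1.5)
  k4 <- edges_to_matrix(4, t(combn(4, 2)))
  expect_equal(mean_degree(k4), 3)
  expect_equal(mean_degree(matrix(0, 3, 3)), 0)
})

test_that("shortest path lengths follow the 1/w length convention", {
  path3 <- edges_to_matrix(3, rbind(c(1, 2), c(2, 3)))
  d <- shortest_path_lengths(path3, "binary")
  expect_equal(d[1, 3], 2)
  single <- edges_to_matrix(2, cbind(1, 2), 0.5)
  expect_equal(shortest_path_lengths(single, "weighted")[1, 2], 2)
  two_comp <- edges_to_matrix(4, rbind(c(1, 2), c(3, 4)))
  expect_true(is.infinite(shortest_path_lengths(two_comp, "binary")[1, 3]))
  expect_equal(diag(shortest_path_lengths(path3, "weighted")), rep(0, 3))
})

test_that("global efficiency matches enumerated pair averages", {
  k5 <- edges_to_matrix(5, t(combn(5, 2)))
  expect_equal(global_efficiency(k5, "binary"), 1)
  path3 <- edges_to_matrix(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(global_efficiency(path3, "binary"), (1 + 1 + 0.5) / 3)
  expect_equal(global_efficiency(matrix(0, 4, 4), "binary"), 0)
  expect_error(global_efficiency(matrix(0, 1, 1)), "at least 2 nodes")
})

test_that("local efficiency is neighborhood global efficiency", {
  tri <- edges_to_matrix(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(local_efficiency(tri, "binary"), rep(1, 3))
  star <- edges_to_matrix(5, cbind(1, 2:5))
  eloc <- local_efficiency(star, "binary")
  expect_equal(eloc[1], 0)  # leaves are mutually disconnected
  expect_equal(eloc[2:5], rep(0, 4))  # < 2 neighbors convention
  iso <- matrix(0, 3, 3)
  expect_equal(local_efficiency(iso, "weighted"), rep(0, 3))
})

test_that("betweenness centrality counts unordered pairs once, unnormalized", {
  path3 <- edges_to_matrix(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(betweenness_centrality(path3, "binary"), c(0, 1, 0))
  k5 <- edges_to_matrix(5, t(combn(5, 2)))
  expect_equal(betweenness_centrality(k5, "binary"), rep(0, 5))
  star <- edges_to_matrix(5, cbind(1, 2:5))
  expect_equal(betweenness_centrality(star, "binary"), c(6, 0, 0, 0, 0))
})

test_that("possible-connection count is n(n-1)", {
  expect_identical(count_possible_connections(164), 26732L)
  expect_identical(count_possible_connections(2), 2L)
  expect_identical(count_possible_connections(10), 90L)
  expect_error(count_possible_connections(1), "at least 2")
})

test_that("metrics agree with the exhaustive-path oracle on small graphs", {
  set.seed(42)
  for (rep in 1:12) {
    n <- sample(4:7, 1)
    w <- random_small_graph(n, density = runif(1, 0.4, 0.9))
    for (mode in c("weighted", "binary")) {
      expect_equal(global_efficiency(w, mode), oracle_global_efficiency(w, mode),
                   tolerance = 1e-9)
      expect_equal(local_efficiency(w, mode), oracle_local_efficiency(w, mode),
                   tolerance = 1e-9)
      expect_equal(betweenness_centrality(w, mode), oracle_betweenness(w, mode),
                   tolerance = 1e-9)
    }
  }
})

test_that("node permutation permutes nodal metrics and fixes scalars", {
  set.seed(7)
  w <- random_small_graph(7, density = 0.6)
  perm <- sample(7)
  wp <- w[perm, perm]
  expect_equal(node_degree(wp), node_degree(w)[perm])
  expect_equal(local_efficiency(wp), local_efficiency(w)[perm], tolerance = 1e-12)
  expect_equal(betweenness_centrality(wp), betweenness_centrality(w)[perm],
               tolerance = 1e-9)
  expect_equal(global_efficiency(wp), global_efficiency(w), tolerance = 1e-12)
})

test_that("adding a binary edge never decreases global efficiency", {
  set.seed(11)
  for (rep in 1:10) {
    w <- random_small_graph(6, density = 0.4)
    w[w > 0] <- 1
    absent <- which(w == 0 & upper.tri(w), arr.ind = TRUE)
    if (!nrow(absent)) next
    pick <- absent[sample(nrow(absent), 1), ]
    w2 <- w
    w2[pick[1], pick[2]] <- w2[pick[2], pick[1]] <- 1
    expect_gte(global_efficiency(w2, "binary"), global_efficiency(w, "binary") - 1e-12)
  }
})

test_that("leaves have zero betweenness", {
  set.seed(13)
  for (rep in 1:8) {
    w <- random_small_graph(7, density = 0.5)
    deg <- node_degree(w)
    leaves <- which(deg == 1)
    if (length(leaves))
      expect_equal(betweenness_centrality(w, "weighted")[leaves],
                   rep(0, length(leaves)))
  }
})

test_that("metrics table covers all subjects and flags failures by subject", {
  cfg <- simulation_config(n_nodes = 12, n_patients = 3, n_controls = 3,
                           planted_component = cbind(1L, 2:3),
                           deficit_nodes = 4:5, clinical_node = 4, seed = 2)
  co <- simulate_cohort(cfg)
  tbl <- compute_metrics_table(co)
  expect_equal(nrow(tbl$global), 6)
  expect_equal(nrow(tbl$nodal), 6 * 12)
  # identical matrices give identical rows
  co2 <- co
  for (sid in cohort_subjects(co2)) co2$matrices[[sid]] <- co2$matrices[[1]]
  tbl2 <- compute_metrics_table(co2)
  expect_equal(length(unique(tbl2$global$eglob)), 1)
  # single complete graph: eglob 1, mean degree n-1
  k4 <- connectivity_matrix(edges_to_matrix(4, t(combn(4, 2))), subject_id = "s1")
  expect_equal(global_efficiency(k4, "binary"), 1)
  expect_equal(mean_degree(k4), 3)
})
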