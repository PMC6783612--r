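# Independent brute-force oracles used to validate the graph metrics and
# the rank-sum test. Everything here enumerates exhaustively and shares no
# code with the package implementation.

# enumerate all simple paths s -> t over a length matrix (Inf = no edge);
# returns list of list(len=, interior=)
oracle_all_paths <- function(L, s, t) {
  n <- nrow(L)
  res <- list()
  rec <- function(v, visited, len, interior) {
    if (v == t) {
      res[[length(res) + 1]] <<- list(len = len, interior = interior)
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (!visited[u] && is.finite(L[v, u])) {
        visited[u] <- TRUE
        rec(u, visited, len + L[v, u],
            if (u == t) interior else c(interior, u))
        visited[u] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n)
  visited[s] <- TRUE
  rec(s, visited, 0, integer(0))
  res
}

oracle_length_matrix <- function(w, mode) {
  L <- matrix(Inf, nrow(w), ncol(w))
  L[w > 0] <- if (mode == "binary") 1 else 1 / w[w > 0]
  diag(L) <- Inf
  L
}

# all-pairs shortest distances by enumeration
oracle_distances <- function(w, mode = "weighted") {
  n <- nrow(w)
  L <- oracle_length_matrix(w, mode)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- oracle_all_paths(L, s, t)
    if (length(paths)) d[s, t] <- d[t, s] <- min(vapply(paths, `[[`, numeric(1), "len"))
  }
  d
}

oracle_global_efficiency <- function(w, mode = "weighted") {
  n <- nrow(w)
  d <- oracle_distances(w, mode)
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(w, mode = "weighted") {
  n <- nrow(w)
  vapply(seq_len(n), function(v) {
    nb <- which(w[v, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(w[nb, nb, drop = FALSE], mode)
  }, numeric(1))
}

# betweenness by explicit shortest-path counting over unordered pairs
oracle_betweenness <- function(w, mode = "weighted", tol = 1e-9) {
  n <- nrow(w)
  L <- oracle_length_matrix(w, mode)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- oracle_all_paths(L, s, t)
    if (!length(paths)) next
    lens <- vapply(paths, `[[`, numeric(1), "len")
    dmin <- min(lens)
    short <- paths[lens <= dmin + tol]
    sigma <- length(short)
    for (p in short) for (v in p$interior) bc[v] <- bc[v] + 1 / sigma
  }
  bc
}

# random symmetric weighted graph for oracle comparisons
random_small_graph <- function(n, density = 0.6, wmin = 0.2, wmax = 0.9) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  pres <- runif(sum(ut)) < density
  vals <- numeric(sum(ut))
  vals[pres] <- runif(sum(pres), wmin, wmax)
  w[ut] <- vals
  w + t(w)
}

# exhaustive two-sided rank-sum p-value: enumerate all group assignments,
# statistic = rank sum of the first group
oracle_rank_sum_p <- function(x, y) {
  all <- c(x, y)
  n1 <- length(x)
  r <- rank(all)
  obs <- sum(r[seq_len(n1)])
  picks <- combn(length(all), n1)
  stats <- apply(picks, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(all) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

# small helper: symmetric matrix from an edge list with weights
edges_to_matrix <- function(n, edges, weights = 1) {
  w <- matrix(0, n, n)
  weights <- rep_len(weights, nrow(edges))
  for (k in seq_len(nrow(edges))) {
    w[edges[k, 1], edges[k, 2]] <- weights[k]
    w[edges[k, 2], edges[k, 1]] <- weights[k]
  }
  w
}
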