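# Internal helpers: hashing, seed derivation, truncated normals, union-find.

# 32-bit FNV-1a over a character string, done in doubles to avoid integer
# overflow (terms kept < 2^41, well inside exact double range).
fnv1a <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  h
}

# xor of a 32-bit value held in a double with a byte
bitwXor_dbl <- function(h, b) {
  lo <- h %% 2147483648
  hi <- h - lo
  hi + bitwXor(as.integer(lo), as.integer(b))
}

#' Derive a reproducible sub-seed from a master seed and a stream tag
#'
#' Expands one user-facing seed into independent substreams (one per
#' subject, one for topology, one for clinical sampling, ...) by hashing
#' the tag. Subject-level substreams make cohorts extensible: adding a
#' subject never reshuffles the draws of existing subjects.
#'
#' @param seed master integer seed
#' @param tag character stream label
#' @return an integer in [0, 2^31 - 2] suitable for `set.seed()`
#' @keywords internal
derive_seed <- function(seed, tag) {
  as.integer(fnv1a(paste0(format(seed, scientific = FALSE), ":", tag)) %% 2147483647)
}

# Truncated normal draws on (lower, upper) via inverse-CDF; exact and fast.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) {
    return(pmin(pmax(rep(mean, n), lower), upper))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  x <- stats::qnorm(stats::runif(n, plo, phi), mean, sd)
  pmin(pmax(x, lower), upper)
}

# Union-find with path halving; edges is a 2-column integer matrix.
# Returns a list of components, each list(nodes=, edges=<2-col matrix>, extent=).
components_from_edge_list <- function(edges, n_nodes) {
  if (is.null(edges) || nrow(edges) == 0) return(list())
  parent <- seq_len(n_nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(edges[, 1], find, integer(1))
  comps <- split(seq_len(nrow(edges)), roots)
  out <- lapply(comps, function(idx) {
    e <- edges[idx, , drop = FALSE]
    list(nodes = sort(unique(as.vector(e))), edges = e, extent = nrow(e))
  })
  # deterministic order: largest first, ties by smallest node id
  ord <- order(-vapply(out, `[[`, integer(1), "extent"),
               vapply(out, function(c) c$nodes[1], integer(1)))
  unname(out[ord])
}

# Indices of the upper triangle (i < j) as a 2-column matrix, cached per n.
upper_pairs <- function(n) {
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ut[order(ut[, "col"], ut[, "row"]), , drop = FALSE]
}

# Map (i, j) pairs (i < j) to positions in the column-major upper-tri vector.
pair_to_ut_index <- function(i, j, n) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  (hi - 1) * (hi - 2) / 2 + lo
}

`%||%` <- function(a, b) if (is.null(a)) b else a
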