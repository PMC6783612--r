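#' @importFrom igraph graph_from_adjacency_matrix distances betweenness E ecount
NULL

# Build an igraph from a weighted adjacency, returning graph + edge lengths.
# Weighted mode maps FA weight w to edge length 1/w (stronger tracts are
# "shorter"); binary mode gives every edge unit length.
as_length_graph <- function(m, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  g <- igraph::graph_from_adjacency_matrix(as_plain_matrix(m), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- if (igraph::ecount(g) == 0) numeric(0)
         else if (mode == "binary") rep(1, igraph::ecount(g))
         else 1 / igraph::E(g)$weight
  list(graph = g, lengths = len)
}

#' Node degree of a connectivity matrix
#'
#' Degree is the number of edges incident to a node, i.e. the count of
#' strictly positive off-diagonal weights in its row; weights themselves do
#' not enter.
#'
#' @param m a [connectivity_matrix()] or symmetric numeric matrix
#' @return integer vector of length N
#' @export
node_degree <- function(m) {
  as.integer(colSums(unclass(m) > 0))
}

#' Mean nodal degree of one subject's network
#' @inheritParams node_degree
#' @return scalar mean of [node_degree()]
#' @export
mean_degree <- function(m) {
  mean(node_degree(m))
}

#' All-pairs shortest path lengths
#'
#' @inheritParams node_degree
#' @param mode `"weighted"` (Dijkstra over edge lengths 1/w) or `"binary"`
#'   (hop counts)
#' @return N x N matrix of distances; disconnected pairs are `Inf`, the
#'   diagonal is 0
#' @export
shortest_path_lengths <- function(m, mode = c("weighted", "binary")) {
  lg <- as_length_graph(m, mode)
  d <- igraph::distances(lg$graph, weights = lg$lengths, algorithm = "dijkstra")
  dimnames(d) <- NULL
  d
}

#' Global efficiency
#'
#' The average inverse shortest path length over all ordered pairs of
#' distinct nodes, with disconnected pairs contributing 0. On binary graphs
#' this lies in \[0, 1\] and equals 1 for a complete graph.
#'
#' @inheritParams shortest_path_lengths
#' @return scalar efficiency
#' @export
global_efficiency <- function(m, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  n <- nrow(m)
  if (is.null(n) || n < 2) stop("global efficiency requires at least 2 nodes", call. = FALSE)
  global_efficiency_dense(as_plain_matrix(m), mode == "binary")
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced by its
#' neighbors (the node itself excluded). Nodes with fewer than two
#' neighbors get 0.
#'
#' @inheritParams shortest_path_lengths
#' @return numeric vector of length N
#' @export
local_efficiency <- function(m, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  local_efficiency_dense(as_plain_matrix(m), mode == "binary")
}

#' Betweenness centrality
#'
#' Brandes accumulation over unordered source-target pairs s != t != v of
#' the fraction of shortest s-t paths passing through v; each pair counted
#' once, unnormalized. Equal-length ties are shared proportionally via
#' path counting.
#'
#' @inheritParams shortest_path_lengths
#' @return numeric vector of length N
#' @export
betweenness_centrality <- function(m, mode = c("weighted", "binary")) {
  lg <- as_length_graph(m, mode)
  unname(igraph::betweenness(lg$graph, weights = lg$lengths, normalized = FALSE))
}

#' Number of possible directed connections in an N-node network
#'
#' The count of ordered pairs of distinct nodes, n(n-1); for the 164-node
#' Destrieux parcellation this is 26732.
#'
#' @param n_nodes number of nodes (>= 2)
#' @return integer count
#' @export
count_possible_connections <- function(n_nodes) {
  if (n_nodes < 2) stop("need at least 2 nodes", call. = FALSE)
  as.integer(n_nodes) * (as.integer(n_nodes) - 1L)
}

#' Compute the full per-subject metrics table for a cohort
#'
#' @param cohort a `connectome_cohort`
#' @param mode `"weighted"` or `"binary"` (applies to efficiency and
#'   betweenness; degree is always the binary edge count)
#' @param metrics which nodal metrics to compute; `"degree"` is always
#'   included.
#' @param globals compute the per-subject global efficiency scalar
#'   (default TRUE; mean degree is always computed). Skipping it avoids
#'   all-pairs shortest paths when only nodal degree analyses are needed.
#' @return a `metrics_table`: list with `nodal` (one row per subject x
#'   node) and `global` (one row per subject) data frames
#' @export
compute_metrics_table <- function(cohort, mode = c("weighted", "binary"),
                                  metrics = c("degree", "eloc", "bc"),
                                  globals = TRUE) {
  mode <- match.arg(mode)
  metrics <- union("degree", match.arg(metrics, c("degree", "eloc", "bc"),
                                       several.ok = TRUE))
  ids <- cohort_subjects(cohort)
  n <- length(cohort$node_ids)
  nodal <- vector("list", length(ids))
  glob <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    sid <- ids[k]
    m <- cohort$matrices[[sid]]
    row <- tryCatch({
      deg <- node_degree(m)
      out <- data.frame(subject_id = sid, group = unname(cohort$groups[sid]),
                        node = seq_len(n), region = cohort$node_ids,
                        degree = deg, stringsAsFactors = FALSE)
      if ("eloc" %in% metrics) out$eloc <- local_efficiency(m, mode)
      if ("bc" %in% metrics) out$bc <- betweenness_centrality(m, mode)
      out
    }, error = function(e)
      stop(sprintf("metric computation failed for subject %s: %s", sid,
                   conditionMessage(e)), call. = FALSE))
    nodal[[k]] <- row
    glob[[k]] <- data.frame(subject_id = sid, group = unname(cohort$groups[sid]),
                            eglob = if (globals) global_efficiency(m, mode) else NA_real_,
                            mean_degree = mean(row$degree),
                            stringsAsFactors = FALSE)
  }
  structure(list(nodal = do.call(rbind, nodal), global = do.call(rbind, glob),
                 mode = mode, n_nodes = n),
            class = "metrics_table")
}

#' @export
print.metrics_table <- function(x, ...) {
  cat(sprintf("<metrics_table> %d subjects x %d nodes (%s mode); nodal metrics: %s\n",
              nrow(x$global), x$n_nodes, x$mode,
              paste(setdiff(names(x$nodal), c("subject_id", "group", "node", "region")),
                    collapse = ", ")))
  invisible(x)
}

# subject x node matrix of one nodal metric from a metrics_table
nodal_matrix <- function(tbl, metric) {
  if (!metric %in% names(tbl$nodal))
    stop(sprintf("metric %s not present in metrics table", sQuote(metric)), call. = FALSE)
  ids <- unique(tbl$nodal$subject_id)
  out <- matrix(NA_real_, length(ids), tbl$n_nodes,
                dimnames = list(ids, NULL))
  for (sid in ids) {
    rows <- tbl$nodal[tbl$nodal$subject_id == sid, ]
    out[sid, rows$node] <- rows[[metric]]
  }
  out
}
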