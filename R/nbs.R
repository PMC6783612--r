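#' Configuration for the network-based statistic
#'
#' @param edge_stat edge-wise two-sample statistic: `"t"` (pooled-variance
#'   Student t) or `"rank"` (normal-approximation rank-sum z with tie
#'   correction); both oriented control minus patient so positive values
#'   flag FA decreases in patients
#' @param primary_threshold supra-threshold cutoff in statistic units
#'   (default 3.0)
#' @param n_permutations number of group-label permutations (>= 100;
#'   default 5000)
#' @param alpha family-wise error level (default 0.05)
#' @param edge_mask_rule minimum fraction of subjects with a nonzero
#'   weight for an edge to enter testing (default 1: the edge must exist
#'   in every subject, so group FA means are always over the same support)
#' @param alternative `"decrease"` (one-sided, FA lower in patients) or
#'   `"two.sided"`
#' @param seed integer seed for the permutation stream
#' @param method `"montecarlo"` (random permutations) or `"exact"`
#'   (enumerate all group assignments; feasible for small cohorts)
#' @param perm_block permutations processed per vectorized block (memory
#'   knob, does not affect results)
#' @return an `nbs_config`
#' @export
nbs_config <- function(edge_stat = c("t", "rank"),
                       primary_threshold = 3.0,
                       n_permutations = 5000L,
                       alpha = 0.05,
                       edge_mask_rule = 1.0,
                       alternative = c("decrease", "two.sided"),
                       seed = 1L,
                       method = c("montecarlo", "exact"),
                       perm_block = 128L) {
  edge_stat <- match.arg(edge_stat)
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (method == "montecarlo" && n_permutations < 100)
    stop("n_permutations must be >= 100", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (primary_threshold <= 0) stop("primary_threshold must be positive", call. = FALSE)
  if (edge_mask_rule < 0 || edge_mask_rule > 1)
    stop("edge_mask_rule must lie in [0, 1]", call. = FALSE)
  structure(list(edge_stat = edge_stat, primary_threshold = primary_threshold,
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 edge_mask_rule = edge_mask_rule, alternative = alternative,
                 seed = as.integer(seed), method = method,
                 perm_block = as.integer(perm_block)),
            class = "nbs_config")
}

# subjects x upper-tri-edges weight matrix, subjects sorted by id for
# order invariance
cohort_edge_matrix <- function(cohort) {
  ids <- sort(cohort_subjects(cohort))
  n <- length(cohort$node_ids)
  nut <- n * (n - 1) / 2
  E <- t(vapply(ids, function(sid) {
    w <- unclass(cohort$matrices[[sid]])
    w[upper.tri(w)]
  }, numeric(nut)))
  rownames(E) <- ids
  list(E = E, ids = ids, groups = cohort$groups[ids], n_nodes = n)
}

# vectorized pooled-t / rank statistics for a block of group-1 indicator
# columns; returns a (n_indicators x n_edges) matrix, oriented g1 - g2.
block_edge_stats <- function(Em, G, stat = "t") {
  n <- nrow(Em)
  n1 <- sum(G[, 1]); n2 <- n - n1
  if (stat == "rank") {
    R <- apply(Em, 2, rank)  # ties -> average ranks
    S1 <- crossprod(G, R)    # rank sums in group 1
    mu <- n1 * (n + 1) / 2
    tie <- apply(Em, 2, function(col) {
      tt <- table(col); sum(tt^3 - tt)
    })
    sig2 <- outer(rep(1, ncol(G)), n1 * n2 / 12 * ((n + 1) - tie / (n * (n - 1))))
    z <- (S1 - mu) / sqrt(sig2)
    # orient: larger ranks in group 1 => positive
    return(z)
  }
  S1 <- crossprod(G, Em)
  Q1 <- crossprod(G, Em^2)
  Tot <- matrix(colSums(Em), nrow(S1), ncol(S1), byrow = TRUE)
  QTot <- matrix(colSums(Em^2), nrow(S1), ncol(S1), byrow = TRUE)
  S2 <- Tot - S1
  Q2 <- QTot - Q1
  m1 <- S1 / n1; m2 <- S2 / n2
  ss <- pmax(Q1 - S1^2 / n1, 0) + pmax(Q2 - S2^2 / n2, 0)
  sp2 <- ss / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  zero <- se == 0
  if (any(zero)) {
    eq <- zero & (abs(m1 - m2) < 1e-12)
    tt[eq] <- 0
    tt[zero & !eq] <- sign((m1 - m2)[zero & !eq]) * Inf
  }
  tt
}

#' Edge-wise group statistics for NBS
#'
#' Computes the two-sample statistic on every edge passing the mask rule,
#' oriented control minus patient (positive = FA decrease in patients).
#' Edges failing the mask are `NA`; edges with zero pooled variance and
#' equal means are set to 0 and counted in the `zero_variance` attribute.
#'
#' @param cohort a `connectome_cohort`
#' @param edge_stat `"t"` or `"rank"`
#' @param edge_mask_rule minimum fraction of subjects with nonzero weight
#' @return an N x N symmetric matrix of statistics with attribute
#'   `n_masked` (edges tested) and `zero_variance` (count)
#' @export
edge_statistic <- function(cohort, edge_stat = c("t", "rank"),
                           edge_mask_rule = 1.0) {
  edge_stat <- match.arg(edge_stat)
  ce <- cohort_edge_matrix(cohort)
  if (sum(ce$groups == "patient") < 2 || sum(ce$groups == "control") < 2)
    stop("edge statistics require >= 2 subjects per group", call. = FALSE)
  mask <- colMeans(ce$E > 0) >= edge_mask_rule - 1e-12
  g1 <- matrix(as.numeric(ce$groups == "control"), ncol = 1)
  stat_ut <- rep(NA_real_, ncol(ce$E))
  if (any(mask)) {
    s <- block_edge_stats(ce$E[, mask, drop = FALSE], g1, edge_stat)
    stat_ut[mask] <- as.numeric(s)
  }
  n <- ce$n_nodes
  out <- matrix(NA_real_, n, n)
  out[upper.tri(out)] <- stat_ut
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  attr(out, "n_masked") <- sum(mask)
  attr(out, "zero_variance") <- sum(stat_ut == 0 & mask, na.rm = TRUE)
  out
}

#' Connected components of the supra-threshold edge graph
#'
#' @param stat_matrix symmetric matrix of edge statistics (`NA` = untested)
#' @param threshold supra-threshold cutoff; edges with statistic >=
#'   threshold are retained
#' @return list of components, each with `nodes`, `edges` (2-column
#'   matrix), and `extent` (edge count), largest first
#' @export
supra_threshold_components <- function(stat_matrix, threshold) {
  n <- nrow(stat_matrix)
  ut <- upper_pairs(n)
  v <- stat_matrix[upper.tri(stat_matrix)]
  sel <- which(!is.na(v) & v >= threshold)
  components_from_edge_list(ut[sel, , drop = FALSE], n)
}

# max component extent from a logical supra vector over ut edges
max_extent_from_supra <- function(supra_idx, ut, n_nodes) {
  k <- length(supra_idx)
  if (k <= 1) return(k)
  comps <- components_from_edge_list(ut[supra_idx, , drop = FALSE], n_nodes)
  comps[[1]]$extent
}

#' Network-based statistic with permutation FWER inference
#'
#' Tests every masked edge for a group difference, forms connected
#' components of supra-threshold edges, and assesses each component's
#' extent (edge count) against a permutation null built by shuffling the
#' group labels and recording the maximal component extent of each
#' permutation. Component-level family-wise p-values use the
#' (1 + exceedances) / (n_permutations + 1) estimator. For each component
#' significant at `alpha`, per-subject NBS FA sums (sum of the subject's
#' FA over the component's edges) are returned together with a rank-sum
#' group comparison.
#'
#' @param cohort a `connectome_cohort`
#' @param config an [nbs_config()]
#' @return an `nbs_result`: list with `components` (each with nodes,
#'   edges, extent, p_fwer, significant flag), `null_max_extent`,
#'   `stat_matrix`, `n_masked_edges`, `fa_sums` and `fa_sum_test` for the
#'   largest significant component (NULL when none), and the config used
#' @export
nbs_test <- function(cohort, config = nbs_config()) {
  ce <- cohort_edge_matrix(cohort)
  n1 <- sum(ce$groups == "control")
  n2 <- sum(ce$groups == "patient")
  if (n1 < 2 || n2 < 2) stop("NBS requires >= 2 subjects per group", call. = FALSE)
  n <- ce$n_nodes
  nsub <- n1 + n2
  if (config$method == "montecarlo" &&
      choose(nsub, n1) < config$n_permutations)
    stop(sprintf(paste("only %d distinct group assignments exist for %d subjects;",
                       "use method = 'exact' to enumerate them"),
                 choose(nsub, n1), nsub), call. = FALSE)
  mask <- colMeans(ce$E > 0) >= config$edge_mask_rule - 1e-12
  Em <- ce$E[, mask, drop = FALSE]
  ut <- upper_pairs(n)
  ut_masked <- ut[mask, , drop = FALSE]
  one_sided <- config$alternative == "decrease"
  thresholded <- function(s) if (one_sided) s >= config$primary_threshold
                             else abs(s) >= config$primary_threshold
  g_obs <- matrix(as.numeric(ce$groups == "control"), ncol = 1)
  s_obs <- as.numeric(block_edge_stats(Em, g_obs, config$edge_stat))
  supra_obs <- which(thresholded(s_obs))
  comps <- components_from_edge_list(ut_masked[supra_obs, , drop = FALSE], n)

  null_max <- numeric(0)
  if (length(comps)) {
    labels <- as.numeric(ce$groups == "control")
    if (config$method == "exact") {
      picks <- utils::combn(nsub, n1)
      G <- matrix(0, nsub, ncol(picks))
      G[cbind(as.vector(picks), rep(seq_len(ncol(picks)), each = n1))] <- 1
      null_max <- perm_max_extents(Em, G, config, ut_masked, n, thresholded)
      total <- ncol(picks)
      pfun <- function(ext) sum(null_max >= ext) / total
    } else {
      set.seed(derive_seed(config$seed, "nbs-permutations"))
      nperm <- config$n_permutations
      done <- 0
      null_max <- numeric(nperm)
      while (done < nperm) {
        b <- min(config$perm_block, nperm - done)
        G <- vapply(seq_len(b), function(i) sample(labels), numeric(nsub))
        null_max[done + seq_len(b)] <-
          perm_max_extents(Em, G, config, ut_masked, n, thresholded)
        done <- done + b
      }
      pfun <- function(ext) (1 + sum(null_max >= ext)) / (config$n_permutations + 1)
    }
    for (i in seq_along(comps)) {
      comps[[i]]$p_fwer <- pfun(comps[[i]]$extent)
      comps[[i]]$significant <- comps[[i]]$p_fwer <= config$alpha
    }
  }

  fa_sums <- NULL
  fa_sum_test <- NULL
  sig <- Filter(function(c) isTRUE(c$significant), comps)
  if (length(sig)) {
    primary <- sig[[1]]  # components are ordered largest first
    sums <- vapply(ce$ids, function(sid)
      nbs_fa_sum(cohort$matrices[[sid]], primary$edges), numeric(1))
    fa_sums <- data.frame(subject_id = ce$ids, group = unname(ce$groups),
                          nbs_fa_sum = unname(sums), stringsAsFactors = FALSE)
    fa_sum_test <- rank_sum_test(sums[ce$groups == "patient"],
                                 sums[ce$groups == "control"])
  }

  stat_full <- matrix(NA_real_, n, n)
  sv <- rep(NA_real_, nrow(ut))
  sv[mask] <- s_obs
  stat_full[upper.tri(stat_full)] <- sv
  stat_full[lower.tri(stat_full)] <- t(stat_full)[lower.tri(stat_full)]

  structure(list(components = comps, null_max_extent = null_max,
                 stat_matrix = stat_full, n_masked_edges = sum(mask),
                 fa_sums = fa_sums, fa_sum_test = fa_sum_test,
                 config = config),
            class = "nbs_result")
}

perm_max_extents <- function(Em, G, config, ut_masked, n_nodes, thresholded) {
  S <- block_edge_stats(Em, G, config$edge_stat)
  sel <- thresholded(S)
  vapply(seq_len(nrow(S)), function(r)
    max_extent_from_supra(which(sel[r, ]), ut_masked, n_nodes), numeric(1))
}

#' @export
print.nbs_result <- function(x, ...) {
  nsig <- sum(vapply(x$components, function(c) isTRUE(c$significant), logical(1)))
  cat(sprintf("<nbs_result> %d masked edges, %d supra-threshold component(s), %d significant at alpha = %g\n",
              x$n_masked_edges, length(x$components), nsig, x$config$alpha))
  if (length(x$components)) {
    c1 <- x$components[[1]]
    cat(sprintf("  largest: %d nodes, %d edges, p_fwer = %.4g\n",
                length(c1$nodes), c1$extent, c1$p_fwer))
  }
  invisible(x)
}

#' Per-subject FA sum over a component's edges
#'
#' @param m a subject's [connectivity_matrix()]
#' @param edges 2-column matrix of node pairs; a pair absent in the
#'   subject contributes 0
#' @return scalar total FA over the component's edges
#' @export
nbs_fa_sum <- function(m, edges) {
  if (is.null(edges) || nrow(edges) == 0)
    stop("component edge set is empty", call. = FALSE)
  w <- unclass(m)
  if (any(edges < 1) || any(edges > nrow(w)))
    stop("component edges reference nodes outside the matrix", call. = FALSE)
  sum(w[cbind(edges[, 1], edges[, 2])])
}
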