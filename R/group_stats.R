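#' Significance threshold scheme for nodal and clinical testing
#'
#' Encodes the two-tier nodal thresholds — Bonferroni `alpha / n_tests`
#' and the exploratory `1 / n_tests` — plus the fixed correction levels
#' used for clinical correlations: 0.0125 for global metrics and 0.004
#' for the local (nodal) metrics.
#'
#' @param alpha base level (default 0.05)
#' @param n_tests number of tests, typically the node count (default 164)
#' @param global_corr_alpha level for global-metric clinical correlations
#' @param local_corr_alpha level for nodal clinical correlations
#' @return a `threshold_scheme`
#' @export
threshold_scheme <- function(alpha = 0.05, n_tests = 164L,
                             global_corr_alpha = 0.0125,
                             local_corr_alpha = 0.004) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (n_tests < 1) stop("n_tests must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, n_tests = as.integer(n_tests),
                 bonferroni = alpha / n_tests,
                 exploratory = 1 / n_tests,
                 global_corr_alpha = global_corr_alpha,
                 local_corr_alpha = local_corr_alpha),
            class = "threshold_scheme")
}

#' Disease progression rate
#'
#' The monthly progression rate (48 - ALSFRS-R) / disease duration, where
#' ALSFRS-R is the revised ALS Functional Rating Scale (0-48, higher =
#' less disability) and duration is in months.
#'
#' @param alsfrs_r score(s) in \[0, 48\]
#' @param duration_months positive duration(s) in months
#' @return numeric progression rate(s), per month
#' @export
progression_rate <- function(alsfrs_r, duration_months) {
  if (any(!is.na(alsfrs_r) & (alsfrs_r < 0 | alsfrs_r > 48)))
    stop("ALSFRS-R must lie in [0, 48]", call. = FALSE)
  if (any(!is.na(duration_months) & duration_months <= 0))
    stop("disease duration must be positive", call. = FALSE)
  (48 - alsfrs_r) / duration_months
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Unpaired two-sided rank-sum test with exact p-values for small
#' tie-free samples and the tie-corrected normal approximation otherwise.
#'
#' @param x,y numeric samples (each of size >= 2)
#' @return list with `statistic` (Mann-Whitney U for `x`), `p.value`, and
#'   `method`
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample must contain at least 2 values", call. = FALSE)
  if (length(unique(c(x, y))) == 1)
    stop("all values tied across both samples; rank-sum test degenerate",
         call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p.value = wt$p.value, method = wt$method)
}

#' Spearman rank correlation
#'
#' Rank correlation with average-rank tie handling and a two-sided
#' p-value (t approximation, as appropriate for n in the tens).
#'
#' @param x,y paired numeric samples of length >= 4
#' @return list with `rho`, `p.value`, and `n`
#' @export
spearman_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("constant input; Spearman correlation undefined", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}

#' Per-node group comparison with two-tier significance flags
#'
#' For every node and nodal metric, compares patients and controls with
#' the rank-sum test and flags results at the Bonferroni (`alpha / n`)
#' and exploratory (`1 / n`) thresholds of the scheme. Per-node test
#' failures (e.g. fully tied values) are recorded as `NA` rows, never
#' aborting the table.
#'
#' @param tbl a `metrics_table`
#' @param scheme a [threshold_scheme()]
#' @param metrics nodal metrics to test (subset of those in the table)
#' @return data frame: node, region, metric, group means/SDs, p,
#'   sig_bonferroni, sig_exploratory
#' @export
nodal_group_comparison <- function(tbl, scheme = threshold_scheme(n_tests = tbl$n_nodes),
                                   metrics = c("degree", "eloc", "bc")) {
  metrics <- intersect(metrics, names(tbl$nodal))
  if (!length(metrics)) stop("no requested metric present in table", call. = FALSE)
  grp <- tbl$nodal$group
  if (!all(c("patient", "control") %in% unique(grp)))
    stop("nodal comparison requires both groups", call. = FALSE)
  out <- vector("list", length(metrics))
  regions <- tbl$nodal$region[match(seq_len(tbl$n_nodes), tbl$nodal$node)]
  for (j in seq_along(metrics)) {
    met <- metrics[j]
    mat <- nodal_matrix(tbl, met)
    g <- tbl$global$group[match(rownames(mat), tbl$global$subject_id)]
    pm <- colMeans(mat[g == "patient", , drop = FALSE])
    cm <- colMeans(mat[g == "control", , drop = FALSE])
    psd <- apply(mat[g == "patient", , drop = FALSE], 2, stats::sd)
    csd <- apply(mat[g == "control", , drop = FALSE], 2, stats::sd)
    p <- vapply(seq_len(ncol(mat)), function(v) {
      tryCatch(rank_sum_test(mat[g == "patient", v], mat[g == "control", v])$p.value,
               error = function(e) NA_real_)
    }, numeric(1))
    out[[j]] <- data.frame(node = seq_len(tbl$n_nodes), region = regions,
                           metric = met,
                           patient_mean = pm, patient_sd = psd,
                           control_mean = cm, control_sd = csd,
                           p = p,
                           sig_bonferroni = !is.na(p) & p < scheme$bonferroni,
                           sig_exploratory = !is.na(p) & p < scheme$exploratory,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Demographic comparisons between groups
#'
#' Continuous variables are compared with the Kruskal-Wallis test;
#' categorical variables with the chi-squared test (no Yates correction
#' by default).
#'
#' @param data data frame with one row per subject
#' @param group_col name of the group column
#' @param vars variable columns to compare (defaults to all others)
#' @param correct apply Yates continuity correction to 2x2 chi-squared
#'   tables (default FALSE)
#' @return data frame: variable, test, statistic, p
#' @export
demographics_comparison <- function(data, group_col = "group", vars = NULL,
                                    correct = FALSE) {
  if (!group_col %in% names(data)) stop("group column not found", call. = FALSE)
  g <- factor(data[[group_col]])
  if (nlevels(g) < 2) stop("need at least two groups", call. = FALSE)
  if (is.null(vars)) vars <- setdiff(names(data), group_col)
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    if (is.numeric(x)) {
      kt <- stats::kruskal.test(x, g)
      data.frame(variable = v, test = "kruskal-wallis",
                 statistic = unname(kt$statistic), p = kt$p.value,
                 stringsAsFactors = FALSE)
    } else {
      tab <- table(g, x)
      exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(exp_counts == 0))
        stop(sprintf("variable %s has an expected cell count of 0; use an exact test",
                     sQuote(v)), call. = FALSE)
      ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
      data.frame(variable = v, test = "chi-squared",
                 statistic = unname(ct$statistic), p = ct$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
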