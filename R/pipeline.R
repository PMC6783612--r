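#' Default analysis configuration
#'
#' One nested list governs every stage: `simulation` (arguments of
#' [simulation_config()]; ignored when `manifest` is given), `nbs`
#' (arguments of [nbs_config()]), `scheme` (arguments of
#' [threshold_scheme()]; `n_tests` defaults to the node count), `mode`
#' (`"weighted"` or `"binary"`), `nodal_metrics`, and `seed`. A YAML file
#' with the same structure can be passed anywhere a config is accepted.
#'
#' @param seed master seed applied to simulation and NBS substreams
#' @return a nested configuration list
#' @export
default_analysis_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       simulation = list(),
       manifest = NULL, matrix_dir = NULL, labels = NULL,
       nbs = list(n_permutations = 1000L),
       scheme = list(alpha = 0.05),
       mode = "weighted",
       nodal_metrics = c("degree", "eloc", "bc"))
}

resolve_config <- function(config, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_analysis_config()
  for (nm in names(config)) base[[nm]] <- config[[nm]]
  if (!is.null(seed)) base$seed <- as.integer(seed)
  base
}

config_hash <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
  h <- fnv1a(as.character(js))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the complete connectome group analysis
#'
#' Executes every stage on one cohort: cohort acquisition (synthetic
#' simulation, or loading from a manifest), per-subject graph metrics,
#' global and nodal group comparisons at the two-tier thresholds, hub
#' identification and overlap, hub disruption indices with group tests,
#' the network-based statistic, and clinical correlations (progression
#' rate and ALSFRS-R against the degree of every node flagged at the
#' exploratory threshold, plus the global metrics). Every number in the
#' report is recomputable from the configuration and seed, which the
#' report carries.
#'
#' @param config a configuration list (see [default_analysis_config()]) or
#'   the path to a YAML file with the same structure
#' @param seed optional seed override
#' @return an `analysis_report`
#' @export
run_full_analysis <- function(config = default_analysis_config(), seed = NULL) {
  cfg <- resolve_config(config, seed)

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage %s failed: %s", sQuote(name), conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[connectokit] %-12s %6.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    out
  }

  cohort <- stage("cohort", {
    if (!is.null(cfg$manifest)) {
      load_cohort(cfg$manifest, cfg$matrix_dir, cfg$labels)
    } else {
      sim_args <- cfg$simulation
      sim_args$seed <- sim_args$seed %||% cfg$seed
      if (!is.null(sim_args$planted_component) &&
          !is.matrix(sim_args$planted_component))
        sim_args$planted_component <- do.call(rbind, lapply(sim_args$planted_component,
                                                            as.integer))
      simulate_cohort(do.call(simulation_config, sim_args))
    }
  })
  n_nodes <- length(cohort$node_ids)

  tbl <- stage("metrics", compute_metrics_table(cohort, mode = cfg$mode,
                                                metrics = cfg$nodal_metrics))

  scheme_args <- cfg$scheme
  scheme_args$n_tests <- scheme_args$n_tests %||% n_nodes
  scheme <- do.call(threshold_scheme, scheme_args)

  global_cmp <- stage("global", {
    gl <- tbl$global
    per_subj <- list(eglob = gl$eglob, mean_degree = gl$mean_degree)
    for (met in intersect(c("eloc", "bc"), names(tbl$nodal))) {
      mm <- nodal_matrix(tbl, met)
      per_subj[[paste0("mean_", met)]] <-
        rowMeans(mm)[match(gl$subject_id, rownames(mm))]
    }
    do.call(rbind, lapply(names(per_subj), function(nm) {
      v <- per_subj[[nm]]
      pat <- v[gl$group == "patient"]; ctl <- v[gl$group == "control"]
      ts <- tryCatch(rank_sum_test(pat, ctl),
                     error = function(e) list(p.value = NA_real_))
      data.frame(metric = nm,
                 patient_mean = mean(pat), patient_sd = stats::sd(pat),
                 control_mean = mean(ctl), control_sd = stats::sd(ctl),
                 p = ts$p.value, stringsAsFactors = FALSE)
    }))
  })

  nodal_cmp <- stage("nodal", nodal_group_comparison(tbl, scheme,
                                                     metrics = cfg$nodal_metrics))

  hubs <- stage("hubs", {
    hp <- identify_hubs(tbl, "patient")
    hc <- identify_hubs(tbl, "control")
    list(patient = hp, control = hc,
         shared = intersect(hp$hubs, hc$hubs),
         control_only = setdiff(hc$hubs, hp$hubs),
         patient_only = setdiff(hp$hubs, hc$hubs))
  })

  kappa <- stage("kappa", {
    mets <- intersect(c("degree", "eloc", "bc"), names(tbl$nodal))
    stats::setNames(lapply(mets, function(m) cohort_kappa(tbl, m)), mets)
  })

  nbs <- stage("nbs", {
    nbs_args <- cfg$nbs
    nbs_args$seed <- nbs_args$seed %||% derive_seed(cfg$seed, "nbs")
    nbs_test(cohort, do.call(nbs_config, nbs_args))
  })

  clinical <- stage("clinical", {
    cl <- cohort$clinical
    pats <- cohort_subjects(cohort, "patient")
    cl <- cl[match(pats, cl$subject_id), ]
    if (all(is.na(cl$alsfrs_r))) NULL else {
      rate <- progression_rate(cl$alsfrs_r, cl$duration_months)
      deg <- nodal_matrix(tbl, "degree")[pats, , drop = FALSE]
      flagged <- sort(unique(nodal_cmp$node[nodal_cmp$metric == "degree" &
                                            nodal_cmp$sig_exploratory]))
      rows <- list()
      for (v in flagged) {
        for (target in c("progression_rate", "alsfrs_r")) {
          y <- if (target == "progression_rate") rate else cl$alsfrs_r
          sc <- tryCatch(spearman_correlation(deg[, v], y),
                         error = function(e) list(rho = NA_real_, p.value = NA_real_))
          rows[[length(rows) + 1]] <-
            data.frame(scope = "nodal", metric = "degree", node = v,
                       region = cohort$node_ids[v], clinical = target,
                       rho = sc$rho, p = sc$p.value,
                       significant = !is.na(sc$p.value) & sc$p.value < scheme$local_corr_alpha,
                       stringsAsFactors = FALSE)
        }
      }
      gl <- tbl$global[match(pats, tbl$global$subject_id), ]
      for (gm in c("eglob", "mean_degree")) {
        for (target in c("progression_rate", "alsfrs_r")) {
          y <- if (target == "progression_rate") rate else cl$alsfrs_r
          sc <- tryCatch(spearman_correlation(gl[[gm]], y),
                         error = function(e) list(rho = NA_real_, p.value = NA_real_))
          rows[[length(rows) + 1]] <-
            data.frame(scope = "global", metric = gm, node = NA_integer_,
                       region = NA_character_, clinical = target,
                       rho = sc$rho, p = sc$p.value,
                       significant = !is.na(sc$p.value) & sc$p.value < scheme$global_corr_alpha,
                       stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    }
  })

  structure(list(
    provenance = list(package = "connectokit",
                      version = as.character(utils::packageVersion("connectokit")),
                      seed = cfg$seed, config_hash = config_hash(cfg),
                      config = cfg),
    scheme = unclass(scheme),
    global_comparison = global_cmp,
    nodal_comparison = nodal_cmp,
    hubs = hubs,
    kappa = kappa,
    nbs = nbs,
    clinical_correlations = clinical),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(sprintf("  seed %d, config %s\n", x$provenance$seed, x$provenance$config_hash))
  eg <- x$global_comparison[x$global_comparison$metric == "eglob", ]
  cat(sprintf("  Eglob: patients %.4f vs controls %.4f (p = %.4g)\n",
              eg$patient_mean, eg$control_mean, eg$p))
  nd <- x$nodal_comparison[x$nodal_comparison$metric == "degree", ]
  cat(sprintf("  degree nodes flagged: %d bonferroni, %d exploratory\n",
              sum(nd$sig_bonferroni), sum(nd$sig_exploratory)))
  cat(sprintf("  hubs: %d patient / %d control (%d shared)\n",
              length(x$hubs$patient$hubs), length(x$hubs$control$hubs),
              length(x$hubs$shared)))
  for (m in names(x$kappa))
    cat(sprintf("  kappa-%s: patient mean %.3f, group p = %.3g\n", m,
                mean(x$kappa[[m]]$kappa$kappa[x$kappa[[m]]$kappa$group == "patient"]),
                x$kappa[[m]]$test$p.value))
  print(x$nbs)
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits `report.json` (the full report) plus CSV tables
#' (`global_comparison.csv`, `nodal_comparison.csv`, `kappa.csv`,
#' `hubs.csv`, `correlations.csv`, `nbs_components.csv`,
#' `nbs_fa_sums.csv`). Output is deterministic: identical reports produce
#' byte-identical files.
#'
#' @param report an `analysis_report`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ser <- report
  ser$nbs <- list(
    n_masked_edges = report$nbs$n_masked_edges,
    config = unclass(report$nbs$config),
    components = lapply(report$nbs$components, function(c)
      list(nodes = c$nodes, extent = c$extent, p_fwer = c$p_fwer,
           significant = c$significant,
           edges = apply(c$edges, 1, paste, collapse = "-"))),
    fa_sum_p = if (is.null(report$nbs$fa_sum_test)) NULL
               else report$nbs$fa_sum_test$p.value)
  ser$kappa <- lapply(report$kappa, function(k)
    list(kappa = k$kappa, group_p = k$test$p.value,
         control_reference = k$control_reference))
  ser$hubs <- list(patient = unclass(report$hubs$patient),
                   control = unclass(report$hubs$control),
                   shared = report$hubs$shared,
                   control_only = report$hubs$control_only,
                   patient_only = report$hubs$patient_only)
  jsonlite::write_json(ser, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE, pretty = TRUE)
  wcsv <- function(df, f) if (!is.null(df))
    utils::write.csv(df, file.path(dir, f), row.names = FALSE, quote = FALSE)
  wcsv(report$global_comparison, "global_comparison.csv")
  wcsv(report$nodal_comparison, "nodal_comparison.csv")
  wcsv(do.call(rbind, lapply(report$kappa, `[[`, "kappa")), "kappa.csv")
  wcsv(data.frame(group = rep(c("patient", "control"),
                              c(length(report$hubs$patient$hubs),
                                length(report$hubs$control$hubs))),
                  node = c(report$hubs$patient$hubs, report$hubs$control$hubs)),
       "hubs.csv")
  wcsv(report$clinical_correlations, "correlations.csv")
  if (length(report$nbs$components)) {
    comp_df <- do.call(rbind, lapply(seq_along(report$nbs$components), function(i) {
      c <- report$nbs$components[[i]]
      data.frame(component = i, extent = c$extent, n_nodes = length(c$nodes),
                 p_fwer = c$p_fwer, significant = c$significant,
                 nodes = paste(c$nodes, collapse = "|"))
    }))
    wcsv(comp_df, "nbs_components.csv")
  }
  wcsv(report$nbs$fa_sums, "nbs_fa_sums.csv")
  invisible(dir)
}
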