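#' Configuration for synthetic connectome cohorts
#'
#' Defines the study conditions a generated cohort emulates: a patient and
#' a control group of dense FA-weighted 164-node networks, a weakened
#' (low-FA) planted subnetwork, nodal degree deficits, an optional planted
#' hub-disruption slope, and a clinical covariate coupled to a nodal
#' metric.
#'
#' Topology model: each node i carries a connection propensity f_i drawn
#' from a truncated normal with mean `base_density` and SD `degree_spread`
#' (rescaled so mean(f) = `base_density`), and the pair (i, j) is connected
#' with probability min(1, f_i f_j / base_density). Expected nodal degree
#' is therefore f_i (N - 1): mean about `base_density * (N - 1)` (~110 at
#' the defaults) with an across-node SD of about `degree_spread * (N - 1)`
#' (~29 at the defaults), matching dense tractography connectomes whose
#' regions differ widely in connectedness. Setting `degree_spread = 0`
#' recovers a homogeneous Erdős–Rényi graph at `base_density`. The edge
#' skeleton is drawn once per cohort (subjects share anatomy); FA weights
#' are drawn independently per subject from a truncated normal
#' (`fa_mean`, `fa_sd`) on (0, 1).
#'
#' @param n_nodes number of parcellation nodes (default 164)
#' @param n_patients,n_controls group sizes (defaults 25 and 26)
#' @param base_density expected edge density in (0, 1]; default 110/163 so
#'   expected nodal degree is about 110
#' @param degree_spread across-node SD of connection propensity (density
#'   units); default 0.18 gives an expected-degree SD of about 29
#' @param private_edge_rate expected number of subject-private edges per
#'   node (default 10): connections outside the shared cohort skeleton
#'   drawn independently per subject, emulating individual anatomical
#'   variability. They give nodal degree its between-subject variance
#'   (SD about `sqrt(private_edge_rate)`) without entering the
#'   every-subject NBS edge mask. Capped by both the density and the
#'   available non-skeleton pair pool, so degenerate densities (0 or 1)
#'   remain exactly empty or complete.
#' @param fa_mean,fa_sd FA weight distribution (FA units, in (0, 1))
#' @param planted_component integer 2-column matrix of node-pair edges
#'   forming the weakened subnetwork; default a 10-edge star on nodes 1-11
#' @param fa_effect FA reduction applied to planted edges in patients
#' @param deficit_nodes nodes with planted degree deficits (default 6 nodes)
#' @param edge_removal_prob probability of deleting each edge incident to a
#'   deficit node in patients
#' @param kappa_target optional planted hub-disruption slope in \[-1, 1\];
#'   realized as uniform edge deletion (negative) or propensity-matched
#'   edge addition (positive), whose expected degree profile is
#'   (1 + kappa) times baseline
#' @param clinical_rho target Spearman correlation, in (-1, 1), between the
#'   clinical progression rate and the configured nodal metric
#' @param clinical_metric `"degree"` or `"mean_degree"`
#' @param clinical_node node whose metric is coupled to the clinic (used
#'   for `clinical_metric = "degree"`); default the first deficit node
#' @param alsfrs_mean,alsfrs_sd,alsfrs_range marginal distribution of the
#'   ALSFRS-R score (0-48 scale; defaults 39 +/- 6, range 23-47)
#' @param progression_mean,progression_sd,progression_range marginal
#'   distribution of the disease progression rate, (48 - ALSFRS-R) /
#'   duration, per month (defaults 0.9 +/- 0.9, truncated to 0.05-4)
#' @param seed master integer seed; expands into per-subject substreams so
#'   changing the cohort size never reshuffles existing subjects
#' @return a validated `simulation_config`
#' @export
simulation_config <- function(n_nodes = 164L,
                              n_patients = 25L,
                              n_controls = 26L,
                              base_density = 110 / 163,
                              degree_spread = 0.18,
                              private_edge_rate = 10,
                              fa_mean = 0.40,
                              fa_sd = 0.08,
                              planted_component = cbind(1L, 2:11),
                              fa_effect = 0.15,
                              deficit_nodes = 12:17,
                              edge_removal_prob = 0.15,
                              kappa_target = NULL,
                              clinical_rho = -0.54,
                              clinical_metric = c("degree", "mean_degree"),
                              clinical_node = NULL,
                              alsfrs_mean = 39, alsfrs_sd = 6,
                              alsfrs_range = c(23, 47),
                              progression_mean = 0.9, progression_sd = 0.9,
                              progression_range = c(0.05, 4),
                              seed = 1L) {
  clinical_metric <- match.arg(clinical_metric)
  chk_prob <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      stop(sprintf("invalid config: %s must be a probability in [0, 1]", name),
           call. = FALSE)
  }
  if (n_nodes < 2) stop("invalid config: n_nodes must be >= 2", call. = FALSE)
  if (n_patients < 1 || n_controls < 1)
    stop("invalid config: n_patients and n_controls must be >= 1", call. = FALSE)
  chk_prob(base_density, "base_density")
  chk_prob(edge_removal_prob, "edge_removal_prob")
  if (private_edge_rate < 0)
    stop("invalid config: private_edge_rate must be non-negative", call. = FALSE)
  if (fa_mean - 3 * fa_sd <= 0 || fa_mean + 3 * fa_sd >= 1)
    stop("invalid config: fa_mean +/- 3 fa_sd must lie inside (0, 1)", call. = FALSE)
  if (fa_effect < 0 || fa_effect >= 1)
    stop("invalid config: fa_effect must be in [0, 1)", call. = FALSE)
  planted_component <- matrix(as.integer(planted_component), ncol = 2)
  if (nrow(planted_component) > 0) {
    if (any(planted_component < 1) || any(planted_component > n_nodes))
      stop("invalid config: planted_component references node indices out of range",
           call. = FALSE)
    if (any(planted_component[, 1] == planted_component[, 2]))
      stop("invalid config: planted_component contains self-pairs", call. = FALSE)
  }
  deficit_nodes <- as.integer(deficit_nodes)
  if (length(deficit_nodes) && (any(deficit_nodes < 1) || any(deficit_nodes > n_nodes)))
    stop("invalid config: deficit_nodes out of range", call. = FALSE)
  if (!is.null(kappa_target) &&
      (!is.numeric(kappa_target) || abs(kappa_target) > 1))
    stop("invalid config: kappa_target must lie in [-1, 1]", call. = FALSE)
  if (!is.null(clinical_rho) && (clinical_rho <= -1 || clinical_rho >= 1))
    stop("invalid config: clinical_rho must lie in (-1, 1)", call. = FALSE)
  if (is.null(clinical_node))
    clinical_node <- if (length(deficit_nodes)) deficit_nodes[1] else 1L
  structure(list(n_nodes = as.integer(n_nodes),
                 n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 base_density = base_density, degree_spread = degree_spread,
                 private_edge_rate = private_edge_rate,
                 fa_mean = fa_mean, fa_sd = fa_sd,
                 planted_component = planted_component, fa_effect = fa_effect,
                 deficit_nodes = deficit_nodes,
                 edge_removal_prob = edge_removal_prob,
                 kappa_target = kappa_target,
                 clinical_rho = clinical_rho,
                 clinical_metric = clinical_metric,
                 clinical_node = as.integer(clinical_node),
                 alsfrs_mean = alsfrs_mean, alsfrs_sd = alsfrs_sd,
                 alsfrs_range = alsfrs_range,
                 progression_mean = progression_mean,
                 progression_sd = progression_sd,
                 progression_range = progression_range,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' A null-effect variant of a simulation configuration
#'
#' All planted effects are switched off (no FA reduction, no degree
#' deficits, no hub-disruption slope, clinical covariates independent of
#' the network), so patient and control networks are exchangeable draws.
#'
#' @param config a `simulation_config` to start from (defaults used if missing)
#' @param ... overrides passed to [simulation_config()]
#' @return a `simulation_config`
#' @export
null_simulation_config <- function(config = simulation_config(), ...) {
  args <- unclass(config)
  args$fa_effect <- 0
  args$edge_removal_prob <- 0
  args$kappa_target <- NULL
  args$clinical_rho <- 0
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

# -- internal building blocks ------------------------------------------------

# Latent Gaussian-copula correlation calibrated so the *expected sample*
# Spearman at size n over the observed (possibly tied) metric hits the
# target. Two corrections to the large-sample identity r = 2 sin(pi rho/6):
# (1) the normal-theory small-sample mean of the Spearman coefficient,
#     E[r_s] = 6 / (pi (n + 1)) * ((n - 2) asin(r / 2) + asin(r));
# (2) attenuation from ties in the conditioning metric, approximated by
#     the usual tie-correction factor sqrt(1 - sum(t^3 - t) / (n^3 - n)).
copula_r_for_spearman <- function(rho, n, metric_values) {
  if (rho == 0) return(0)
  exp_rs <- function(r) 6 / (pi * (n + 1)) * ((n - 2) * asin(r / 2) + asin(r))
  r0 <- tryCatch(
    stats::uniroot(function(r) exp_rs(r) - rho, c(-0.9999, 0.9999),
                   tol = 1e-10)$root,
    error = function(e) 2 * sin(pi * rho / 6))
  tt <- table(metric_values)
  tie_factor <- sqrt(max(1e-6, 1 - sum(tt^3 - tt) / (n^3 - n)))
  max(-0.9999, min(0.9999, r0 / tie_factor))
}

# expected subject-private edges per node, capped so degenerate densities
# stay exactly empty/complete and the skeleton density stays positive
private_rate_eff <- function(config) {
  n1 <- config$n_nodes - 1
  min(config$private_edge_rate, config$base_density * n1,
      (1 - config$base_density) * n1)
}

# expected density of the shared skeleton (total density minus the
# private-edge contribution)
skeleton_density <- function(config) {
  max(config$base_density - private_rate_eff(config) / (config$n_nodes - 1), 0)
}

# node connection propensities (uses the current RNG stream)
sim_propensities <- function(config) {
  if (config$base_density <= 0) return(rep(0, config$n_nodes))
  if (config$degree_spread <= 0) return(rep(config$base_density, config$n_nodes))
  f <- rtruncnorm(config$n_nodes, config$base_density, config$degree_spread,
                  0.02, 0.999)
  f <- f * config$base_density / mean(f)
  pmin(pmax(f, 0.001), 1)
}

# upper-triangle skeleton pair probabilities from propensities
sim_pair_probs <- function(config, f) {
  n <- config$n_nodes
  target <- skeleton_density(config)
  if (target <= 0) return(rep(0, n * (n - 1) / 2))
  pr <- upper_pairs(n)
  p <- f[pr[, 1]] * f[pr[, 2]] / config$base_density
  p <- pmin(p, 1)
  # clamping at 1 compresses the mean; rescale so the expected skeleton
  # density equals its target by construction
  for (it in 1:3) {
    if (mean(p) <= 0) break
    p <- pmin(p * target / mean(p), 1)
  }
  p
}

# draw one subject's upper-triangle weight vector: truncated-normal FA on
# every skeleton edge plus a sprinkling of subject-private edges outside
# the skeleton (uses the current RNG stream)
sim_subject_weights <- function(skel, config) {
  w <- numeric(length(skel))
  w[skel] <- sim_weights(sum(skel), config)
  r_eff <- private_rate_eff(config)
  pool <- which(!skel)
  if (r_eff > 0 && length(pool)) {
    q <- min(1, config$n_nodes * r_eff / 2 / length(pool))
    add <- pool[stats::runif(length(pool)) < q]
    if (length(add)) w[add] <- sim_weights(length(add), config)
  }
  w
}

# FA weights for present edges (uses current RNG stream)
sim_weights <- function(n, config) {
  rtruncnorm(n, config$fa_mean, config$fa_sd, 1e-4, 1 - 1e-4)
}

ut_to_matrix <- function(v, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m + t(m)
}

#' Generate a single control connectome
#'
#' Draws a network from the configured topology model (see
#' [simulation_config()]) with truncated-normal FA weights on present
#' edges. Uses the current RNG state; callers wanting reproducibility
#' should `set.seed()` first (as [simulate_cohort()] does per subject).
#'
#' @param config a `simulation_config`
#' @param subject_id identifier to attach
#' @return a [connectivity_matrix()]
#' @export
generate_control_connectome <- function(config, subject_id = "control") {
  if (!inherits(config, "simulation_config"))
    stop("config must be a simulation_config", call. = FALSE)
  f <- sim_propensities(config)
  p <- sim_pair_probs(config, f)
  skel <- stats::runif(length(p)) < p
  w <- sim_subject_weights(skel, config)
  connectivity_matrix(ut_to_matrix(w, config$n_nodes),
                      subject_id = subject_id)
}

#' Apply planted patient effects to a baseline connectome
#'
#' Three effects, in order: (1) FA on planted-component edges reduced by
#' `fa_effect` (floored at 0.01 so the edge survives); (2) each edge
#' incident to a deficit node deleted independently with probability
#' `edge_removal_prob`; (3) if `kappa_target` is set, uniform edge
#' deletion with probability -kappa (negative targets) or edge addition
#' with odds kappa p/(1-p) (positive targets), so the expected nodal
#' degree profile is rescaled by (1 + kappa). Uses the current RNG state.
#'
#' @param m baseline [connectivity_matrix()]
#' @param config a `simulation_config`
#' @param pair_probs optional upper-triangle edge probabilities (as
#'   produced inside [simulate_cohort()]); used to calibrate edge addition
#'   for positive `kappa_target`. Defaults to a flat `base_density`.
#' @return a modified [connectivity_matrix()]
#' @export
apply_patient_effects <- function(m, config, pair_probs = NULL) {
  n <- nrow(m)
  if (nrow(config$planted_component) > 0 &&
      any(config$planted_component > n))
    stop("planted edge index out of range for this matrix", call. = FALSE)
  w <- unclass(m)
  ut <- upper.tri(w)
  v <- w[ut]
  # (1) FA reduction on the planted subnetwork
  if (config$fa_effect > 0 && nrow(config$planted_component) > 0) {
    idx <- pair_to_ut_index(config$planted_component[, 1],
                            config$planted_component[, 2], n)
    present <- v[idx] > 0
    v[idx[present]] <- pmax(v[idx[present]] - config$fa_effect, 0.01)
  }
  # (2) degree deficits: delete edges touching deficit nodes
  if (config$edge_removal_prob > 0 && length(config$deficit_nodes)) {
    pr <- upper_pairs(n)
    touch <- which((pr[, 1] %in% config$deficit_nodes |
                    pr[, 2] %in% config$deficit_nodes) & v > 0)
    if (length(touch)) {
      drop <- touch[stats::runif(length(touch)) < config$edge_removal_prob]
      v[drop] <- 0
    }
  }
  # (3) hub-disruption slope: rescale the expected degree profile
  k <- config$kappa_target
  if (!is.null(k) && k != 0) {
    if (k < 0) {
      pres <- which(v > 0)
      drop <- pres[stats::runif(length(pres)) < -k]
      v[drop] <- 0
    } else {
      p <- pair_probs %||% rep(config$base_density, length(v))
      absent <- which(v == 0)
      padd <- pmin(1, k * p[absent] / pmax(1 - p[absent], 1e-9))
      add <- absent[stats::runif(length(absent)) < padd]
      if (length(add)) v[add] <- sim_weights(length(add), config)
    }
  }
  w2 <- ut_to_matrix(v, n)
  connectivity_matrix(w2, node_ids = attr(m, "node_ids"),
                      subject_id = attr(m, "subject_id"))
}

#' Attach clinical covariates coupled to a nodal metric
#'
#' Patients receive an ALSFRS-R score and a disease duration sampled so
#' that the progression rate (48 - ALSFRS-R) / duration has Spearman
#' correlation approximately `clinical_rho` with the configured nodal
#' metric, via a Gaussian copula (latent Pearson r = 2 sin(pi rho / 6)).
#' The rate marginal is a truncated lognormal matched to the configured
#' mean/SD; ALSFRS-R is drawn independently and the duration solved from
#' the two (clamped to 1-120 months). Controls get no clinical scores.
#' Uses the current RNG state.
#'
#' @param cohort a `connectome_cohort` with patient subjects
#' @param config a `simulation_config`
#' @return the cohort with its `clinical` table filled in
#' @export
generate_clinical <- function(cohort, config) {
  pats <- cohort_subjects(cohort, "patient")
  if (!length(pats)) stop("no patient subjects in cohort", call. = FALSE)
  rho <- config$clinical_rho %||% 0
  metric <- vapply(pats, function(sid) {
    m <- cohort$matrices[[sid]]
    if (config$clinical_metric == "degree")
      sum(unclass(m)[config$clinical_node, ] > 0)
    else mean_degree(m)
  }, numeric(1))
  np <- length(pats)
  z_m <- stats::qnorm(rank(metric, ties.method = "average") / (np + 1))
  r <- copula_r_for_spearman(rho, np, metric)
  z2 <- r * z_m + sqrt(max(0, 1 - r^2)) * stats::rnorm(np)
  u2 <- stats::pnorm(z2)
  # truncated lognormal marginal for the progression rate
  cv2 <- (config$progression_sd / config$progression_mean)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(config$progression_mean) - sdlog^2 / 2
  lo <- stats::plnorm(config$progression_range[1], meanlog, sdlog)
  hi <- stats::plnorm(config$progression_range[2], meanlog, sdlog)
  rate <- stats::qlnorm(lo + u2 * (hi - lo), meanlog, sdlog)
  alsfrs <- round(rtruncnorm(np, config$alsfrs_mean, config$alsfrs_sd,
                             config$alsfrs_range[1] - 0.49,
                             config$alsfrs_range[2] + 0.49))
  alsfrs <- pmin(pmax(alsfrs, 0), 47)  # keep 48 - score > 0
  duration <- pmin(pmax((48 - alsfrs) / rate, 1), 120)
  cl <- cohort$clinical
  cl$alsfrs_r[match(pats, cl$subject_id)] <- alsfrs
  cl$duration_months[match(pats, cl$subject_id)] <- duration
  cohort$clinical <- cl
  cohort
}

#' Simulate a full synthetic cohort
#'
#' Draws a shared cohort topology (node propensities and edge skeleton,
#' with planted-component edges always present), independent per-subject
#' FA weights, patient effects per [apply_patient_effects()], and clinical
#' covariates per [generate_clinical()]. All randomness derives from
#' `config$seed` through named substreams, so regeneration is
#' bit-identical and per-subject draws are stable under cohort resizing.
#'
#' @param config a [simulation_config()]
#' @return a `connectome_cohort` with a `truth` record of every planted
#'   effect
#' @export
simulate_cohort <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config"))
    stop("config must be a simulation_config", call. = FALSE)
  set.seed(derive_seed(config$seed, "topology"))
  f <- sim_propensities(config)
  p <- sim_pair_probs(config, f)
  skel <- stats::runif(length(p)) < p
  if (nrow(config$planted_component) > 0) {
    idx <- pair_to_ut_index(config$planted_component[, 1],
                            config$planted_component[, 2], config$n_nodes)
    skel[idx] <- TRUE
  }
  ids <- c(sprintf("patient%02d", seq_len(config$n_patients)),
           sprintf("control%02d", seq_len(config$n_controls)))
  groups <- stats::setNames(rep(c("patient", "control"),
                                c(config$n_patients, config$n_controls)), ids)
  mats <- vector("list", length(ids))
  names(mats) <- ids
  for (sid in ids) {
    set.seed(derive_seed(config$seed, sid))
    w <- sim_subject_weights(skel, config)
    m <- connectivity_matrix(ut_to_matrix(w, config$n_nodes),
                             node_ids = paste0("region_", seq_len(config$n_nodes)),
                             subject_id = sid)
    if (groups[sid] == "patient") m <- apply_patient_effects(m, config, p)
    mats[[sid]] <- m
  }
  clinical <- data.frame(subject_id = ids, alsfrs_r = NA_real_,
                         duration_months = NA_real_, stringsAsFactors = FALSE)
  cohort <- new_cohort(matrices = mats, groups = groups, clinical = clinical,
                       node_ids = paste0("region_", seq_len(config$n_nodes)),
                       truth = list(
                         seed = config$seed,
                         planted_component = config$planted_component,
                         fa_effect = config$fa_effect,
                         deficit_nodes = config$deficit_nodes,
                         edge_removal_prob = config$edge_removal_prob,
                         kappa_target = config$kappa_target,
                         clinical_rho = config$clinical_rho,
                         clinical_node = config$clinical_node,
                         config = config))
  set.seed(derive_seed(config$seed, "clinical"))
  generate_clinical(cohort, config)
}
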