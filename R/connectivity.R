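#' Construct and validate a connectivity matrix
#'
#' A connectivity matrix is one subject's symmetric weighted adjacency
#' matrix over N parcellation nodes. Edge weights are mean fractional
#' anisotropy (FA) of the streamlines connecting two regions; an entry of
#' exactly 0 means "no edge". Validation enforces squareness, symmetry
#' (asymmetries up to `tol` are averaged away, larger ones are an error),
#' a zero diagonal, and non-negative weights.
#'
#' @param weights numeric N x N matrix
#' @param node_ids optional character vector of region labels (length N)
#' @param subject_id optional subject identifier
#' @param tol symmetry tolerance (default 1e-9)
#' @return a `connectivity_matrix` (a numeric matrix with attributes
#'   `subject_id` and `node_ids`)
#' @export
connectivity_matrix <- function(weights, node_ids = NULL, subject_id = NA_character_,
                                tol = 1e-9) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("weights must be a numeric matrix", call. = FALSE)
  n <- nrow(weights)
  if (ncol(weights) != n)
    stop(sprintf("matrix is not square (%d x %d) [subject %s]",
                 n, ncol(weights), subject_id), call. = FALSE)
  if (anyNA(weights) || any(!is.finite(weights)))
    stop(sprintf("non-finite weight entries [subject %s]", subject_id), call. = FALSE)
  asym <- max(abs(weights - t(weights)))
  if (asym > tol)
    stop(sprintf("matrix asymmetric beyond tolerance (max |A - t(A)| = %.3g) [subject %s]",
                 asym, subject_id), call. = FALSE)
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) {
    bad <- which(diag(weights) != 0)[1]
    stop(sprintf("nonzero diagonal entry at node %d [subject %s]", bad, subject_id),
         call. = FALSE)
  }
  if (any(weights < 0)) {
    bad <- which(weights < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative weight at (%d, %d) [subject %s]", bad[1], bad[2], subject_id),
         call. = FALSE)
  }
  if (!is.null(node_ids)) {
    if (length(node_ids) != n)
      stop("node_ids length does not match matrix dimension", call. = FALSE)
    node_ids <- as.character(node_ids)
  }
  structure(weights,
            subject_id = as.character(subject_id),
            node_ids = node_ids,
            class = c("connectivity_matrix", "matrix", "array"))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<connectivity_matrix> subject %s: %d nodes, %d edges, mean FA %.3f\n",
              attr(x, "subject_id"), n, sum(x[upper.tri(x)] > 0),
              mean(x[upper.tri(x)][x[upper.tri(x)] > 0])))
  invisible(x)
}

# strip class/attrs to a plain base matrix (for igraph etc.)
as_plain_matrix <- function(m) {
  matrix(as.numeric(m), nrow(m), ncol(m))
}

#' Read a connectivity matrix from delimited text
#'
#' Matrices are stored as headerless delimited text: N rows of N numeric
#' fields, whitespace- or comma-separated (auto-detected). Node identity
#' lives in a separate label table, never in the matrix file.
#'
#' @param path file path
#' @param node_ids optional region labels to attach
#' @param subject_id subject identifier (defaults to the file stem)
#' @param tol symmetry tolerance
#' @return a [connectivity_matrix()]
#' @export
read_connectivity_matrix <- function(path, node_ids = NULL, subject_id = NULL,
                                     tol = 1e-9) {
  if (!file.exists(path)) stop(sprintf("matrix file not found: %s", path), call. = FALSE)
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sep <- if (grepl(",", lines[1], fixed = TRUE)) "," else ""
  rows <- lapply(lines, function(l) {
    f <- if (sep == ",") strsplit(trimws(l), ",")[[1]] else strsplit(trimws(l), "[[:space:]]+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) stop(sprintf("non-numeric field in %s", path), call. = FALSE)
    v
  })
  nfield <- lengths(rows)
  if (length(unique(nfield)) != 1 || nfield[1] != length(rows))
    stop(sprintf("file %s is not a square numeric matrix (%d rows, %s fields)",
                 path, length(rows), paste(unique(nfield), collapse = "/")), call. = FALSE)
  m <- do.call(rbind, rows)
  tryCatch(
    connectivity_matrix(m, node_ids = node_ids, subject_id = subject_id, tol = tol),
    error = function(e) stop(sprintf("%s [file %s]", conditionMessage(e), path), call. = FALSE)
  )
}

#' Write a connectivity matrix as delimited text at full precision
#'
#' @param m a [connectivity_matrix()] or numeric matrix
#' @param path output file
#' @return `path`, invisibly
#' @export
write_connectivity_matrix <- function(m, path) {
  txt <- apply(unclass(m), 1, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  writeLines(txt, path)
  invisible(path)
}

#' Load a cohort from a manifest and a directory of matrix files
#'
#' The manifest is a CSV with header
#' `subject_id,group,alsfrs_r,duration_months`; `group` must be `patient`
#' or `control`; clinical fields may be empty (controls carry none). Each
#' `subject_id` must correspond to `<matrix_dir>/<subject_id>.txt`.
#'
#' @param manifest_path manifest CSV path
#' @param matrix_dir directory holding one matrix file per subject
#' @param labels_path optional node-label CSV with header `index,region_name`
#' @return a `connectome_cohort`
#' @export
load_cohort <- function(manifest_path, matrix_dir, labels_path = NULL) {
  if (!file.exists(manifest_path))
    stop(sprintf("manifest not found: %s", manifest_path), call. = FALSE)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  req <- c("subject_id", "group")
  if (!all(req %in% names(man)))
    stop("manifest must contain columns subject_id and group", call. = FALSE)
  bad <- setdiff(unique(man$group), c("patient", "control"))
  if (length(bad))
    stop(sprintf("unknown group label(s) %s; allowed labels: patient, control",
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  node_ids <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    node_ids <- lab$region_name[order(lab$index)]
  }
  mats <- list()
  for (k in seq_len(nrow(man))) {
    sid <- man$subject_id[k]
    f <- file.path(matrix_dir, paste0(sid, ".txt"))
    if (!file.exists(f))
      stop(sprintf("matrix file missing for subject %s: %s", sid, f), call. = FALSE)
    mats[[sid]] <- read_connectivity_matrix(f, node_ids = node_ids, subject_id = sid)
  }
  ns <- vapply(mats, nrow, integer(1))
  if (length(unique(ns)) > 1) {
    tab <- split(names(ns), ns)
    stop(sprintf("inconsistent node counts across subjects: %s",
                 paste(vapply(names(tab), function(n) sprintf("%s nodes: %s", n,
                   paste(tab[[n]], collapse = ",")), character(1)), collapse = "; ")),
         call. = FALSE)
  }
  clinical <- data.frame(subject_id = man$subject_id,
                         alsfrs_r = if ("alsfrs_r" %in% names(man)) as.numeric(man$alsfrs_r) else NA_real_,
                         duration_months = if ("duration_months" %in% names(man)) as.numeric(man$duration_months) else NA_real_,
                         stringsAsFactors = FALSE)
  ok <- is.na(clinical$alsfrs_r) | (clinical$alsfrs_r >= 0 & clinical$alsfrs_r <= 48)
  if (!all(ok))
    stop(sprintf("ALSFRS-R outside [0, 48] for subject(s): %s",
                 paste(clinical$subject_id[!ok], collapse = ", ")), call. = FALSE)
  ok <- is.na(clinical$duration_months) | clinical$duration_months > 0
  if (!all(ok))
    stop(sprintf("non-positive disease duration for subject(s): %s",
                 paste(clinical$subject_id[!ok], collapse = ", ")), call. = FALSE)
  new_cohort(matrices = mats,
             groups = stats::setNames(man$group, man$subject_id),
             clinical = clinical,
             node_ids = node_ids %||% paste0("region_", seq_len(ns[1])))
}

new_cohort <- function(matrices, groups, clinical, node_ids, truth = NULL) {
  grp_n <- table(factor(groups, levels = c("patient", "control")))
  structure(list(matrices = matrices, groups = groups, clinical = clinical,
                 node_ids = node_ids, truth = truth,
                 n_patients = unname(grp_n["patient"]),
                 n_controls = unname(grp_n["control"])),
            class = "connectome_cohort")
}

#' @export
print.connectome_cohort <- function(x, ...) {
  cat(sprintf("<connectome_cohort> %d patients, %d controls, %d nodes%s\n",
              x$n_patients, x$n_controls, length(x$node_ids),
              if (!is.null(x$truth)) " (synthetic, truth attached)" else ""))
  invisible(x)
}

#' Subject ids of a cohort, optionally restricted to one group
#' @param cohort a `connectome_cohort`
#' @param group optional `"patient"` or `"control"`
#' @return character vector of subject ids
#' @export
cohort_subjects <- function(cohort, group = NULL) {
  ids <- names(cohort$matrices)
  if (is.null(group)) ids else ids[cohort$groups[ids] == group]
}

#' Write a cohort to disk (matrices, manifest, labels, truth record)
#'
#' Produces `<dir>/matrices/<subject_id>.txt` (delimited text),
#' `<dir>/manifest.csv`, `<dir>/node_labels.csv`, and, for synthetic
#' cohorts, `<dir>/truth.json` recording every planted effect and the seed.
#'
#' @param cohort a `connectome_cohort`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  mdir <- file.path(dir, "matrices")
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(cohort$matrices))
    write_connectivity_matrix(cohort$matrices[[sid]], file.path(mdir, paste0(sid, ".txt")))
  ids <- names(cohort$matrices)
  man <- data.frame(subject_id = ids,
                    group = unname(cohort$groups[ids]),
                    alsfrs_r = cohort$clinical$alsfrs_r[match(ids, cohort$clinical$subject_id)],
                    duration_months = cohort$clinical$duration_months[match(ids, cohort$clinical$subject_id)])
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(index = seq_along(cohort$node_ids) - 1L,
                              region_name = cohort$node_ids),
                   file.path(dir, "node_labels.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    tr$config <- unclass(tr$config)
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}
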