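# Plain-text I/O: dense matrices as header-less CSV (6-decimal fixed
# point), edge lists as TSV with 0-based node indices, manifests and
# results as JSON. All readers validate and report the offending line.

#' Write a numeric matrix as CSV
#'
#' Header-less comma-separated values, 6-decimal fixed point.
#'
#' @param m numeric matrix.
#' @param path output file.
#' @export
write_matrix_csv <- function(m, path) {
  if (any(!is.finite(m))) stop_mfnet("refusing to write non-finite values")
  lines <- apply(m, 1, function(r) paste(sprintf("%.6f", r),
                                         collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a numeric matrix from CSV
#'
#' @param path input file (header-less CSV).
#' @param symmetric require symmetry (default TRUE).
#' @return Numeric matrix.
#' @export
read_matrix_csv <- function(path, symmetric = TRUE) {
  if (!file.exists(path)) stop_mfnet("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- strsplit(lines, ",", fixed = TRUE)
  width <- length(rows[[1]])
  m <- matrix(NA_real_, length(rows), width)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != width)
      stop_mfnet(path, ":", i, ": expected ", width, " fields, got ",
                 length(rows[[i]]))
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (any(is.na(v))) {
      j <- which(is.na(v))[1]
      stop_mfnet(path, ":", i, ": non-numeric or missing value in field ",
                 j, " ('", rows[[i]][j], "')")
    }
    m[i, ] <- v
  }
  if (symmetric) check_square_symmetric(m, paste0("matrix in ", path),
                                        tol = 1e-5)
  m
}

#' Convert a binary adjacency matrix to an edge list
#'
#' @param A symmetric matrix (binary or weighted).
#' @return data.frame `i`, `j` (0-based, i < j), `weight`.
#' @export
adjacency_to_edgelist <- function(A) {
  check_square_symmetric(A, "adjacency matrix")
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L, weight = A[idx])
}

#' Convert an edge list back to an adjacency matrix
#'
#' @param edges data.frame with 0-based `i`, `j`, `weight`.
#' @param n node count.
#' @return Symmetric n x n matrix.
#' @export
edgelist_to_adjacency <- function(edges, n) {
  A <- matrix(0, n, n)
  if (nrow(edges)) {
    ii <- edges$i + 1L
    jj <- edges$j + 1L
    if (any(ii < 1 | ii > n | jj < 1 | jj > n))
      stop_mfnet("edge endpoints outside 0..", n - 1)
    A[cbind(ii, jj)] <- edges$weight
    A[cbind(jj, ii)] <- edges$weight
  }
  A
}

#' Write a cohort to disk
#'
#' Writes one CSV matrix per subject and band under `dir/` plus a JSON
#' manifest (`manifest.json`) listing subjects, group labels, scores and
#' relative matrix paths.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if absent).
#' @return Path to the manifest.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "cohort")) stop_mfnet("expected a cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- list()
  for (i in seq_len(nrow(cohort$subjects))) {
    id <- cohort$subjects$id[i]
    bc <- cohort$connectomes[[id]]
    files <- list()
    for (b in bc$bands) {
      rel <- file.path(id, paste0(b, ".csv"))
      dir.create(file.path(dir, id), showWarnings = FALSE)
      write_matrix_csv(bc$matrices[[b]], file.path(dir, rel))
      files[[b]] <- rel
    }
    subjects[[i]] <- list(
      id = id, group = cohort$subjects$group[i],
      MMSE = cohort$subjects$MMSE[i], FR = cohort$subjects$FR[i],
      TR = cohort$subjects$TR[i], matrices = files)
  }
  manifest <- list(n_nodes = cohort$spec$n_nodes,
                   bands = cohort$connectomes[[1]]$bands,
                   subjects = subjects)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a cohort from a manifest
#'
#' @param manifest path to a `manifest.json` written by [write_cohort()]
#'   (matrix paths are resolved relative to its directory).
#' @return A `cohort` (its `spec` field is NULL: the manifest does not
#'   record generator parameters).
#' @export
read_cohort <- function(manifest) {
  mf <- jsonlite::read_json(manifest)
  base <- dirname(manifest)
  subs <- mf$subjects
  ids <- vapply(subs, function(s) s$id, character(1))
  getnum <- function(s, f) {
    v <- s[[f]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  subjects <- data.frame(
    id = ids,
    group = vapply(subs, function(s) s$group, character(1)),
    MMSE = vapply(subs, getnum, numeric(1), "MMSE"),
    FR = vapply(subs, getnum, numeric(1), "FR"),
    TR = vapply(subs, getnum, numeric(1), "TR"),
    stringsAsFactors = FALSE)
  connectomes <- lapply(subs, function(s) {
    mats <- lapply(s$matrices, function(rel)
      read_matrix_csv(file.path(base, rel)))
    band_connectome(mats)
  })
  names(connectomes) <- ids
  structure(list(subjects = subjects, connectomes = connectomes,
                 spec = NULL), class = "cohort")
}

#' Write a per-node metric table as TSV
#'
#' @param tab data.frame (e.g. from [node_metric_table()]).
#' @param path output file.
#' @export
write_metrics_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a results list as JSON
#'
#' @param x list of results (numbers, vectors, data.frames).
#' @param path output file.
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
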