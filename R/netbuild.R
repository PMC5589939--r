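# Network construction: fixed-mean-degree thresholding, multiplex assembly,
# flattening. All graphs are undirected, binary, zero-diagonal.

#' Threshold a weighted matrix to a fixed mean degree
#'
#' Retains the `L = round(k * n / 2)` strongest edges (round-half-up) of a
#' symmetric nonnegative weighted matrix and binarizes, so every network in
#' a study has the same number of links regardless of its weight
#' distribution. The resulting edge density is `2L / (n (n - 1))`.
#' Tie-breaking at the weight boundary is deterministic: edges are sorted
#' by weight descending, then by row index ascending, then column index
#' ascending, guaranteeing exactly L edges and reproducibility.
#'
#' @param W symmetric numeric matrix with zero diagonal and nonnegative
#'   weights (negative entries are rejected, not ranked by magnitude).
#' @param k target average node degree; must give
#'   `1 <= round(k*n/2) <= n(n-1)/2`.
#' @return Binary symmetric adjacency matrix with exactly L edges.
#' @examples
#' W <- matrix(runif(16), 4); W <- (W + t(W)) / 2; diag(W) <- 0
#' A <- threshold_to_mean_degree(W, k = 2)
#' sum(A) / 2  # round(2*4/2) = 4 edges
#' @export
threshold_to_mean_degree <- function(W, k) {
  check_square_symmetric(W, "weighted matrix")
  if (any(W < 0))
    stop_mfnet("weighted matrix has negative entries; expected nonnegative ",
               "connectivity weights")
  n <- nrow(W)
  max_edges <- n * (n - 1) / 2
  L <- round_half_up(k * n / 2)
  if (L < 1 || L > max_edges)
    stop_mfnet("k = ", k, " gives ", L, " edges; need between 1 and ",
               max_edges, " for n = ", n)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[ut]
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ut[ord[seq_len(L)], , drop = FALSE]
  A <- matrix(0, n, n)
  A[keep] <- 1
  A <- A + t(A)
  dimnames(A) <- dimnames(W)
  A
}

#' Edge density of a binary network
#'
#' @param A binary symmetric adjacency matrix.
#' @return Fraction of possible edges present, `2 E / (n (n - 1))`.
#' @export
edge_density <- function(A) {
  check_adjacency(A)
  n <- nrow(A)
  sum(A) / (n * (n - 1))
}

#' Assemble band layers into a multiplex network
#'
#' A multiplex network holds M >= 2 binary adjacency layers over the same
#' node set; each node is implicitly coupled to its own replicas in every
#' other layer (identity inter-layer coupling, which is therefore not
#' stored). Layer order is preserved as given (band order delta..gamma for
#' the default scheme).
#'
#' @param layers named list of binary adjacency matrices.
#' @return Object of class `multiplex` with fields `layers`, `n_nodes`,
#'   `n_layers`.
#' @export
build_multiplex <- function(layers) {
  if (length(layers) < 2)
    stop_mfnet("a multiplex needs at least 2 layers, got ", length(layers))
  if (is.null(names(layers)))
    names(layers) <- paste0("layer", seq_along(layers))
  n <- nrow(layers[[1]])
  bad <- character()
  for (nm in names(layers)) {
    check_adjacency(layers[[nm]], paste0("layer '", nm, "'"))
    if (nrow(layers[[nm]]) != n) bad <- c(bad, nm)
  }
  if (length(bad))
    stop_mfnet("layers with mismatched node counts: ",
               paste(bad, collapse = ", "), " (expected ", n, " nodes)")
  structure(list(layers = layers, n_nodes = n, n_layers = length(layers)),
            class = "multiplex")
}

#' @export
print.multiplex <- function(x, ...) {
  cat("<multiplex>", x$n_layers, "layers x", x$n_nodes, "nodes:",
      paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Flatten a multiplex into an overlapping network
#'
#' The overlapping network's integer edge weight counts in how many layers
#' each node pair is connected: `o_ij = sum_lambda a_ij^[lambda]`.
#'
#' @param mx a `multiplex` from [build_multiplex()].
#' @return Symmetric integer matrix with entries in 0..M.
#' @export
flatten_overlapping <- function(mx) {
  if (!inherits(mx, "multiplex")) stop_mfnet("expected a multiplex")
  Reduce(`+`, mx$layers)
}

#' Flatten a multiplex into an aggregated network
#'
#' Binary union across layers: an edge exists if the node pair is connected
#' in at least one layer. Flattened networks do not preserve the connection
#' density of the individual layers.
#'
#' @param mx a `multiplex` from [build_multiplex()].
#' @return Binary symmetric adjacency matrix.
#' @export
flatten_aggregated <- function(mx) {
  (flatten_overlapping(mx) > 0) * 1
}
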