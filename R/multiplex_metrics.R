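# Multiplex statistics: node-degree layer proportion (NLP), the
# multi-participation coefficient (MPC), and the across-layer degree
# coefficient of variation (CV).

layer_degree_matrix <- function(mx) {
  if (!inherits(mx, "multiplex")) stop_mfnet("expected a multiplex")
  vapply(mx$layers, rowSums, numeric(mx$n_nodes))  # n x M
}

#' Node-degree layer proportion
#'
#' `NLP_i^[lambda] = k_i^[lambda] / o_i`, the fraction of node i's total
#' cross-layer (overlapping) degree `o_i = sum_lambda k_i^[lambda]` that
#' falls in layer lambda. Rows sum to 1 for every connected node; nodes
#' disconnected in all layers get an all-zero row. If connectivity were
#' equally distributed across the M layers every entry would be 1/M.
#'
#' @param mx a `multiplex` from [build_multiplex()].
#' @return n x M numeric matrix (rows nodes, columns layers).
#' @export
node_degree_layer_proportion <- function(mx) {
  k <- layer_degree_matrix(mx)
  o <- rowSums(k)
  nlp <- k / ifelse(o > 0, o, 1)
  nlp[o == 0, ] <- 0
  nlp
}

#' Multi-participation coefficient
#'
#' Measures how evenly a node's connectivity is distributed across the M
#' layers of the multiplex:
#' `MPC_i = M/(M-1) * (1 - sum_lambda (NLP_i^[lambda])^2)`.
#' MPC_i = 1 when the node has equal degree in every layer (a perfect
#' inter-frequency hub) and 0 when its connectivity is confined to a single
#' layer. Nodes disconnected in every layer are assigned MPC_i = 0 to avoid
#' an indeterminate 0/0. The global MPC averages MPC_i over all n nodes
#' (disconnected ones included).
#'
#' @param mx a `multiplex` from [build_multiplex()] with M >= 2 layers.
#' @return List with `mpc` (per-node vector) and `global` (mean over all
#'   nodes).
#' @export
multi_participation_coefficient <- function(mx) {
  if (!inherits(mx, "multiplex")) stop_mfnet("expected a multiplex")
  M <- mx$n_layers
  if (M < 2) stop_mfnet("MPC needs M >= 2 layers (normalization undefined)")
  nlp <- node_degree_layer_proportion(mx)
  o <- rowSums(layer_degree_matrix(mx))
  mpc <- M / (M - 1) * (1 - rowSums(nlp^2))
  mpc[o == 0] <- 0
  mpc <- pmin(pmax(mpc, 0), 1)
  list(mpc = as.numeric(mpc), global = mean(mpc))
}

#' Across-layer degree coefficient of variation
#'
#' `CV_i = sd(k_i^[1..M]) / mean(k_i^[1..M])`, the dispersion of node i's
#' degree across layers. Uses the population standard deviation
#' (divide-by-M) by default; set `sample_sd = TRUE` for the divide-by-(M-1)
#' convention. Fully disconnected nodes get CV_i = 0. High CV marks
#' connectivity concentrated in few layers, so CV and MPC rank nodes in
#' opposite order.
#'
#' @param mx a `multiplex` from [build_multiplex()] with M >= 2 layers.
#' @param sample_sd use the sample (M-1 denominator) standard deviation
#'   instead of the population one (default FALSE).
#' @return List with `cv` (per-node vector) and `global` (mean over nodes).
#' @export
layer_degree_cv <- function(mx, sample_sd = FALSE) {
  if (!inherits(mx, "multiplex")) stop_mfnet("expected a multiplex")
  M <- mx$n_layers
  if (M < 2) stop_mfnet("CV needs M >= 2 layers")
  k <- layer_degree_matrix(mx)
  mu <- rowMeans(k)
  ss <- rowSums((k - mu)^2)
  s <- sqrt(ss / if (sample_sd) (M - 1) else M)
  cv <- ifelse(mu > 0, s / mu, 0)
  list(cv = as.numeric(cv), global = mean(cv))
}

#' Per-node multiplex metric table
#'
#' Convenience wrapper collecting overlapping degree, NLP per layer, MPC
#' and CV into one data.frame plus global summaries.
#'
#' @param mx a `multiplex`.
#' @return List with `table` (data.frame: node, o, NLP columns, MPC, CV)
#'   and `global` (named vector: MPC, CV).
#' @export
node_metric_table <- function(mx) {
  k <- layer_degree_matrix(mx)
  nlp <- node_degree_layer_proportion(mx)
  colnames(nlp) <- paste0("NLP_", names(mx$layers))
  mpc <- multi_participation_coefficient(mx)
  cv <- layer_degree_cv(mx)
  tab <- data.frame(node = seq_len(mx$n_nodes) - 1L, o = rowSums(k),
                    nlp, MPC = mpc$mpc, CV = cv$cv)
  list(table = tab, global = c(MPC = mpc$global, CV = cv$global))
}
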