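# Internal validation helpers shared across modules.

stop_mfnet <- function(...) stop(..., call. = FALSE)

check_square_symmetric <- function(W, name = "matrix", tol = 1e-8) {
  if (!is.matrix(W) || !is.numeric(W))
    stop_mfnet(name, " must be a numeric matrix")
  if (nrow(W) != ncol(W))
    stop_mfnet(name, " must be square, got ", nrow(W), "x", ncol(W))
  if (any(!is.finite(W)))
    stop_mfnet(name, " contains non-finite values")
  if (max(abs(W - t(W))) > tol)
    stop_mfnet(name, " must be symmetric (max asymmetry ",
               signif(max(abs(W - t(W))), 3), ")")
  invisible(TRUE)
}

check_adjacency <- function(A, name = "adjacency matrix") {
  check_square_symmetric(A, name)
  if (!all(A %in% c(0, 1)))
    stop_mfnet(name, " must be binary (entries in {0,1})")
  if (any(diag(A) != 0))
    stop_mfnet(name, " must have a zero diagonal")
  invisible(TRUE)
}

# Round-half-up: round(2.5) in R is 2 (banker's rounding); edge counts use
# the arithmetic convention so k*n/2 with .5 fractions rounds upward.
round_half_up <- function(x) floor(x + 0.5)

#' Derive a per-subject random seed from a cohort seed
#'
#' Splitting rule: `(seed * 48271 + index) mod (2^31 - 1)`, i.e. one step of
#' a Lehmer multiplicative congruential generator offset by the subject
#' index. Keeps every derived seed a valid 32-bit integer and makes cohorts
#' reproducible element-wise: subject `i` of cohort `seed` always receives
#' the same draws regardless of how many subjects precede it.
#'
#' @param seed integer cohort-level seed.
#' @param index integer subject index (1-based).
#' @return A single integer seed.
#' @export
split_seed <- function(seed, index) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + as.numeric(index)) %% m)
}
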