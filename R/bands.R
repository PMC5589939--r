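#' Canonical MEG frequency band scheme
#'
#' Returns the ordered band definitions used throughout the package: delta
#' (2-4 Hz), theta (4.5-7.5 Hz), alpha1 (8-10.5 Hz), alpha2 (11-13 Hz),
#' beta1 (13.5-20 Hz), beta2 (20.5-29.5 Hz) and gamma (30-45 Hz). All band
#' edges fall on a 0.5 Hz grid, so with the default Welch settings
#' (fs = 1000 Hz, nfft = 2000) every edge coincides with a frequency bin.
#'
#' @param bands optional data.frame with columns `name`, `f_low`, `f_high`
#'   to use instead of the default scheme; validated for ordering.
#' @return A data.frame with columns `name`, `f_low`, `f_high` (Hz).
#' @export
band_scheme <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- data.frame(
      name   = c("delta", "theta", "alpha1", "alpha2", "beta1", "beta2",
                 "gamma"),
      f_low  = c(2, 4.5, 8, 11, 13.5, 20.5, 30),
      f_high = c(4, 7.5, 10.5, 13, 20, 29.5, 45),
      stringsAsFactors = FALSE
    )
  }
  if (!all(c("name", "f_low", "f_high") %in% names(bands)))
    stop_mfnet("band scheme needs columns name, f_low, f_high")
  if (any(bands$f_low >= bands$f_high))
    stop_mfnet("each band must satisfy f_low < f_high")
  if (nrow(bands) > 1) {
    if (any(diff(bands$f_low) <= 0) ||
        any(bands$f_low[-1] < bands$f_high[-nrow(bands)]))
      stop_mfnet("bands must be non-overlapping and increasing")
  }
  bands
}

#' Construct a band connectome
#'
#' A band connectome is one symmetric weighted matrix per frequency band,
#' all over the same node set and with zero diagonals.
#'
#' @param matrices named list of symmetric numeric matrices (one per band,
#'   in band order).
#' @param validate check symmetry/diagonal invariants (default TRUE).
#' @return An object of class `band_connectome`.
#' @export
band_connectome <- function(matrices, validate = TRUE) {
  if (!length(matrices)) stop_mfnet("band connectome needs at least one band")
  if (is.null(names(matrices)) || any(!nzchar(names(matrices))))
    stop_mfnet("band matrices must be named by band")
  n <- nrow(matrices[[1]])
  if (validate) {
    for (b in names(matrices)) {
      check_square_symmetric(matrices[[b]], paste0("band '", b, "'"))
      if (nrow(matrices[[b]]) != n)
        stop_mfnet("band '", b, "' has ", nrow(matrices[[b]]),
                   " nodes, expected ", n)
      if (any(diag(matrices[[b]]) != 0))
        stop_mfnet("band '", b, "' must have a zero diagonal")
    }
  }
  structure(list(matrices = matrices, n_nodes = n,
                 bands = names(matrices)),
            class = "band_connectome")
}

#' @export
print.band_connectome <- function(x, ...) {
  cat("<band_connectome>", length(x$matrices), "bands x", x$n_nodes,
      "nodes:", paste(x$bands, collapse = ", "), "\n")
  invisible(x)
}
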