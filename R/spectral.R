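# Spectral estimation: Welch PSD, cross-spectra, (imaginary) coherence,
# band averaging. Signals are plain numeric matrices, samples x ROIs, with
# an explicit sampling rate; nothing here assumes a particular recording
# modality beyond stationarity within an epoch.

# Shared Welch segmentation: mean-detrended, Hann-tapered, zero-padded
# segment FFTs. Returns one-sided bins and the complex segment spectra as
# an array (n_bins x n_segments x n_rois).
welch_segments <- function(x, fs, window_s = 2, overlap_frac = 0.25,
                           nfft = 2000) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (any(!is.finite(x))) stop_mfnet("signals contain non-finite values")
  if (fs <= 0) stop_mfnet("sampling rate must be positive")
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop_mfnet("overlap_frac must be in [0,1)")
  nsamp <- nrow(x)
  L <- round_half_up(window_s * fs)
  if (L < 2) stop_mfnet("window too short: ", L, " samples")
  if (nsamp < L)
    stop_mfnet("signal has ", nsamp, " samples but one ", window_s,
               "-second window needs at least ", L)
  if (nfft < L)
    stop_mfnet("nfft (", nfft, ") must be >= window length (", L, ")")
  step <- max(1L, floor(L * (1 - overlap_frac)))
  starts <- seq.int(1L, nsamp - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))  # Hann taper
  n_bins <- floor(nfft / 2) + 1L
  n_rois <- ncol(x)
  out <- array(complex(real = 0), dim = c(n_bins, length(starts), n_rois))
  pad <- matrix(0, nfft, n_rois)
  for (s in seq_along(starts)) {
    seg <- x[starts[s]:(starts[s] + L - 1L), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))  # per-segment detrend (mean only)
    pad[seq_len(L), ] <- seg * w
    pad[-seq_len(L), ] <- 0
    out[, s, ] <- stats::mvfft(pad)[seq_len(n_bins), ]
  }
  list(freq = (seq_len(n_bins) - 1L) * fs / nfft, spectra = out,
       window = w, n_segments = length(starts), fs = fs, nfft = nfft)
}

#' Welch power spectral density
#'
#' Averaged-periodogram PSD estimate with a sliding Hann window: the signal
#' is cut into `window_s`-second segments with fractional overlap
#' `overlap_frac`, each segment is mean-detrended, tapered and zero-padded
#' to `nfft` points, and the squared one-sided spectra are averaged. The
#' default settings (2 s window, 25% overlap, nfft = 2000 at fs = 1000 Hz)
#' give a 0.5 Hz frequency resolution.
#'
#' @param x numeric matrix, samples x ROIs (a single epoch).
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (default 2).
#' @param overlap_frac fractional overlap of successive windows (default
#'   0.25).
#' @param nfft FFT length; bin spacing is `fs / nfft` (default 2000).
#' @return List with `freq` (Hz), `psd` (bins x ROIs, density units
#'   signal^2/Hz), and `n_segments`.
#' @examples
#' x <- cbind(sin(2 * pi * 10 * seq(0, 4, by = 1e-3)))
#' p <- welch_psd(x, fs = 1000)
#' p$freq[which.max(p$psd)]  # 10 Hz
#' @export
welch_psd <- function(x, fs, window_s = 2, overlap_frac = 0.25,
                      nfft = 2000) {
  ws <- welch_segments(x, fs, window_s, overlap_frac, nfft)
  U <- sum(ws$window^2)
  p <- apply(Mod(ws$spectra)^2, c(1, 3), mean) / (fs * U)
  # one-sided density: double all bins except DC and (if present) Nyquist
  dbl <- rep(2, length(ws$freq))
  dbl[1] <- 1
  if (ws$nfft %% 2 == 0) dbl[length(dbl)] <- 1
  p <- p * dbl
  list(freq = ws$freq, psd = p, n_segments = ws$n_segments)
}

# Averaged cross-spectral matrices for all ROI pairs at every bin.
welch_cross_spectra <- function(x, fs, window_s, overlap_frac, nfft) {
  ws <- welch_segments(x, fs, window_s, overlap_frac, nfft)
  if (ncol(x) < 2) stop_mfnet("need at least 2 ROIs for coherence")
  if (ws$n_segments < 2)
    stop_mfnet("coherence needs >= 2 Welch segments (a single segment ",
               "gives coherence identically 1); lengthen the signal or ",
               "shorten the window")
  n_bins <- length(ws$freq)
  n <- ncol(x)
  S <- array(complex(real = 0), dim = c(n, n, n_bins))
  for (b in seq_len(n_bins)) {
    M <- ws$spectra[b, , , drop = TRUE]
    if (is.null(dim(M))) M <- matrix(M, ncol = n)
    S[, , b] <- t(M) %*% Conj(M) / ws$n_segments
  }
  list(freq = ws$freq, S = S, n_segments = ws$n_segments)
}

new_spectral_connectome <- function(freq, coh, measure) {
  structure(list(freq = freq, coh = coh, measure = measure),
            class = "spectral_connectome")
}

#' @export
print.spectral_connectome <- function(x, ...) {
  cat("<spectral_connectome>", x$measure, ":", dim(x$coh)[1], "ROIs x",
      length(x$freq), "bins (", min(x$freq), "-", max(x$freq), "Hz )\n")
  invisible(x)
}

#' Magnitude-squared coherence matrices
#'
#' Spectral coherence between every ROI pair at every frequency bin,
#' `|S_xy|^2 / (S_xx * S_yy)`, with the auto- and cross-spectra estimated
#' by Welch averaging (see [welch_psd()]). Values lie in [0,1]; the
#' diagonal is set to zero for network use.
#'
#' @inheritParams welch_psd
#' @return A `spectral_connectome`: `freq` (Hz) and `coh`, an
#'   n x n x bins array of coherence values.
#' @export
coherence_matrix <- function(x, fs, window_s = 2, overlap_frac = 0.25,
                             nfft = 2000) {
  cs <- welch_cross_spectra(x, fs, window_s, overlap_frac, nfft)
  n <- dim(cs$S)[1]
  coh <- array(0, dim = dim(cs$S))
  for (b in seq_along(cs$freq)) {
    auto <- Re(diag(cs$S[, , b]))
    denom <- outer(auto, auto)
    cb <- Mod(cs$S[, , b])^2 / denom
    cb[denom <= 0] <- 0
    cb <- pmin(pmax(cb, 0), 1)
    diag(cb) <- 0
    coh[, , b] <- (cb + t(cb)) / 2
  }
  new_spectral_connectome(cs$freq, coh, "coherence")
}

#' Imaginary coherence matrices
#'
#' The absolute imaginary part of the complex coherency,
#' `|Im(S_xy / sqrt(S_xx * S_yy))|`. Insensitive to zero-phase-lag
#' coupling (e.g. instantaneous field spread), at the cost of discarding
#' true zero-lag interactions.
#'
#' @inheritParams welch_psd
#' @return A `spectral_connectome` with values in [0,1].
#' @export
imaginary_coherence_matrix <- function(x, fs, window_s = 2,
                                       overlap_frac = 0.25, nfft = 2000) {
  cs <- welch_cross_spectra(x, fs, window_s, overlap_frac, nfft)
  coh <- array(0, dim = dim(cs$S))
  for (b in seq_along(cs$freq)) {
    auto <- Re(diag(cs$S[, , b]))
    denom <- sqrt(outer(auto, auto))
    cb <- abs(Im(cs$S[, , b] / denom))
    cb[!is.finite(cb)] <- 0
    cb <- pmin(cb, 1)
    diag(cb) <- 0
    coh[, , b] <- (cb + t(cb)) / 2
  }
  new_spectral_connectome(cs$freq, coh, "imaginary_coherence")
}

#' Average a spectral connectome into frequency bands
#'
#' Element-wise mean of the per-bin connectivity matrices over all bins f
#' with `f_low <= f <= f_high` (both endpoints included: band edges align
#' with the 0.5 Hz grid under default settings, so half-open rules would
#' drop stated edges).
#'
#' @param sc a `spectral_connectome` from [coherence_matrix()] or
#'   [imaginary_coherence_matrix()].
#' @param bands a band scheme data.frame (default [band_scheme()]).
#' @return A [band_connectome()] with one matrix per band.
#' @export
band_average <- function(sc, bands = band_scheme()) {
  if (!inherits(sc, "spectral_connectome"))
    stop_mfnet("expected a spectral_connectome")
  bands <- band_scheme(bands)
  tol <- 1e-9
  mats <- vector("list", nrow(bands))
  names(mats) <- bands$name
  for (i in seq_len(nrow(bands))) {
    sel <- which(sc$freq >= bands$f_low[i] - tol &
                 sc$freq <= bands$f_high[i] + tol)
    if (!length(sel))
      stop_mfnet("band '", bands$name[i], "' (", bands$f_low[i], "-",
                 bands$f_high[i], " Hz) contains no frequency bins")
    m <- apply(sc$coh[, , sel, drop = FALSE], c(1, 2), mean)
    diag(m) <- 0
    mats[[i]] <- m
  }
  band_connectome(mats)
}

#' Average band connectomes across epochs
#'
#' Element-wise mean of per-epoch band connectomes, giving a more robust
#' single estimate per subject.
#'
#' @param epochs list of [band_connectome()] objects with identical band
#'   schemes and node counts.
#' @return A single averaged `band_connectome`.
#' @export
average_epochs <- function(epochs) {
  if (!length(epochs)) stop_mfnet("no epochs to average")
  if (!all(vapply(epochs, inherits, logical(1), "band_connectome")))
    stop_mfnet("all epochs must be band_connectome objects")
  ref <- epochs[[1]]
  for (e in epochs[-1]) {
    if (!identical(e$bands, ref$bands) || e$n_nodes != ref$n_nodes)
      stop_mfnet("epochs differ in band scheme or node count")
  }
  mats <- lapply(ref$bands, function(b) {
    Reduce(`+`, lapply(epochs, function(e) e$matrices[[b]])) / length(epochs)
  })
  names(mats) <- ref$bands
  band_connectome(mats)
}
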