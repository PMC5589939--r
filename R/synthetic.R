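# Synthetic cohort generator: planted-partition weighted connectomes over M
# frequency-band layers, an AD-like layer imbalance on a chosen node set,
# and cognitive scores coupled monotonically to a network feature. Exists
# so every downstream stage (thresholding, metrics, statistics,
# classification) can be exercised and calibrated without external
# recordings.

#' Specification of a synthetic cohort
#'
#' Bundles and validates every generator parameter. Edge weights follow
#' `clip(mean + N(0, weight_noise_sd), 0, 1)` with mean `w_in` inside
#' modules and `w_out` between them. Subjects in the AD-like group have all
#' weights incident to `affected_nodes` scaled by `(1 - delta)` in the
#' alpha2 layer and by `(1 + delta)` (capped at 1) in the theta layer,
#' reproducing a concentration of node degree away from alpha2 toward
#' theta; control subjects are unscaled. Scores follow
#' `intercept + slope * feature + N(0, score_noise_sd)`.
#'
#' @param n_hc,n_ad subjects per group (default 25 + 25).
#' @param n_nodes nodes/ROIs (default 148; reduce to 40 for fast runs).
#' @param n_layers frequency-band layers (default 7).
#' @param module_sizes integer vector summing to `n_nodes`; default four
#'   near-equal modules.
#' @param w_in,w_out mean within-/between-module edge weight, with
#'   `0 <= w_out < w_in <= 1` (defaults 0.6 / 0.3).
#' @param weight_noise_sd sd of the Gaussian weight noise (default 0.1).
#' @param affected_nodes 1-based node indices carrying the group effect;
#'   default the first module.
#' @param delta layer-imbalance effect size in [0, 1) (default 0.3).
#' @param score_slope,score_intercept,score_noise_sd linear score model
#'   parameters (defaults 30, 0, 2).
#' @param seed integer cohort seed; per-subject seeds derive from it via
#'   [split_seed()].
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hc = 25, n_ad = 25, n_nodes = 148, n_layers = 7,
                        module_sizes = NULL, w_in = 0.6, w_out = 0.3,
                        weight_noise_sd = 0.1, affected_nodes = NULL,
                        delta = 0.3, score_slope = 30, score_intercept = 0,
                        score_noise_sd = 2, seed = 1L) {
  if (is.null(module_sizes)) {
    base <- n_nodes %/% 4
    module_sizes <- rep(base, 4)
    module_sizes[seq_len(n_nodes - 4 * base)] <-
      module_sizes[seq_len(n_nodes - 4 * base)] + 1
  }
  if (sum(module_sizes) != n_nodes)
    stop_mfnet("module_sizes sum to ", sum(module_sizes), ", expected ",
               n_nodes)
  if (!(w_out >= 0 && w_out < w_in && w_in <= 1))
    stop_mfnet("need 0 <= w_out < w_in <= 1")
  if (weight_noise_sd < 0) stop_mfnet("weight_noise_sd must be nonnegative")
  if (delta < 0 || delta >= 1)
    stop_mfnet("delta must lie in [0, 1), got ", delta)
  if (is.null(affected_nodes)) affected_nodes <- seq_len(module_sizes[1])
  affected_nodes <- as.integer(affected_nodes)
  if (any(affected_nodes < 1) || any(affected_nodes > n_nodes))
    stop_mfnet("affected_nodes must be 1..n_nodes indices")
  if (n_hc < 1 || n_ad < 1) stop_mfnet("both groups must be nonempty")
  if (n_layers < 2) stop_mfnet("need at least 2 layers")
  structure(list(
    n_hc = n_hc, n_ad = n_ad, n_nodes = n_nodes, n_layers = n_layers,
    module_sizes = as.integer(module_sizes), w_in = w_in, w_out = w_out,
    weight_noise_sd = weight_noise_sd, affected_nodes = affected_nodes,
    delta = delta, score_slope = score_slope,
    score_intercept = score_intercept, score_noise_sd = score_noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

spec_layer_names <- function(spec) {
  if (spec$n_layers == 7) band_scheme()$name
  else paste0("layer", seq_len(spec$n_layers))
}

# Layers carrying the AD-like imbalance: degree shifted away from "alpha2"
# (weights shrunk) and toward "theta" (weights boosted). For non-default
# layer counts the 4th and 2nd layers play those roles.
imbalance_layers <- function(spec) {
  nm <- spec_layer_names(spec)
  list(down = if ("alpha2" %in% nm) "alpha2" else nm[min(4, spec$n_layers)],
       up = if ("theta" %in% nm) "theta" else nm[min(2, spec$n_layers)])
}

module_membership <- function(spec) {
  rep(seq_along(spec$module_sizes), spec$module_sizes)
}

#' Generate one subject's multi-band connectome
#'
#' Draws M symmetric weighted matrices in [0,1] with zero diagonals from
#' the planted-partition model of `spec` (expected weight `w_in` within
#' modules, `w_out` between). For `group = "AD"` the weights incident to
#' the affected nodes are multiplicatively rescaled in the two imbalance
#' layers (see [cohort_spec()]); multiplicative scaling, rather than edge
#' rewiring, shifts those nodes' rank in the weight ordering so the effect
#' survives fixed-degree thresholding.
#'
#' @param spec a [cohort_spec()].
#' @param group `"HC"` or `"AD"`.
#' @param subject_seed integer seed for this subject's draws.
#' @return A [band_connectome()] with `spec$n_layers` layers.
#' @export
generate_subject_connectome <- function(spec, group = c("HC", "AD"),
                                        subject_seed = 1L) {
  if (!inherits(spec, "cohort_spec")) stop_mfnet("expected a cohort_spec")
  group <- match.arg(group)
  n <- spec$n_nodes
  memb <- module_membership(spec)
  same <- outer(memb, memb, `==`)
  Wmean <- ifelse(same, spec$w_in, spec$w_out)
  diag(Wmean) <- 0
  lay <- imbalance_layers(spec)
  affected <- rep(FALSE, n)
  affected[spec$affected_nodes] <- TRUE
  incident <- outer(affected, affected, `|`)
  nm <- spec_layer_names(spec)
  set.seed(subject_seed)
  mats <- vector("list", spec$n_layers)
  names(mats) <- nm
  ut <- upper.tri(Wmean)
  for (l in nm) {
    W <- Wmean
    W[ut] <- W[ut] + stats::rnorm(sum(ut), 0, spec$weight_noise_sd)
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
    if (group == "AD" && spec$delta > 0) {
      if (l == lay$down) W[incident] <- W[incident] * (1 - spec$delta)
      if (l == lay$up)   W[incident] <- W[incident] * (1 + spec$delta)
    }
    W <- pmin(pmax(W, 0), 1)
    diag(W) <- 0
    mats[[l]] <- W
  }
  band_connectome(mats)
}

#' Generate a full synthetic cohort
#'
#' Generates `n_hc + n_ad` subjects (HC first), derives each subject's seed
#' from the cohort seed by [split_seed()], and optionally attaches
#' cognitive scores driven by each subject's global multi-participation
#' coefficient after thresholding every layer at mean degree `k`.
#'
#' @param spec a [cohort_spec()].
#' @param scores attach scores coupled to global MPC (default TRUE).
#' @param k mean-degree threshold used for the score-driving feature
#'   (default 12).
#' @return Object of class `cohort`: `subjects` (data.frame id, group,
#'   MMSE, FR, TR), `connectomes` (list of [band_connectome()]), `spec`.
#' @export
generate_cohort <- function(spec, scores = TRUE, k = 12) {
  if (!inherits(spec, "cohort_spec")) stop_mfnet("expected a cohort_spec")
  groups <- c(rep("HC", spec$n_hc), rep("AD", spec$n_ad))
  ids <- c(sprintf("HC%03d", seq_len(spec$n_hc)),
           sprintf("AD%03d", seq_len(spec$n_ad)))
  connectomes <- vector("list", length(ids))
  names(connectomes) <- ids
  for (i in seq_along(ids)) {
    connectomes[[i]] <- generate_subject_connectome(
      spec, groups[i], split_seed(spec$seed, i))
  }
  subjects <- data.frame(id = ids, group = groups, MMSE = NA_real_,
                         FR = NA_real_, TR = NA_real_,
                         stringsAsFactors = FALSE)
  cohort <- structure(list(subjects = subjects, connectomes = connectomes,
                           spec = spec), class = "cohort")
  if (scores) {
    k <- min(k, spec$n_nodes - 1)  # cap for very small toy networks
    feature <- vapply(connectomes, function(bc) {
      mx <- build_multiplex(lapply(bc$matrices, threshold_to_mean_degree,
                                   k = k))
      multi_participation_coefficient(mx)$global
    }, numeric(1))
    cohort <- generate_scores(cohort, feature, spec)
  }
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", sum(x$subjects$group == "HC"), "HC +",
      sum(x$subjects$group == "AD"), "AD subjects,",
      x$spec$n_nodes, "nodes x", x$spec$n_layers, "layers\n")
  invisible(x)
}

#' Attach cognitive scores to a cohort
#'
#' Each score (TR, MMSE, FR) follows the linear model
#' `score_intercept + score_slope * feature + N(0, score_noise_sd)` with
#' independent noise per score; deterministic given the spec seed.
#'
#' @param cohort a `cohort`.
#' @param feature numeric vector, one network feature value per subject
#'   (same order as `cohort$subjects`).
#' @param spec the [cohort_spec()] providing slope/intercept/noise/seed.
#' @return The cohort with MMSE, FR, TR columns filled.
#' @export
generate_scores <- function(cohort, feature, spec = cohort$spec) {
  if (!inherits(cohort, "cohort")) stop_mfnet("expected a cohort")
  ns <- nrow(cohort$subjects)
  if (length(feature) != ns)
    stop_mfnet("feature has ", length(feature), " values for ", ns,
               " subjects")
  if (any(!is.finite(feature))) stop_mfnet("feature values must be finite")
  set.seed(split_seed(spec$seed, 999983L))
  mk <- function() spec$score_intercept + spec$score_slope * feature +
    stats::rnorm(ns, 0, spec$score_noise_sd)
  cohort$subjects$TR <- mk()
  cohort$subjects$MMSE <- mk()
  cohort$subjects$FR <- mk()
  cohort
}

# Zero-mean unit-variance noise confined to [f_low, f_high] Hz, built by
# masking the FFT of white noise.
band_limited_noise <- function(n_samp, fs, f_low, f_high) {
  z <- stats::fft(stats::rnorm(n_samp))
  freq <- (seq_len(n_samp) - 1) * fs / n_samp
  freq <- pmin(freq, fs - freq)  # fold to physical frequency
  z[freq < f_low | freq > f_high] <- 0
  x <- Re(stats::fft(z, inverse = TRUE)) / n_samp
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Generate coupled band-limited test signals
#'
#' Builds `n_rois` zero-mean signals: independent white noise of sd
#' `noise_sd` per ROI, plus, for every coupling, a shared band-limited
#' component of variance `strength` and an independent band-limited
#' component of variance `1 - strength` added to each member of the pair.
#' Expected band coherence between a coupled pair therefore increases with
#' `strength`, reaching ~1 at `strength = 1` with `noise_sd = 0`.
#'
#' @param n_rois number of signals.
#' @param fs sampling rate (Hz).
#' @param duration length in seconds.
#' @param coupling list of couplings, each a list with `pair` (two 1-based
#'   ROI indices), `band` (a name from the scheme) and `strength` in [0,1].
#' @param seed integer RNG seed.
#' @param noise_sd sd of the per-ROI broadband noise (default 1).
#' @param bands band scheme (default [band_scheme()]).
#' @return samples x n_rois numeric matrix.
#' @export
generate_band_signals <- function(n_rois, fs, duration, coupling = list(),
                                  seed = 1L, noise_sd = 1,
                                  bands = band_scheme()) {
  if (fs <= 0) stop_mfnet("fs must be positive")
  n_samp <- round_half_up(fs * duration)
  set.seed(seed)
  x <- matrix(stats::rnorm(n_samp * n_rois, 0, noise_sd), n_samp, n_rois)
  for (cp in coupling) {
    if (!all(c("pair", "band", "strength") %in% names(cp)))
      stop_mfnet("each coupling needs fields pair, band, strength")
    if (cp$strength < 0 || cp$strength > 1)
      stop_mfnet("coupling strength must be in [0,1]")
    row <- match(cp$band, bands$name)
    if (is.na(row))
      stop_mfnet("unknown band '", cp$band, "'; supported: ",
                 paste(bands$name, collapse = ", "))
    shared <- band_limited_noise(n_samp, fs, bands$f_low[row],
                                 bands$f_high[row])
    for (r in cp$pair) {
      own <- band_limited_noise(n_samp, fs, bands$f_low[row],
                                bands$f_high[row])
      x[, r] <- x[, r] + sqrt(cp$strength) * shared +
        sqrt(1 - cp$strength) * own
    }
  }
  sweep(x, 2, colMeans(x))
}
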