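# Pipeline orchestration: threshold-grid screening, representative
# threshold selection, hierarchical statistics, score correlations and
# classification, with JSON/TSV outputs and structured logging.

#' Pipeline configuration
#'
#' @param k_grid ascending mean-degree thresholds to screen (default
#'   c(1, 3, 6, 12, 24, 48)).
#' @param bands band scheme data.frame (default [band_scheme()]).
#' @param measure connectivity measure for the spectral stage,
#'   `"coherence"` or `"imcoh"`.
#' @param B permutations per statistical test (default 10000).
#' @param q FDR level (default 0.05).
#' @param alpha global-scale significance level (default 0.05).
#' @param cv_iter repeated-CV iterations (default 1000).
#' @param max_k_each grid-search depth per feature family (default 5).
#' @param restarts modularity restarts (default 20).
#' @param default_k fallback threshold when no k in the grid is significant
#'   for both analyses (default 12).
#' @param seed master RNG seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(k_grid = c(1, 3, 6, 12, 24, 48),
                            bands = band_scheme(),
                            measure = c("coherence", "imcoh"),
                            B = 10000L, q = 0.05, alpha = 0.05,
                            cv_iter = 1000L, max_k_each = 5L,
                            restarts = 20L, default_k = 12,
                            seed = 1L) {
  if (!length(k_grid) || is.unsorted(k_grid, strictly = TRUE))
    stop_mfnet("k_grid must be nonempty and strictly ascending")
  if (q <= 0 || q >= 1) stop_mfnet("q must lie in (0,1)")
  structure(list(k_grid = k_grid, bands = band_scheme(bands),
                 measure = match.arg(measure), B = as.integer(B), q = q,
                 alpha = alpha, cv_iter = as.integer(cv_iter),
                 max_k_each = as.integer(max_k_each),
                 restarts = as.integer(restarts), default_k = default_k,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Polynomial rolling hash (mod 2^32) over the canonical JSON encoding;
# recorded in outputs so a run can be matched to its exact configuration.
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (ch in utf8ToInt(as.character(s)))
    h <- (h * 33 + ch) %% 4294967296
  sprintf("%08x", h)
}

#' Select the representative threshold
#'
#' Given, for every screened mean degree k, the global-scale p-values of
#' the single-layer analysis (PC in the band of interest) and of the
#' multiplex analysis (MPC), returns the smallest k at which both are
#' significant at `alpha`. If no k qualifies, returns `NA` with attribute
#' `reason`; callers fall back to a configured default with a warning.
#'
#' @param results data.frame with columns `k`, `p_pc`, `p_mpc` covering
#'   the full grid.
#' @param alpha significance level (default 0.05).
#' @return The selected k, or NA.
#' @export
select_threshold <- function(results, alpha = 0.05) {
  need <- c("k", "p_pc", "p_mpc")
  if (!all(need %in% names(results)))
    stop_mfnet("expected columns k, p_pc, p_mpc")
  if (any(is.na(results$p_pc)) || any(is.na(results$p_mpc)))
    stop_mfnet("missing p-values for k = ",
               paste(results$k[is.na(results$p_pc) | is.na(results$p_mpc)],
                     collapse = ", "))
  ok <- results$p_pc < alpha & results$p_mpc < alpha
  if (!any(ok)) {
    out <- NA_real_
    attr(out, "reason") <- "no threshold significant for both analyses"
    return(out)
  }
  min(results$k[ok])
}

log_stage <- function(con, stage, ...) {
  line <- paste0("[", format(Sys.time(), "%H:%M:%S"), "] stage=", stage,
                 " ", paste(..., collapse = " "))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

# Per-subject node-level features at threshold k: local PC in `pc_band`
# (with a fresh modularity partition per subject) and local MPC.
subject_features_at_k <- function(cohort, k, pc_band, restarts, seed) {
  ids <- cohort$subjects$id
  n <- cohort$connectomes[[1]]$n_nodes
  pc_local <- matrix(NA_real_, length(ids), n)
  mpc_local <- matrix(NA_real_, length(ids), n)
  for (si in seq_along(ids)) {
    bc <- cohort$connectomes[[ids[si]]]
    layers <- lapply(bc$matrices, threshold_to_mean_degree, k = k)
    mx <- build_multiplex(layers)
    A <- layers[[pc_band]]
    part <- modularity_partition(A, seed = split_seed(seed, si),
                                 restarts = restarts)
    pc_local[si, ] <- participation_coefficient(A, part)$pc
    mpc_local[si, ] <- multi_participation_coefficient(mx)$mpc
  }
  list(pc = pc_local, mpc = mpc_local,
       pc_global = rowMeans(pc_local), mpc_global = rowMeans(mpc_local))
}

#' Run the full multi-frequency network analysis
#'
#' End-to-end orchestration on a cohort of band connectomes: (1) screen
#' every mean-degree threshold in the configured grid with global
#' permutation tests of the single-layer PC (in `pc_band`) and the
#' multiplex MPC; (2) select the representative threshold as the smallest
#' k significant for both analyses; (3) at that threshold run the
#' hierarchical global-to-local tests with FDR correction; (4) correlate
#' global features with cognitive scores inside the case group (Spearman,
#' permutation p); (5) grid-search combined PC/MPC ranked feature vectors
#' with the repeated-CV Mahalanobis classifier. Deterministic given the
#' config seed. If `out_dir` is given, stage outputs, a summary JSON
#' (stamped with the config hash and seed) and a log file are written.
#'
#' @param cohort a `cohort` (from [generate_cohort()] or [read_cohort()]).
#' @param config a [pipeline_config()].
#' @param pc_band band used for the single-layer analysis (default
#'   `"gamma"`).
#' @param out_dir optional output directory.
#' @return List with `threshold_screen`, `k_star`, `hierarchical`,
#'   `correlations`, `classification`, `config_hash`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         pc_band = "gamma", out_dir = NULL) {
  if (!inherits(cohort, "cohort")) stop_mfnet("expected a cohort")
  if (!inherits(config, "pipeline_config"))
    stop_mfnet("expected a pipeline_config")
  if (!pc_band %in% cohort$connectomes[[1]]$bands)
    stop_mfnet("band '", pc_band, "' not present in the cohort")
  labels <- cohort$subjects$group
  con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    con <- file(file.path(out_dir, "pipeline.log"), open = "wt")
    on.exit(close(con))
  }
  hash <- config_hash(config)
  log_stage(con, "start", paste0("config_hash=", hash),
            paste0("seed=", config$seed))
  t0 <- Sys.time()

  # stage 1: threshold screening
  screen <- data.frame(k = config$k_grid, p_pc = NA_real_,
                       p_mpc = NA_real_, z_pc = NA_real_, z_mpc = NA_real_)
  feats_by_k <- list()
  for (i in seq_along(config$k_grid)) {
    k <- config$k_grid[i]
    fk <- subject_features_at_k(cohort, k, pc_band, config$restarts,
                                split_seed(config$seed, 1000 + i))
    feats_by_k[[as.character(k)]] <- fk
    ad <- labels == "AD"
    g_pc <- permutation_ttest(fk$pc_global[ad], fk$pc_global[!ad],
                              B = config$B, seed = split_seed(config$seed,
                                                             2000 + i))
    g_mpc <- permutation_ttest(fk$mpc_global[ad], fk$mpc_global[!ad],
                               B = config$B, seed = split_seed(config$seed,
                                                               3000 + i))
    screen[i, c("p_pc", "p_mpc", "z_pc", "z_mpc")] <-
      c(g_pc$p, g_mpc$p, g_pc$Z, g_mpc$Z)
    log_stage(con, "screen", paste0("k=", k),
              sprintf("p_pc=%.4g p_mpc=%.4g", g_pc$p, g_mpc$p))
  }

  # stage 2: representative threshold
  k_star <- select_threshold(screen, alpha = config$alpha)
  fallback <- is.na(k_star)
  if (fallback) {
    warning("no threshold significant for both analyses; falling back to ",
            "k = ", config$default_k)
    k_star <- config$default_k
  }
  log_stage(con, "threshold", paste0("k_star=", k_star),
            paste0("fallback=", fallback))
  fk <- feats_by_k[[as.character(k_star)]]
  if (is.null(fk))
    fk <- subject_features_at_k(cohort, k_star, pc_band, config$restarts,
                                split_seed(config$seed, 1999))

  # stage 3: hierarchical global -> local statistics
  hier <- hierarchical_test(
    global_features = list(pc = fk$pc_global, mpc = fk$mpc_global),
    local_features = list(pc = fk$pc, mpc = fk$mpc),
    labels = labels, case = "AD", B = config$B, alpha = config$alpha,
    q = config$q, seed = split_seed(config$seed, 4000))
  log_stage(con, "stats",
            sprintf("global_p_pc=%.4g global_p_mpc=%.4g",
                    hier$pc$global$p, hier$mpc$global$p))

  # stage 4: correlations with scores in the case group
  ad <- labels == "AD"
  correlations <- list()
  if (!all(is.na(cohort$subjects$MMSE))) {
    correlations$pc_mmse <- spearman_correlation(
      fk$pc_global[ad], cohort$subjects$MMSE[ad], B = config$B,
      seed = split_seed(config$seed, 5000))
    correlations$mpc_tr <- spearman_correlation(
      fk$mpc_global[ad], cohort$subjects$TR[ad], B = config$B,
      seed = split_seed(config$seed, 5001))
    log_stage(con, "correlate",
              sprintf("R_mpc_tr=%.4f p=%.4g", correlations$mpc_tr$R,
                      correlations$mpc_tr$p))
  }

  # stage 5: classification grid over ranked PC/MPC features
  grid <- feature_grid_search(
    fk$pc, fk$mpc, labels, max_k_each = config$max_k_each,
    n_iter = config$cv_iter, seed = split_seed(config$seed, 6000))
  log_stage(con, "classify",
            sprintf("best_acc=%.2f%% at k_pc=%d k_mpc=%d", grid$best$acc,
                    grid$best$k1, grid$best$k2))

  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  log_stage(con, "done", sprintf("elapsed=%.1fs", elapsed))
  res <- list(threshold_screen = screen, k_star = k_star,
              fallback = fallback, hierarchical = hier,
              correlations = correlations, classification = grid,
              config_hash = hash, seed = config$seed)

  if (!is.null(out_dir)) {
    write_results_json(list(
      config_hash = hash, seed = config$seed,
      threshold_screen = screen, k_star = k_star, fallback = fallback,
      global = list(
        pc = hier$pc$global[c("statistic", "Z", "p")],
        mpc = hier$mpc$global[c("statistic", "Z", "p")]),
      correlations = correlations,
      best_cell = grid$best,
      accuracy_matrix = grid$acc
    ), file.path(out_dir, "summary.json"))
    for (f in names(hier)) {
      if (!is.null(hier[[f]]$local))
        write_metrics_tsv(hier[[f]]$local,
                          file.path(out_dir, paste0("local_", f, ".tsv")))
    }
  }
  res
}
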