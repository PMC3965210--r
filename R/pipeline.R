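#' Pipeline configuration
#'
#' Resolves and validates the full set of analysis settings. Defaults
#' reproduce the standard envelope-HMM pipeline: 4--30 Hz band, 100 ms
#' envelope windows with 75% overlap (40 Hz output from 200 Hz input),
#' 9.4 mm FWHM spatial smoothing, 40 principal components, an 8-state HMM
#' with 10 restarts, and a logarithmic 0.1--8 s sweep grid.
#'
#' @param band band-pass edges in Hz.
#' @param env_window_s envelope downsampling window in seconds.
#' @param env_overlap envelope window overlap fraction.
#' @param smooth_fwhm_mm spatial smoothing kernel FWHM in mm.
#' @param pca_components number of principal components M.
#' @param n_states number of HMM states K.
#' @param n_restarts VB restarts per fit.
#' @param tol relative free-energy convergence tolerance.
#' @param max_iter maximum VB iterations.
#' @param fo_window_s,fo_overlap fractional-occupancy window settings.
#' @param sweep_widths window-width sweep grid in seconds.
#' @param threshold_fraction display threshold for the spatial maps.
#' @param ridge_fraction beamformer covariance ridge fraction.
#' @param seed root seed; all stage seeds derive from it.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(band = c(4, 30), env_window_s = 0.1,
                            env_overlap = 0.75, smooth_fwhm_mm = 9.4,
                            pca_components = 40, n_states = 8,
                            n_restarts = 10, tol = 1e-5, max_iter = 500,
                            fo_window_s = 10, fo_overlap = 0.75,
                            sweep_widths = default_sweep_widths(),
                            threshold_fraction = 0.6, ridge_fraction = 0,
                            seed = 1L) {
  cfg <- list(band = band, env_window_s = env_window_s,
              env_overlap = env_overlap, smooth_fwhm_mm = smooth_fwhm_mm,
              pca_components = as.integer(pca_components),
              n_states = as.integer(n_states),
              n_restarts = as.integer(n_restarts), tol = tol,
              max_iter = as.integer(max_iter), fo_window_s = fo_window_s,
              fo_overlap = fo_overlap, sweep_widths = sweep_widths,
              threshold_fraction = threshold_fraction,
              ridge_fraction = ridge_fraction, seed = as.integer(seed))
  if (length(cfg$band) != 2L || cfg$band[1L] <= 0 ||
      cfg$band[2L] <= cfg$band[1L])
    stop("band must be increasing positive edges")
  if (cfg$n_states < 1L) stop("n_states must be at least 1")
  if (cfg$n_restarts < 1L) stop("n_restarts must be at least 1")
  if (cfg$pca_components < 1L) stop("pca_components must be at least 1")
  if (cfg$env_overlap < 0 || cfg$env_overlap >= 1 ||
      cfg$fo_overlap < 0 || cfg$fo_overlap >= 1)
    stop("overlap fractions must lie in [0, 1)")
  if (any(diff(cfg$sweep_widths) <= 0))
    stop("sweep_widths must be strictly increasing")
  structure(cfg, class = "pipeline_config")
}

#' Run the full envelope-HMM analysis
#'
#' Executes the analysis stages in their fixed order on a prepared
#' group-level envelope dataset: PCA whitening, VB-HMM fit, Viterbi
#' decoding, temporal summary statistics, fractional-occupancy time
#' courses and their correlation matrix, model and empirical transition
#' matrices, partial-correlation spatial maps (on the full-rank envelope
#' data, not the PCA scores), and the per-state window-width sweeps at
#' each state's representative voxel. All artifacts are written to
#' `out_dir` together with a manifest echoing the resolved configuration.
#'
#' @param dataset a group-level [envelope_dataset()] (normalized and
#'   concatenated; see [normalize_and_concatenate()]).
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with `model`, `posterior`, `path`, `stats`,
#'   `fo_tc`, `fo_cor`, `transition_model`, `transition_empirical`,
#'   `maps`, `sweeps`, `out_dir`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config(),
                         out_dir = tempfile("envhmm_run_")) {
  stopifnot(inherits(dataset, "envelope_dataset"))
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  rank_bound <- min(nrow(dataset$data), ncol(dataset$data) - 1L)
  n_comp <- min(config$pca_components, rank_bound)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  wh <- pca_whiten(dataset, n_comp)
  fit <- fit_hmm(wh, K = config$n_states, n_restarts = config$n_restarts,
                 max_iter = config$max_iter, tol = config$tol,
                 seed = config$seed)
  path <- viterbi_decode(fit$model, wh)
  stats_df <- summary_stats(path)
  fo_tc <- fo_timecourse(path, config$fo_window_s, config$fo_overlap)
  fo_cor <- fo_correlation_matrix(fo_tc)
  A_model <- transition_probability_matrix(fit$model)
  A_emp <- transition_probability_matrix(path)
  design <- build_design_matrix(path, config$n_states)
  maps <- partial_correlation_maps(design, dataset)
  sweeps <- lapply(seq_len(config$n_states), function(k) {
    if (!(k %in% maps$states_present)) return(NULL)
    vox <- representative_voxel(maps, k)
    sw <- fo_window_sweep(path, k, dataset$data[vox, ],
                          widths = config$sweep_widths)
    data.frame(state = k, voxel = vox, width_s = sw$widths,
               correlation = sw$correlations)
  })
  sweeps <- do.call(rbind, sweeps)

  write_csv <- function(x, name)
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  write_csv(data.frame(sample = seq_along(path$states), state = path$states),
            "state_path.csv")
  write_csv(stats_df, "stats.csv")
  write_csv(as.data.frame(fo_tc$occupancy), "fo_timecourse.csv")
  write_csv(as.data.frame(fo_cor), "fo_correlation.csv")
  write_csv(as.data.frame(A_model), "transition_model.csv")
  write_csv(as.data.frame(A_emp), "transition_empirical.csv")
  map_df <- data.frame(
    state = rep(seq_len(config$n_states), each = ncol(maps$coefficients)),
    voxel = rep(seq_len(ncol(maps$coefficients)), config$n_states),
    coefficient = as.numeric(t(maps$coefficients)))
  write_csv(map_df, "maps.csv")
  if (!is.null(sweeps)) write_csv(sweeps, "sweeps.csv")
  model_to_json(fit$model, file.path(out_dir, "model.json"))
  manifest <- list(package = "envhmm",
                   version = as.character(utils::packageVersion("envhmm")),
                   created = format(Sys.time(), tz = "UTC"),
                   config = unclass(config),
                   data = list(voxels = nrow(dataset$data),
                               samples = ncol(dataset$data),
                               sampling_rate = dataset$sampling_rate,
                               segments = length(dataset$segment_boundaries)),
                   free_energy = fit$model$free_energy)
  writeLines(jsonlite::toJSON(manifest, digits = NA, auto_unbox = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(list(model = fit$model, posterior = fit$posterior, path = path,
                 stats = stats_df, fo_tc = fo_tc, fo_cor = fo_cor,
                 transition_model = A_model, transition_empirical = A_emp,
                 maps = maps, sweeps = sweeps, out_dir = out_dir))
}
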