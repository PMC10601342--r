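#' Experiment configuration
#'
#' Validated bundle of every tunable in the pipeline. All fields are checked
#' here, before any stage runs, and the configuration is serialized verbatim
#' into the output manifest of [run_experiment()].
#'
#' @param n_cells,n_genes Dataset size.
#' @param params Shared [kinetic_params()].
#' @param noise_levels Non-empty numeric vector of noise levels.
#' @param k,n_pcs k-NN graph settings.
#' @param knn_preprocess,knn_mapping Graph sources for smoothing and mapping.
#' @param mapping_methods Mapping methods to evaluate.
#' @param models Velocity models to fit.
#' @param lambda Transition kernel width.
#' @param delta_t Embedding-transform time step.
#' @param grid_resolution Vector-field grid resolution.
#' @param loess_span QC loess span.
#' @param mu_threshold,gap_threshold QC flag thresholds.
#' @param n_seeds Seeds per sweep combination.
#' @param seed Global seed; per-stage seeds are derived from it by fixed
#'   offsets (stage index x 1000), so adding a stage never perturbs earlier
#'   stages' draws.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_cells = 500, n_genes = 10,
                              params = kinetic_params(),
                              noise_levels = 1:5,
                              k = 30, n_pcs = 30,
                              knn_preprocess = c("learned", "true"),
                              knn_mapping = "learned",
                              mapping_methods = c("projection", "transition"),
                              models = "dynamical",
                              lambda = 0.1, delta_t = 1,
                              grid_resolution = 20, loess_span = 0.3,
                              mu_threshold = 0.1, gap_threshold = 0.5,
                              n_seeds = 3, seed = 1L) {
  if (length(noise_levels) == 0)
    stop("invalid config: 'noise_levels' must be non-empty", call. = FALSE)
  if (any(noise_levels < 0))
    stop("invalid config: 'noise_levels' must be non-negative", call. = FALSE)
  stopifnot(inherits(params, "kinetic_params"))
  if (n_cells < 2 || n_genes < 1)
    stop("invalid config: 'n_cells'/'n_genes' too small", call. = FALSE)
  if (k >= n_cells)
    stop("invalid config: 'k' must be smaller than 'n_cells'", call. = FALSE)
  if (!all(knn_preprocess %in% c("learned", "true")))
    stop("invalid config: 'knn_preprocess' must be learned/true", call. = FALSE)
  if (!all(knn_mapping %in% c("learned", "true")))
    stop("invalid config: 'knn_mapping' must be learned/true", call. = FALSE)
  if (!all(mapping_methods %in% c("projection", "transition")))
    stop("invalid config: unknown entry in 'mapping_methods'", call. = FALSE)
  if (!all(models %in% c("steady_state", "dynamical")))
    stop("invalid config: unknown entry in 'models'", call. = FALSE)
  if (lambda <= 0 || delta_t <= 0 || grid_resolution < 2 || loess_span <= 0)
    stop("invalid config: 'lambda', 'delta_t', 'grid_resolution' and ",
         "'loess_span' must be positive (resolution >= 2)", call. = FALSE)
  if (n_seeds < 1) stop("invalid config: 'n_seeds' must be >= 1", call. = FALSE)
  structure(
    list(n_cells = n_cells, n_genes = n_genes, params = params,
         noise_levels = noise_levels, k = k, n_pcs = n_pcs,
         knn_preprocess = knn_preprocess, knn_mapping = knn_mapping,
         mapping_methods = mapping_methods, models = models,
         lambda = lambda, delta_t = delta_t,
         grid_resolution = grid_resolution, loess_span = loess_span,
         mu_threshold = mu_threshold, gap_threshold = gap_threshold,
         n_seeds = n_seeds, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

.config_flat <- function(config) {
  p <- config$params
  c(n_cells = config$n_cells, n_genes = config$n_genes,
    alpha = p$alpha, beta = p$beta, gamma = p$gamma,
    t_switch = p$t_switch, t_max = p$t_max,
    noise_levels = paste(config$noise_levels, collapse = ","),
    k = config$k, n_pcs = config$n_pcs,
    knn_preprocess = paste(config$knn_preprocess, collapse = ","),
    knn_mapping = paste(config$knn_mapping, collapse = ","),
    mapping_methods = paste(config$mapping_methods, collapse = ","),
    models = paste(config$models, collapse = ","),
    lambda = config$lambda, delta_t = config$delta_t,
    grid_resolution = config$grid_resolution,
    loess_span = config$loess_span,
    mu_threshold = config$mu_threshold, gap_threshold = config$gap_threshold,
    n_seeds = config$n_seeds, seed = config$seed)
}

#' Run a full simulation experiment
#'
#' Orchestrates simulator, preprocessing, model fitting, mapping, evaluation
#' and QC into one reproducible run: simulates one reference dataset (first
#' noise level), writes it with its learned and true graphs and smoothed
#' matrices, runs the full [evaluation_sweep()] across the configured noise
#' levels and graph/mapping choices, runs [velocity_qc()] on the reference
#' dataset, and writes a `manifest.txt` recording the configuration, a
#' configuration hash, and per-stage record counts. Deterministic given the
#' config; per-gene failures are logged in the fit outputs, never silently
#' dropped.
#'
#' @param config An [experiment_config()].
#' @param out_dir Writable output directory.
#' @param quiet Suppress per-stage progress lines?
#' @return Invisibly, a list with the sweep tibble, the QC report, and the
#'   output paths.
#' @export
run_experiment <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0)
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  say <- function(stage, detail) {
    if (!quiet) message(sprintf("[%s] %s", stage, detail))
  }
  seed0 <- config$seed

  # stage 1: reference dataset at the first configured noise level
  sim <- simulate_dataset(config$n_cells, config$n_genes,
                          params = config$params,
                          noise_level = config$noise_levels[1],
                          seed = seed0 + 1000L)
  say("simulate", sprintf("%d genes x %d cells, noise %g",
                          config$n_genes, config$n_cells,
                          config$noise_levels[1]))
  ds_dir <- file.path(out_dir, "dataset")
  write_dataset(sim, ds_dir)

  # stage 2: graphs and smoothed matrices
  learned <- build_knn_graph(sim$spliced, k = config$k, n_pcs = config$n_pcs)
  truth <- true_knn(sim, k = config$k, n_pcs = config$n_pcs)
  write_graph(learned, file.path(out_dir, "graph_learned.tsv"))
  write_graph(truth, file.path(out_dir, "graph_true.tsv"))
  g_pre <- if (config$knn_preprocess[1] == "true") truth else learned
  sm <- smooth_moments(sim, g_pre)
  write_mtx(sm$Ms, file.path(out_dir, "Ms.mtx"))
  write_mtx(sm$Mu, file.path(out_dir, "Mu.mtx"))
  say("preprocess", sprintf("k = %d, graph = %s", config$k,
                            config$knn_preprocess[1]))

  # stage 3: model fits on the reference dataset
  fits <- list()
  for (model in config$models) {
    fit <- switch(model,
      steady_state = fit_steady_state(sm, force_velocity_genes = TRUE),
      dynamical = fit_dynamical(sm, t_max_hat = config$params$t_max,
                                force_velocity_genes = TRUE))
    fits[[model]] <- fit
    utils::write.table(tidy(fit),
                       file.path(out_dir, paste0("fit_", model, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_mtx(ifelse(is.na(fit$velocity), 0, fit$velocity),
              file.path(out_dir, paste0("velocity_", model, ".mtx")))
    say("fit", sprintf("%s: %d/%d genes fitted", model,
                       sum(!is.na(fit$gamma_hat)), config$n_genes))
  }

  # stage 4: mapped and gridded fields for the reference dataset
  emb <- pca_embedding(sim$spliced, n_pcs = 2)
  fit1 <- fits[[config$models[1]]]
  g_map <- if (config$knn_mapping[1] == "true") truth else learned
  field <- switch(config$mapping_methods[1],
    projection = project_pca(fit1$velocity, emb),
    transition = transition_probabilities(sm$Ms, fit1$velocity, g_map,
                                          emb$coordinates,
                                          lambda = config$lambda))
  field <- grid_vector_field(field, config$grid_resolution)
  utils::write.table(as.data.frame(field[, c("cell", "x", "y", "dx", "dy")]),
                     file.path(out_dir, "vector_field.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(attr(field, "grid")),
                     file.path(out_dir, "vector_field_grid.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("map", sprintf("%s field: %d cells, %d grid boxes",
                     config$mapping_methods[1], nrow(field),
                     nrow(attr(field, "grid"))))

  # stage 5: evaluation sweep over all configured combinations
  sweep <- evaluation_sweep(
    noise_levels = config$noise_levels,
    knn_preprocess = config$knn_preprocess,
    knn_mapping = config$knn_mapping,
    mapping_methods = config$mapping_methods,
    models = config$models,
    n_seeds = config$n_seeds, n_cells = config$n_cells,
    n_genes = config$n_genes, k = config$k, params = config$params,
    lambda = config$lambda, base_seed = seed0 + 5000L)
  utils::write.table(
    as.data.frame(sweep[, c("noise_level", "knn_preprocess", "knn_mapping",
                            "model", "mapping_method", "seed",
                            "median_cosine", "median_pcc", "median_nrmse")]),
    file.path(out_dir, "sweep.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  say("sweep", sprintf("%d records", nrow(sweep)))

  # stage 6: QC on the reference dataset (needs a dynamical fit)
  qc <- NULL
  if ("dynamical" %in% config$models) {
    qc <- velocity_qc(sm, fits[["dynamical"]],
                      mu_threshold = config$mu_threshold,
                      gap_threshold = config$gap_threshold,
                      span = config$loess_span)
    qc_tab <- rbind(
      cbind(as.data.frame(qc[, c("gene", "r2_ms", "r2_mu")]), row = "gene"),
      data.frame(gene = "median", r2_ms = glance(qc)$median_r2_ms,
                 r2_mu = glance(qc)$median_r2_mu, row = "summary"))
    utils::write.table(qc_tab, file.path(out_dir, "qc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    say("qc", sprintf("flag = %s (gap = %.3f)", glance(qc)$flag,
                      glance(qc)$gap))
  }

  flat <- .config_flat(config)
  manifest <- c(paste0(names(flat), "=", flat),
                paste0("config_hash=", rlang::hash(flat)),
                paste0("sweep_records=", nrow(sweep)),
                paste0("qc_genes=", if (is.null(qc)) 0 else nrow(qc)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))

  invisible(list(sweep = sweep, qc = qc, fits = fits, out_dir = out_dir))
}
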