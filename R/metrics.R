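#' Cosine similarity between two vectors
#'
#' \eqn{a \cdot b / (\|a\| \|b\|)}, with the convention that a zero-norm
#' input yields 0.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A value in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b), all(is.finite(a)), all(is.finite(b)))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# rowwise cosine similarity between two n x d matrices (0 where a norm is 0)
.cosine_rows <- function(A, B) {
  na <- sqrt(rowSums(A^2))
  nb <- sqrt(rowSums(B^2))
  out <- rowSums(A * B) / (na * nb)
  out[na == 0 | nb == 0] <- 0
  out
}

#' Per-cell speed of a velocity matrix or vector field
#'
#' The l2 norm of each cell's vector. For a high-dimensional genes x cells
#' velocity matrix the sum runs over `gene_subset` (the velocity genes); for
#' a `vector_field` it runs over the two embedding coordinates.
#'
#' @param vectors Genes x cells matrix, or a `vector_field` tibble.
#' @param gene_subset Optional gene names or indices restricting the
#'   high-dimensional sum.
#' @return Non-negative numeric vector, one speed per cell.
#' @export
speed <- function(vectors, gene_subset = NULL) {
  if (inherits(vectors, "vector_field"))
    return(sqrt(vectors$dx^2 + vectors$dy^2))
  vectors <- as.matrix(vectors)
  if (!is.null(gene_subset))
    vectors <- vectors[gene_subset, , drop = FALSE]
  sqrt(colSums(vectors^2, na.rm = TRUE))
}

#' Pearson correlation coefficient
#'
#' The textbook product-moment formula,
#' \eqn{r = \sum (x_i - \bar x)(y_i - \bar y) /
#'   \sqrt{\sum (x_i - \bar x)^2 \sum (y_i - \bar y)^2}}.
#' Zero variance in either input makes the coefficient undefined; `NA` is
#' returned with a warning rather than an error so evaluation sweeps can
#' carry degenerate genes as missing entries.
#'
#' @param x,y Numeric vectors of equal length, at least 2.
#' @return The correlation, or `NA` if undefined.
#' @export
pcc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  dx <- x - mean(x)
  dy <- y - mean(y)
  denom <- sqrt(sum(dx^2) * sum(dy^2))
  if (denom == 0) {
    warning("zero variance: Pearson correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(dx * dy) / denom
}

#' Normalized root mean square error
#'
#' \eqn{NRMSE = \sqrt{\sum (y_i - \hat y_i)^2 / (n \sigma^2)}} with
#' \eqn{\sigma} the population (1/n) standard deviation of the true values,
#' so that predicting the mean gives exactly 1.
#'
#' @param y_true True values (at least 2, non-constant).
#' @param y_est Estimated values, same length.
#' @return Non-negative error, or `NA` (with a warning) when the true values
#'   are constant.
#' @export
nrmse <- function(y_true, y_est) {
  stopifnot(length(y_true) == length(y_est), length(y_true) >= 2)
  n <- length(y_true)
  sigma2 <- sum((y_true - mean(y_true))^2) / n
  if (sigma2 == 0) {
    warning("constant true values: NRMSE undefined", call. = FALSE)
    return(NA_real_)
  }
  sqrt(sum((y_true - y_est)^2) / (n * sigma2))
}

#' Noise-level by graph-choice evaluation sweep
#'
#' For every combination of noise level, preprocessing graph source,
#' mapping graph source, model and seed: simulate a dataset, smooth with the
#' chosen graph, fit the velocity model, map the estimated velocities into
#' the dataset's own 2-component PCA, and score (a) per-cell cosine
#' similarity of the mapped field against the gold standard — the orthogonal
#' PCA projection of the TRUE velocities — and (b) per-gene Pearson
#' correlation and NRMSE of the estimated against the true high-dimensional
#' velocities. Per-gene fit failures propagate as missing entries, never
#' abort the sweep.
#'
#' @param noise_levels Numeric vector of noise levels.
#' @param knn_preprocess,knn_mapping Graph sources (`"learned"`, `"true"`)
#'   used for smoothing and for the transition candidate sets.
#' @param mapping_methods Subset of `c("projection", "transition")`.
#' @param models Subset of `c("steady_state", "dynamical")`.
#' @param n_seeds Seeds per combination.
#' @param n_cells,n_genes Dataset size. Defaults 500 cells x 10 genes.
#' @param k Neighbors for both graphs. Default 30.
#' @param params Shared [kinetic_params()].
#' @param lambda Transition kernel width.
#' @param base_seed Offset added to each seed index.
#' @return A tibble with one row per combination: summary columns
#'   `median_cosine`, `median_pcc`, `median_nrmse`, plus list-columns
#'   `cosine` (per cell), `gene_pcc` and `gene_nrmse` (per gene).
#' @export
evaluation_sweep <- function(noise_levels = 1:5,
                             knn_preprocess = c("learned", "true"),
                             knn_mapping = "learned",
                             mapping_methods = c("projection", "transition"),
                             models = "dynamical",
                             n_seeds = 10, n_cells = 500, n_genes = 10,
                             k = 30, params = kinetic_params(),
                             lambda = 0.1, base_seed = 0) {
  stopifnot(length(noise_levels) >= 1)
  grid <- tidyr::expand_grid(
    noise_level = noise_levels,
    knn_preprocess = knn_preprocess,
    knn_mapping = knn_mapping,
    model = models,
    mapping_method = mapping_methods,
    seed = base_seed + seq_len(n_seeds)
  )

  purrr::pmap_dfr(grid, function(noise_level, knn_preprocess, knn_mapping,
                                 model, mapping_method, seed) {
    sim <- simulate_dataset(n_cells, n_genes, params = params,
                            noise_level = noise_level, seed = seed)
    learned <- build_knn_graph(sim$spliced, k = k)
    truth <- if (noise_level == 0) learned else true_knn(sim, k = k)
    g_pre <- if (knn_preprocess == "true") truth else learned
    g_map <- if (knn_mapping == "true") truth else learned
    sm <- smooth_moments(sim, g_pre)
    fit <- switch(model,
      steady_state = fit_steady_state(sm, force_velocity_genes = TRUE),
      dynamical = fit_dynamical(sm, t_max_hat = params$t_max,
                                force_velocity_genes = TRUE),
      stop("unknown model: ", model, call. = FALSE))
    emb <- pca_embedding(sim$spliced, n_pcs = 2)
    gold <- project_pca(sim$true_velocity, emb)
    est_field <- switch(mapping_method,
      projection = project_pca(fit$velocity, emb),
      transition = transition_probabilities(sm$Ms, fit$velocity, g_map,
                                            emb$coordinates,
                                            lambda = lambda),
      stop("unknown mapping method: ", mapping_method, call. = FALSE))
    cosine <- .cosine_rows(cbind(est_field$dx, est_field$dy),
                           cbind(gold$dx, gold$dy))
    gene_pcc <- gene_nrmse <- rep(NA_real_, n_genes)
    for (g in seq_len(n_genes)) {
      if (anyNA(fit$velocity[g, ])) next
      gene_pcc[g] <- suppressWarnings(pcc(sim$true_velocity[g, ],
                                          fit$velocity[g, ]))
      gene_nrmse[g] <- suppressWarnings(nrmse(sim$true_velocity[g, ],
                                              fit$velocity[g, ]))
    }
    tibble::tibble(
      noise_level = noise_level, knn_preprocess = knn_preprocess,
      knn_mapping = knn_mapping, model = model,
      mapping_method = mapping_method, seed = seed,
      median_cosine = stats::median(cosine),
      median_pcc = stats::median(gene_pcc, na.rm = TRUE),
      median_nrmse = stats::median(gene_nrmse, na.rm = TRUE),
      cosine = list(cosine), gene_pcc = list(gene_pcc),
      gene_nrmse = list(gene_nrmse)
    )
  })
}
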