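#' Evaluate the two-state kinetics at absolute latent times
#'
#' Pieces together induction (transcription on, starting from `u0 = s0 = 0`)
#' on `[0, t_switch]` and repression (transcription off, initial conditions
#' taken from the induction solution at `t_switch`) afterwards.
#'
#' @param params A [kinetic_params()] object.
#' @param t Vector of absolute latent times in `[0, t_max]`.
#' @return List with vectors `u`, `s` and the per-time `state` factor.
#' @export
kinetics_at <- function(params, t) {
  stopifnot(inherits(params, "kinetic_params"))
  on <- t <= params$t_switch
  u <- s <- numeric(length(t))
  if (any(on)) {
    sol <- solve_dynamics(params, t[on], u0 = 0, s0 = 0, state = "on")
    u[on] <- sol$u
    s[on] <- sol$s
  }
  if (any(!on)) {
    init <- solve_dynamics(params, params$t_switch, u0 = 0, s0 = 0, state = "on")
    sol <- solve_dynamics(params, t[!on] - params$t_switch,
                          u0 = init$u, s0 = init$s, state = "off")
    u[!on] <- sol$u
    s[!on] <- sol$s
  }
  list(u = u, s = s, state = ifelse(on, "on", "off"))
}

#' Simulate spliced/unspliced counts with known ground truth
#'
#' Generates a dataset from the two-state transcription kinetics shared by all
#' genes. A global cell pseudotime is drawn as cumulative log-uniform
#' (exponential) increments scaled to `[0, t_max]`; each gene then rescales it
#' affinely into its own sub-interval (order-preserving), so every gene
#' observes a different window of the same dynamics. Clean matrices come from the closed-form solution; the true
#' velocity is \eqn{\beta u - \gamma s}; observed matrices add i.i.d. Gaussian
#' noise with standard deviation
#' `noise_level * quantile(clean, 0.99) / 10`, computed separately for the
#' spliced and unspliced matrices.
#'
#' @param n_cells Number of cells (columns), at least 2.
#' @param n_genes Number of genes (rows), at least 1.
#' @param params A [kinetic_params()] object shared by all genes.
#' @param noise_level Non-negative noise multiplier; 0 gives observed == clean.
#' @param seed Integer seed; the full output is reproducible from it.
#' @param interval_start_max,interval_end_min Per-gene latent-time windows are
#'   drawn with start uniform on `[0, interval_start_max * t_max]` and end
#'   uniform on `[interval_end_min * t_max, t_max]`, so every gene covers both
#'   induction and repression.
#' @param clip Clip observed counts at zero? Default `FALSE`: the pipeline
#'   operates on raw real-valued matrices and noise may drive entries negative.
#'
#' @return An object of class `velocity_sim`: a list with observed matrices
#'   `spliced`, `unspliced`; clean matrices `spliced_clean`, `unspliced_clean`;
#'   `latent_time` and `true_velocity` (all genes x cells); `params`,
#'   `noise` (sigma values), `gene_ids`, `cell_ids`, `pseudotime` (global),
#'   and `seed`.
#' @examples
#' sim <- simulate_dataset(50, 4, seed = 1)
#' sim
#' @export
simulate_dataset <- function(n_cells, n_genes, params = kinetic_params(),
                             noise_level = 1, seed = 1L,
                             interval_start_max = 0.3,
                             interval_end_min = 0.7,
                             clip = FALSE) {
  stopifnot(inherits(params, "kinetic_params"))
  if (n_cells < 2) stop("n_cells must be at least 2", call. = FALSE)
  if (n_genes < 1) stop("n_genes must be at least 1", call. = FALSE)
  if (noise_level < 0) stop("noise_level must be non-negative", call. = FALSE)
  if (interval_start_max < 0 || interval_start_max >= interval_end_min ||
      interval_end_min > 1)
    stop("need 0 <= interval_start_max < interval_end_min <= 1", call. = FALSE)

  t_max <- params$t_max
  gene_ids <- sprintf("gene%03d", seq_len(n_genes))
  cell_ids <- sprintf("cell%04d", seq_len(n_cells))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # Global pseudotime: cumulative -log(uniform) increments (Poisson arrival
  # times) starting at 0, scaled so the last cell sits at t_max. Given the
  # cell count, arrival times are distributed like sorted uniforms, so the
  # trajectory is covered with near-uniform density.
  raw <- c(0, cumsum(-log(stats::runif(n_cells - 1, min = 1e-3, max = 1))))
  pseudotime <- raw / max(raw) * t_max

  starts <- stats::runif(n_genes, 0, interval_start_max * t_max)
  ends <- stats::runif(n_genes, interval_end_min * t_max, t_max)

  latent_time <- matrix(0, n_genes, n_cells,
                        dimnames = list(gene_ids, cell_ids))
  u_clean <- s_clean <- latent_time
  for (g in seq_len(n_genes)) {
    tg <- starts[g] + pseudotime / t_max * (ends[g] - starts[g])
    latent_time[g, ] <- tg
    sol <- kinetics_at(params, tg)
    u_clean[g, ] <- sol$u
    s_clean[g, ] <- sol$s
  }
  v_true <- params$beta * u_clean - params$gamma * s_clean

  sigma_s <- noise_level * stats::quantile(s_clean, 0.99, names = FALSE) / 10
  sigma_u <- noise_level * stats::quantile(u_clean, 0.99, names = FALSE) / 10
  spliced <- s_clean + matrix(stats::rnorm(length(s_clean), 0, sigma_s),
                              n_genes, n_cells)
  unspliced <- u_clean + matrix(stats::rnorm(length(u_clean), 0, sigma_u),
                                n_genes, n_cells)
  if (noise_level == 0) {
    spliced <- s_clean
    unspliced <- u_clean
  }
  if (clip) {
    spliced <- pmax(spliced, 0)
    unspliced <- pmax(unspliced, 0)
  }
  dimnames(spliced) <- dimnames(unspliced) <- dimnames(latent_time)

  structure(
    list(spliced = spliced, unspliced = unspliced,
         spliced_clean = s_clean, unspliced_clean = u_clean,
         latent_time = latent_time, true_velocity = v_true,
         pseudotime = pseudotime,
         params = params,
         noise = list(noise_level = noise_level,
                      sigma_spliced = sigma_s, sigma_unspliced = sigma_u),
         gene_ids = gene_ids, cell_ids = cell_ids, seed = as.integer(seed)),
    class = "velocity_sim"
  )
}

#' @export
print.velocity_sim <- function(x, ...) {
  cat("<velocity_sim> ", nrow(x$spliced), "genes x", ncol(x$spliced),
      "cells  (noise_level =", x$noise$noise_level,
      ", seed =", x$seed, ")\n")
  cat("  rates: alpha =", x$params$alpha, " beta =", x$params$beta,
      " gamma =", x$params$gamma, " t_max =", x$params$t_max, "\n")
  invisible(x)
}

#' Tidy view of a simulated dataset
#'
#' One row per gene/cell entry with observed and clean abundances, latent time
#' and true velocity.
#'
#' @param x A `velocity_sim` object.
#' @param ... Unused.
#' @return A tibble.
#' @importFrom generics tidy
#' @exportS3Method generics::tidy
tidy.velocity_sim <- function(x, ...) {
  tibble::tibble(
    gene = rep(x$gene_ids, times = ncol(x$spliced)),
    cell = rep(x$cell_ids, each = nrow(x$spliced)),
    latent_time = as.vector(x$latent_time),
    spliced = as.vector(x$spliced),
    unspliced = as.vector(x$unspliced),
    spliced_clean = as.vector(x$spliced_clean),
    unspliced_clean = as.vector(x$unspliced_clean),
    true_velocity = as.vector(x$true_velocity)
  )
}

#' k-NN graph from the pre-noise spliced matrix
#'
#' Builds the "true" neighbor graph: identical procedure to
#' [build_knn_graph()], but run on the noiseless spliced matrix, so the
#' neighborhood structure reflects the signal rather than the noise.
#'
#' @param sim A `velocity_sim` object.
#' @param k Number of neighbors (must be `< n_cells`).
#' @param ... Passed on to [build_knn_graph()].
#' @return A `knn_graph` with `source = "true"`.
#' @export
true_knn <- function(sim, k = 30, ...) {
  stopifnot(inherits(sim, "velocity_sim"))
  g <- build_knn_graph(sim$spliced_clean, k = k, ...)
  g$source <- "true"
  g
}

# Save/restore .Random.seed so seeded constructors do not disturb the
# caller's RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
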