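# Small in-code fixtures shared across test files.

# default kinetic parameters of the simulations
default_params <- function() kinetic_params()

# a small low-noise dataset with its learned graph and smoothed matrices
small_pipeline <- function(n_cells = 120, n_genes = 5, noise_level = 1,
                           seed = 42, k = 10) {
  sim <- simulate_dataset(n_cells, n_genes, noise_level = noise_level,
                          seed = seed)
  graph <- build_knn_graph(sim$spliced, k = k)
  list(sim = sim, graph = graph, smoothed = smooth_moments(sim, graph))
}

# brute-force k nearest neighbors by exhaustive Euclidean search on columns
brute_force_knn <- function(mat, k) {
  d <- as.matrix(stats::dist(t(mat)))
  t(sapply(seq_len(ncol(mat)), function(i) {
    di <- d[i, ]
    di[i] <- Inf
    order(di)[seq_len(k)]
  }))
}

# 2-D point-in-convex-hull test by cross products around the hull polygon
in_convex_hull <- function(point, vertices, tol = 1e-9) {
  hull <- vertices[grDevices::chull(vertices), , drop = FALSE]
  if (nrow(hull) < 3) {
    # degenerate hull: check distance to the segment/point set
    d <- min(sqrt(rowSums((vertices -
      matrix(point, nrow(vertices), 2, byrow = TRUE))^2)))
    return(d < 1e-6)
  }
  n <- nrow(hull)
  signs <- sapply(seq_len(n), function(i) {
    a <- hull[i, ]
    b <- hull[if (i == n) 1 else i + 1, ]
    (b[1] - a[1]) * (point[2] - a[2]) - (b[2] - a[2]) * (point[1] - a[1])
  })
  all(signs >= -tol) || all(signs <= tol)
}
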