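#' Build a weighted k-nearest-neighbor graph of cells
#'
#' Cells are embedded either on the top principal components of the row-mean
#' centered spliced matrix (when the gene count is at least `pca_threshold`)
#' or directly on the spliced matrix (the convention for small simulated gene
#' sets), and each cell is connected to its `k` nearest neighbors in Euclidean
#' distance, with exact search and ties broken by lowest cell index. Each cell
#' is included in its own neighborhood by default. Edge weights decay
#' exponentially with distance relative to the mean distance in the
#' neighborhood (or are uniform); the adjacency is symmetrized and columns of
#' the final weight matrix `W` are normalized to sum to 1, so smoothing with
#' `W` forms convex combinations of cells.
#'
#' @param spliced Genes x cells matrix used to define cell-cell distances.
#' @param k Number of neighbors, `1 <= k < n_cells`. Default 30.
#' @param n_pcs Number of principal components for the neighbor search when
#'   PCA is used. Default 30.
#' @param weighting `"exp"` (distance-decaying) or `"uniform"`.
#' @param include_self Include each cell in its own neighborhood?
#' @param pca_threshold Use PCA coordinates only when `nrow(spliced)` is at
#'   least this many genes; below it, raw spliced columns are used.
#' @return A `knn_graph`: list with `k`, sparse `W` (n x n, columns sum to 1),
#'   integer matrix `neighbor_index` (n x k, self excluded), and `source`.
#' @examples
#' sim <- simulate_dataset(40, 5, seed = 1)
#' g <- build_knn_graph(sim$spliced, k = 5)
#' Matrix::colSums(g$W)[1:3]
#' @export
build_knn_graph <- function(spliced, k = 30, n_pcs = 30,
                            weighting = c("exp", "uniform"),
                            include_self = TRUE,
                            pca_threshold = 500) {
  weighting <- match.arg(weighting)
  spliced <- as.matrix(spliced)
  n <- ncol(spliced)
  if (k < 1 || k >= n)
    stop("k must satisfy 1 <= k < n_cells (got k = ", k,
         ", n_cells = ", n, ")", call. = FALSE)
  row_var <- apply(spliced, 1, stats::var)
  if (all(row_var == 0))
    stop("degenerate input: every gene (row) is constant across cells; ",
         "constant rows: ", paste(utils::head(which(row_var == 0), 5),
                                  collapse = ", "),
         if (sum(row_var == 0) > 5) ", ..." else "", call. = FALSE)

  coords <- if (nrow(spliced) >= pca_threshold) {
    p <- min(n_pcs, nrow(spliced), n - 1)
    stats::prcomp(t(spliced), center = TRUE, scale. = FALSE)$x[, seq_len(p),
                                                               drop = FALSE]
  } else {
    t(spliced)
  }

  d <- as.matrix(stats::dist(coords))
  neighbor_index <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    # order() is stable: ties resolve to the lowest cell index
    neighbor_index[i, ] <- order(di)[seq_len(k)]
  }

  # adjacency: each cell's neighborhood (optionally including itself)
  ii <- jj <- ww <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- neighbor_index[i, ]
    if (include_self) nb <- c(i, nb)
    w <- if (weighting == "uniform") {
      rep(1 / length(nb), length(nb))
    } else {
      dn <- d[i, nb]
      scale <- mean(dn[dn > 0])
      if (!is.finite(scale) || scale == 0) scale <- 1
      exp(-dn / scale)
    }
    ii[[i]] <- rep(i, length(nb))
    jj[[i]] <- nb
    ww[[i]] <- w
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(ww),
                            dims = c(n, n))
  A <- (A + Matrix::t(A)) / 2
  cs <- Matrix::colSums(A)
  W <- A %*% Matrix::Diagonal(x = 1 / cs)

  structure(
    list(k = as.integer(k), W = W, neighbor_index = neighbor_index,
         source = "learned", weighting = weighting,
         include_self = include_self),
    class = "knn_graph"
  )
}

#' @export
print.knn_graph <- function(x, ...) {
  cat("<knn_graph>  n =", nrow(x$W), " k =", x$k,
    " source =", x$source, " weighting =", x$weighting, "\n")
  invisible(x)
}

#' Smooth a count matrix over a k-NN graph
#'
#' First-order moment smoothing: the smoothed profile of cell `i` is the
#' convex combination of raw cell profiles with the weights in column `i` of
#' the graph's weight matrix, `smoothed[, i] = counts %*% W[, i]`. Applied
#' identically and independently to spliced and unspliced matrices (use the
#' same graph for both).
#'
#' @param counts Genes x cells matrix.
#' @param graph A `knn_graph` (or any column-stochastic n x n matrix).
#' @return A dense genes x cells matrix of smoothed values.
#' @examples
#' sim <- simulate_dataset(40, 5, seed = 1)
#' g <- build_knn_graph(sim$spliced, k = 5)
#' Ms <- smooth_counts(sim$spliced, g)
#' @export
smooth_counts <- function(counts, graph) {
  W <- if (inherits(graph, "knn_graph")) graph$W else graph
  counts <- as.matrix(counts)
  if (ncol(counts) != nrow(W))
    stop("shape mismatch: counts has ", ncol(counts),
         " cells but the graph has ", nrow(W), call. = FALSE)
  out <- as.matrix(counts %*% W)
  dimnames(out) <- dimnames(counts)
  out
}

#' Smooth spliced and unspliced matrices with one shared graph
#'
#' Convenience wrapper producing the pair (`Ms`, `Mu`) used by the velocity
#' models.
#'
#' @param sim A `velocity_sim`, or a list with `spliced` and `unspliced`.
#' @param graph A `knn_graph`.
#' @return List with matrices `Ms`, `Mu` and the `graph` used.
#' @export
smooth_moments <- function(sim, graph) {
  list(Ms = smooth_counts(sim$spliced, graph),
       Mu = smooth_counts(sim$unspliced, graph),
       graph = graph)
}
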