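#' PCA embedding of a spliced matrix
#'
#' Principal components of the row-mean centered spliced matrix (no scaling):
#' coordinates \eqn{P = \tilde S^t R} with \eqn{R} the genes x p rotation.
#'
#' @param spliced Genes x cells matrix.
#' @param n_pcs Number of components to keep.
#' @return A `pca_embedding`: list with `rotation` (genes x p), `center`
#'   (per-gene means), and `coordinates` (cells x p).
#' @export
pca_embedding <- function(spliced, n_pcs = 2) {
  spliced <- as.matrix(spliced)
  p <- min(n_pcs, nrow(spliced), ncol(spliced) - 1)
  pc <- stats::prcomp(t(spliced), center = TRUE, scale. = FALSE)
  structure(
    list(rotation = pc$rotation[, seq_len(p), drop = FALSE],
         center = pc$center,
         coordinates = pc$x[, seq_len(p), drop = FALSE]),
    class = "pca_embedding"
  )
}

.new_vector_field <- function(positions, vectors, method, cell_ids = NULL) {
  if (is.null(cell_ids)) cell_ids <- rownames(positions)
  if (is.null(cell_ids)) cell_ids <- sprintf("cell%04d", seq_len(nrow(positions)))
  out <- tibble::tibble(
    cell = cell_ids,
    x = positions[, 1], y = positions[, 2],
    dx = vectors[, 1], dy = vectors[, 2]
  )
  class(out) <- c("vector_field", class(out))
  attr(out, "method") <- method
  out
}

#' Orthogonal projection of velocities into PCA space
#'
#' Maps a high-dimensional velocity matrix with the embedding's rotation:
#' \eqn{V_p = V^t R}, truncated to the first two components. The map is
#' exactly linear in the velocities; gene centering plays no role because
#' velocities are displacements.
#'
#' @param velocity Genes x cells velocity matrix. Genes are matched to the
#'   rotation's rows by name when both are named; rows with `NA` velocities
#'   (unfitted genes) are dropped.
#' @param embedding A [pca_embedding()].
#' @return A `vector_field` tibble: cell, position (x, y) and vector (dx, dy).
#' @export
project_pca <- function(velocity, embedding) {
  stopifnot(inherits(embedding, "pca_embedding"))
  velocity <- as.matrix(velocity)
  R <- embedding$rotation[, 1:2, drop = FALSE]
  if (!is.null(rownames(velocity)) && !is.null(rownames(R))) {
    shared <- intersect(rownames(velocity), rownames(R))
    if (length(shared) == 0)
      stop("no genes shared between the velocity matrix and the rotation",
           call. = FALSE)
    velocity <- velocity[shared, , drop = FALSE]
    R <- R[shared, , drop = FALSE]
  } else if (nrow(velocity) != nrow(R)) {
    stop("velocity gene set does not match the rotation rows", call. = FALSE)
  }
  keep <- stats::complete.cases(velocity)
  vec <- t(velocity[keep, , drop = FALSE]) %*% R[keep, , drop = FALSE]
  .new_vector_field(embedding$coordinates[, 1:2, drop = FALSE], vec,
                    "projection", cell_ids = colnames(velocity))
}

#' Map velocities into an embedding via transition probabilities
#'
#' For each cell \eqn{i}, candidate target cells are its neighbors and
#' neighbors-of-neighbors (self excluded). Each candidate \eqn{j} receives a
#' cosine similarity between the expression displacement
#' \eqn{Ms_j - Ms_i} and the cell's velocity \eqn{v_i}; an exponential kernel
#' \eqn{\tilde\pi(i \to j) \propto \exp(\pi(i,j)/\lambda)} row-normalized
#' over the candidate set turns similarities into transition probabilities.
#' The mapped vector is the probability-weighted sum of unit displacements in
#' the embedding, with a uniform baseline subtracted:
#' \eqn{\sum_j (\tilde\pi(i \to j) - 1/n_i) d(i,j)}, where \eqn{n_i} is the
#' candidate count. Cells with zero velocity (or an empty candidate set, with
#' a warning) map to the zero vector.
#'
#' @param Ms Genes x cells smoothed spliced matrix (the expression space in
#'   which displacements are measured).
#' @param velocity Genes x cells velocity matrix; rows with `NA` are dropped,
#'   and `Ms` is subset to the same genes.
#' @param graph A `knn_graph` supplying the neighbor sets.
#' @param positions Cells x 2 embedding coordinates.
#' @param lambda Kernel width. Default 0.1.
#' @return A `vector_field` tibble.
#' @export
transition_probabilities <- function(Ms, velocity, graph, positions,
                                     lambda = 0.1) {
  stopifnot(inherits(graph, "knn_graph"))
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  Ms <- as.matrix(Ms)
  velocity <- as.matrix(velocity)
  n <- ncol(Ms)
  if (nrow(positions) != n)
    stop("positions must have one row per cell", call. = FALSE)
  keep <- stats::complete.cases(velocity)
  V <- velocity[keep, , drop = FALSE]
  M <- Ms[keep, , drop = FALSE]

  nb <- graph$neighbor_index
  vectors <- matrix(0, n, 2)
  warned <- FALSE
  for (i in seq_len(n)) {
    vi <- V[, i]
    nv <- sqrt(sum(vi^2))
    if (nv == 0) next
    first <- c(i, nb[i, ])
    cand <- setdiff(unique(as.vector(cbind(first, nb[first, ]))), i)
    if (length(cand) == 0) {
      warned <- TRUE
      next
    }
    dm <- M[, cand, drop = FALSE] - M[, i]
    dn <- sqrt(colSums(dm^2))
    cosim <- ifelse(dn > 0, colSums(dm * vi) / (dn * nv), 0)
    # max-shifted exponentiation: the shift cancels in the normalization
    # and keeps small kernel widths from overflowing
    w <- exp((cosim - max(cosim)) / lambda)
    pij <- w / sum(w)
    dq <- positions[cand, , drop = FALSE] -
      matrix(positions[i, ], length(cand), 2, byrow = TRUE)
    dqn <- sqrt(rowSums(dq^2))
    dq <- dq / ifelse(dqn > 0, dqn, 1)
    vectors[i, ] <- colSums((pij - 1 / length(cand)) * dq)
  }
  if (warned)
    warning("some cells had empty candidate sets and were mapped to zero",
            call. = FALSE)
  .new_vector_field(positions[, 1:2, drop = FALSE], vectors, "transition",
                    cell_ids = colnames(Ms))
}

#' Map velocities through an embedding transform
#'
#' Generic future-state mapping for any embedding exposing a transform for
#' new points: \eqn{vector_i = embed(s_i + v_i \Delta t) - embed(s_i)}. For a
#' linear embedding (PCA) this reduces exactly to [project_pca()] scaled by
#' `delta_t`; for nonlinear embeddings the result depends on `delta_t`.
#'
#' @param S Genes x cells expression matrix (current states).
#' @param velocity Genes x cells velocity matrix.
#' @param embed A list with `transform(newdata)` mapping a genes x cells
#'   matrix to cells x 2 coordinates (see [pca_transform()]).
#' @param delta_t Time step. Default 1.
#' @return A `vector_field` tibble.
#' @export
map_via_embedding_transform <- function(S, velocity, embed, delta_t = 1) {
  if (!is.list(embed) || !is.function(embed$transform))
    stop("embedding does not support transforming new points", call. = FALSE)
  S <- as.matrix(S)
  velocity <- as.matrix(velocity)
  keep <- stats::complete.cases(velocity)
  V <- velocity
  V[!keep, ] <- 0
  now <- embed$transform(S)
  future <- embed$transform(S + V * delta_t)
  .new_vector_field(now, future - now, "transform", cell_ids = colnames(S))
}

#' Transform contract for a fitted PCA embedding
#'
#' Wraps a [pca_embedding()] as the transform contract used by
#' [map_via_embedding_transform()].
#'
#' @param embedding A `pca_embedding`.
#' @return List with a `transform` function (genes x cells -> cells x 2).
#' @export
pca_transform <- function(embedding) {
  stopifnot(inherits(embedding, "pca_embedding"))
  R <- embedding$rotation[, 1:2, drop = FALSE]
  ctr <- embedding$center
  list(transform = function(newdata) {
    t(as.matrix(newdata) - ctr) %*% R
  })
}

#' Summarize a vector field on a regular grid
#'
#' Splits the bounding box of the positions into `resolution x resolution`
#' boxes and averages the member-cell vectors within each non-empty box.
#'
#' @param field A `vector_field`.
#' @param resolution Boxes per axis, at least 2. Default 20.
#' @return The input `vector_field` with a `grid` attribute: a tibble with
#'   box centers (`x`, `y`), mean vectors (`dx`, `dy`) and member counts
#'   (`n`). Retrieve it with `attr(field, "grid")`.
#' @export
grid_vector_field <- function(field, resolution = 20) {
  stopifnot(inherits(field, "vector_field"))
  if (resolution < 2) stop("resolution must be at least 2", call. = FALSE)
  rx <- range(field$x)
  ry <- range(field$y)
  bx <- pmin(findInterval(field$x, seq(rx[1], rx[2],
                                       length.out = resolution + 1),
                          rightmost.closed = TRUE), resolution)
  by <- pmin(findInterval(field$y, seq(ry[1], ry[2],
                                       length.out = resolution + 1),
                          rightmost.closed = TRUE), resolution)
  wx <- diff(rx) / resolution
  wy <- diff(ry) / resolution
  grid <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(bx = bx, by = by, dx = field$dx, dy = field$dy),
      .data$bx, .data$by),
    dx = mean(.data$dx), dy = mean(.data$dy), n = dplyr::n(),
    .groups = "drop")
  grid <- dplyr::mutate(grid,
    x = rx[1] + (.data$bx - 0.5) * wx,
    y = ry[1] + (.data$by - 0.5) * wy)
  attr(field, "grid") <- grid[, c("x", "y", "dx", "dy", "n", "bx", "by")]
  attr(field, "resolution") <- resolution
  field
}
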