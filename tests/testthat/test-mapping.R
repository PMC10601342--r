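test_that("PCA projection is linear and matches the future-state difference", {
  withr::with_seed(41, {
    S <- matrix(rnorm(8 * 30, 10), 8, 30)
    V <- matrix(rnorm(8 * 30), 8, 30)
    emb <- pca_embedding(S, n_pcs = 2)
    # zero velocity maps to zero vectors
    f0 <- project_pca(0 * V, emb)
    expect_equal(max(abs(c(f0$dx, f0$dy))), 0)
    # linearity identity: embed(S + V) - embed(S) == project(V)
    tr <- pca_transform(emb)
    diff <- tr$transform(S + V) - tr$transform(S)
    fp <- project_pca(V, emb)
    expect_equal(cbind(fp$dx, fp$dy), unname(diff), tolerance = 1e-10)
    # exact linearity in V
    f2 <- project_pca(2 * V, emb)
    expect_equal(f2$dx, 2 * fp$dx, tolerance = 1e-12)
  })
})

test_that("an identity rotation returns velocity rows verbatim", {
  V <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3)
  emb <- structure(list(rotation = diag(2), center = c(0, 0),
                        coordinates = t(V * 0)), class = "pca_embedding")
  f <- project_pca(V, emb)
  expect_equal(cbind(f$dx, f$dy), unname(t(V)))
})

test_that("projection commutes with subsetting to the rotation's gene set", {
  withr::with_seed(42, {
    S <- matrix(rnorm(6 * 25, 10), 6, 25,
                dimnames = list(paste0("g", 1:6), NULL))
    emb <- pca_embedding(S, n_pcs = 2)
    V <- matrix(rnorm(8 * 25), 8, 25,
                dimnames = list(paste0("g", c(1:6, 98, 99)), NULL))
    full <- project_pca(V, emb)
    sub <- project_pca(V[1:6, ], emb)
    expect_equal(full$dx, sub$dx)
    Vbad <- V
    rownames(Vbad) <- paste0("x", 1:8)
    expect_error(project_pca(Vbad, emb), "no genes shared")
  })
})

# small deterministic scenario for the transition method
transition_toy <- function() {
  sim <- simulate_dataset(80, 5, noise_level = 1, seed = 19)
  graph <- build_knn_graph(sim$spliced, k = 8)
  emb <- pca_embedding(sim$spliced, n_pcs = 2)
  sm <- smooth_moments(sim, graph)
  list(sim = sim, graph = graph, emb = emb, sm = sm)
}

test_that("transition probabilities are row-normalized and vectors sit in the candidate hull", {
  tt <- transition_toy()
  field <- transition_probabilities(tt$sm$Ms, tt$sim$true_velocity, tt$graph,
                                    tt$emb$coordinates)
  expect_equal(nrow(field), 80)
  # recompute candidate sets and probabilities independently per cell
  nb <- tt$graph$neighbor_index
  Ms <- tt$sm$Ms
  V <- tt$sim$true_velocity
  pos <- tt$emb$coordinates
  for (i in c(1, 7, 40, 80)) {
    first <- c(i, nb[i, ])
    cand <- setdiff(unique(as.vector(cbind(first, nb[first, ]))), i)
    dm <- Ms[, cand, drop = FALSE] - Ms[, i]
    cosim <- colSums(dm * V[, i]) /
      (sqrt(colSums(dm^2)) * sqrt(sum(V[, i]^2)))
    pij <- exp(cosim / 0.1)
    pij <- pij / sum(pij)
    expect_equal(sum(pij), 1, tolerance = 1e-12)
    dq <- pos[cand, 1:2, drop = FALSE] -
      matrix(pos[i, 1:2], length(cand), 2, byrow = TRUE)
    dq <- dq / sqrt(rowSums(dq^2))
    oracle <- colSums((pij - 1 / length(cand)) * dq)
    expect_equal(c(field$dx[i], field$dy[i]), unname(oracle),
                 tolerance = 1e-10)
    # the mapped vector is a convex combination of centered displacements
    centered <- sweep(dq, 2, colMeans(dq))
    expect_true(in_convex_hull(c(field$dx[i], field$dy[i]), centered))
  }
})

test_that("the kernel limit concentrates on the aligned candidate", {
  # candidate displacements d and -d with velocity along d: as lambda -> 0
  # all probability mass lands on the aligned candidate and the output
  # approaches d (the baseline term cancels over symmetric displacements)
  Ms <- matrix(c(0, 1, -1), 1, 3) # cell 1 at origin, candidates at +-1
  V <- matrix(c(1, 0, 0), 1, 3)
  graph <- structure(list(k = 2L, W = Matrix::Diagonal(3),
                          neighbor_index = rbind(c(2L, 3L), c(1L, 3L),
                                                 c(1L, 2L)),
                          source = "learned"),
                     class = "knn_graph")
  pos <- cbind(c(0, 1, -1), c(0, 0, 0))
  f <- transition_probabilities(Ms, V, graph, pos, lambda = 1e-3)
  expect_equal(c(f$dx[1], f$dy[1]), c(1, 0), tolerance = 1e-6)
  # zero velocity maps to the zero vector
  V0 <- matrix(0, 1, 3)
  f0 <- transition_probabilities(Ms, V0, graph, pos)
  expect_equal(c(f0$dx[1], f0$dy[1]), c(0, 0))
})

test_that("transition output rotates with a rigid rotation of the embedding", {
  tt <- transition_toy()
  th <- 0.7
  Rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  f1 <- transition_probabilities(tt$sm$Ms, tt$sim$true_velocity, tt$graph,
                                 tt$emb$coordinates)
  f2 <- transition_probabilities(tt$sm$Ms, tt$sim$true_velocity, tt$graph,
                                 tt$emb$coordinates %*% Rot)
  expect_equal(cbind(f2$dx, f2$dy), cbind(f1$dx, f1$dy) %*% Rot,
               tolerance = 1e-10)
})

test_that("vectors can only point at cells present in the embedding", {
  # delete the cells a query cell's vector points toward; its recomputed
  # vector must swing away by more than 30 degrees
  sim <- simulate_dataset(200, 5, noise_level = 1, seed = 29)
  graph <- build_knn_graph(sim$spliced, k = 15)
  emb <- pca_embedding(sim$spliced, n_pcs = 2)
  sm <- smooth_moments(sim, graph)
  field <- transition_probabilities(sm$Ms, sim$true_velocity, graph,
                                    emb$coordinates)
  qi <- order(sqrt(field$dx^2 + field$dy^2), decreasing = TRUE)[1]
  v_q <- c(field$dx[qi], field$dy[qi])
  # cells ahead of the query cell in its direction of motion
  disp <- sweep(emb$coordinates, 2, emb$coordinates[qi, ])
  ahead <- order(disp %*% v_q / pmax(sqrt(rowSums(disp^2)), 1e-12),
                 decreasing = TRUE)
  drop_cells <- setdiff(utils::head(ahead, 40), qi)
  keep <- setdiff(seq_len(200), drop_cells)
  sub_spliced <- sim$spliced[, keep]
  sub_graph <- build_knn_graph(sub_spliced, k = 15)
  sub_field <- transition_probabilities(sm$Ms[, keep],
                                        sim$true_velocity[, keep],
                                        sub_graph,
                                        emb$coordinates[keep, ])
  qi2 <- match(qi, keep)
  v_q2 <- c(sub_field$dx[qi2], sub_field$dy[qi2])
  angle <- acos(min(max(cosine_similarity(v_q, v_q2), -1), 1)) * 180 / pi
  expect_gt(angle, 30)
})

test_that("the embedding-transform contract generalizes the projection", {
  withr::with_seed(47, {
    S <- matrix(rnorm(6 * 40, 10), 6, 40)
    V <- matrix(rnorm(6 * 40), 6, 40)
    emb <- pca_embedding(S, n_pcs = 2)
    tr <- pca_transform(emb)
    # linear embedding: identical to direct projection
    f_tr <- map_via_embedding_transform(S, V, tr, delta_t = 1)
    f_pr <- project_pca(V, emb)
    expect_equal(cbind(f_tr$dx, f_tr$dy), cbind(f_pr$dx, f_pr$dy),
                 tolerance = 1e-10)
    # doubling delta_t exactly doubles the vectors
    f_2 <- map_via_embedding_transform(S, V, tr, delta_t = 2)
    expect_equal(f_2$dx, 2 * f_tr$dx, tolerance = 1e-10)
    # a nonlinear (squaring) map differs from the linear prediction
    sq <- list(transform = function(m) cbind(as.numeric(m[1, ])^2, 0))
    f_sq <- map_via_embedding_transform(matrix(1, 1, 1), matrix(1, 1, 1), sq)
    expect_equal(f_sq$dx, 3) # (1+1)^2 - 1^2, not the linear prediction 2
    expect_error(map_via_embedding_transform(S, V, list()), "transform")
  })
})

test_that("grid averaging reproduces brute-force group means", {
  withr::with_seed(53, {
    pos <- matrix(runif(200), 100, 2)
    vec <- matrix(rnorm(200), 100, 2)
    field <- veloscope:::.new_vector_field(pos, vec, "projection")
    field <- grid_vector_field(field, resolution = 20)
    grid <- attr(field, "grid")
    expect_true(all(grid$n >= 1))
    expect_equal(sum(grid$n), 100)
    # brute-force re-aggregation
    cut_x <- pmin(findInterval(pos[, 1], seq(min(pos[, 1]), max(pos[, 1]),
                                             length.out = 21),
                               rightmost.closed = TRUE), 20)
    cut_y <- pmin(findInterval(pos[, 2], seq(min(pos[, 2]), max(pos[, 2]),
                                             length.out = 21),
                               rightmost.closed = TRUE), 20)
    for (r in sample(nrow(grid), 10)) {
      members <- which(cut_x == grid$bx[r] & cut_y == grid$by[r])
      expect_equal(grid$dx[r], mean(vec[members, 1]))
      expect_equal(grid$dy[r], mean(vec[members, 2]))
    }
    # two opposite vectors in one box average to zero
    f2 <- veloscope:::.new_vector_field(rbind(c(0.1, 0.1), c(0.15, 0.1),
                                              c(0.9, 0.9)),
                                        rbind(c(1, 0), c(-1, 0), c(1, 1)),
                                        "projection")
    g2 <- attr(grid_vector_field(f2, 4), "grid")
    expect_equal(g2$dx[g2$n == 2], 0)
    expect_error(grid_vector_field(f2, 1), "resolution")
  })
})

test_that("transition speed ignores high-dimensional speed while projection reflects it", {
  sim <- simulate_dataset(500, 10, noise_level = 1, seed = 61)
  graph <- build_knn_graph(sim$spliced, k = 30)
  emb <- pca_embedding(sim$spliced, n_pcs = 2)
  sm <- smooth_moments(sim, graph)
  hi_speed <- speed(sim$true_velocity)
  f_proj <- project_pca(sim$true_velocity, emb)
  f_trans <- transition_probabilities(sm$Ms, sim$true_velocity, graph,
                                      emb$coordinates)
  expect_gte(pcc(speed(f_proj), hi_speed), 0.8)
  expect_lt(abs(pcc(speed(f_trans), hi_speed)), 0.5)
})
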