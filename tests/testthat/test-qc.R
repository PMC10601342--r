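test_that("loess R2 handles degenerate, smooth and null signals", {
  t <- seq(0, 1, length.out = 100)
  expect_warning(out <- loess_r2(rep(2, 100), t), "constant")
  expect_equal(out, 0)
  # a clean periodic signal is almost fully explained
  expect_gte(loess_r2(sin(2 * pi * t), t, periodic = TRUE, period = 1), 0.99)
  # independent noise is barely explained on average: the null expectation
  # is roughly the smoother's degrees of freedom over n, so use enough
  # observations for the bound to be meaningful
  withr::with_seed(83, {
    t2 <- seq(0, 1, length.out = 200)
    r2s <- replicate(20, loess_r2(rnorm(200), t2))
    expect_lte(mean(r2s), 0.1)
  })
  expect_error(loess_r2(rnorm(5), seq_len(5)), "at least 10")
  expect_error(loess_r2(rnorm(20), seq_len(20), periodic = TRUE), "period")
})

test_that("periodic loess R2 is invariant to a period shift of the covariate", {
  withr::with_seed(89, {
    t <- runif(120)
    y <- cos(2 * pi * t) + rnorm(120, sd = 0.2)
    r_a <- loess_r2(y, t, periodic = TRUE, period = 1)
    r_b <- loess_r2(y, t + 1, periodic = TRUE, period = 1)
    expect_equal(r_a, r_b, tolerance = 1e-8)
  })
})

test_that("periodic mode beats linear mode on a signal that wraps around", {
  withr::with_seed(97, {
    t <- runif(150)
    y <- sin(2 * pi * t) + rnorm(150, sd = 0.1)
    expect_gt(loess_r2(y, t, periodic = TRUE, period = 1, span = 0.3),
              0.9)
  })
})

# one moderately sized QC scenario reused across the flagging tests
qc_scenario <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      sim <- simulate_dataset(300, 8, noise_level = 1, seed = 101)
      graph <- build_knn_graph(sim$spliced, k = 20)
      sm <- smooth_moments(sim, graph)
      fit <- fit_dynamical(sm, force_velocity_genes = TRUE)
      val <<- list(sim = sim, sm = sm, fit = fit)
    }
    val
  }
})

test_that("identical Ms and Mu give a gap of exactly zero", {
  qs <- qc_scenario()
  sm_eq <- list(Ms = qs$sm$Ms, Mu = qs$sm$Ms)
  rep_eq <- velocity_qc(sm_eq, qs$fit)
  expect_equal(glance(rep_eq)$gap, 0)
  expect_equal(rep_eq$r2_ms, rep_eq$r2_mu)
})

test_that("a low-noise simulation is flagged trustworthy", {
  qs <- qc_scenario()
  report <- velocity_qc(qs$sm, qs$fit)
  s <- glance(report)
  expect_gt(s$median_r2_mu, 0.5)
  expect_identical(s$flag, "trustworthy")
  expect_true(all(report$r2_ms >= 0 & report$r2_ms <= 1))
})

test_that("destroying the latent time drives Mu R2 to zero and flags suspect", {
  qs <- qc_scenario()
  fit_perm <- qs$fit
  withr::with_seed(7, {
    for (g in seq_len(nrow(fit_perm$latent_time)))
      fit_perm$latent_time[g, ] <- sample(fit_perm$latent_time[g, ])
  })
  report <- velocity_qc(qs$sm, fit_perm)
  s <- glance(report)
  expect_lt(s$median_r2_mu, 0.1)
  expect_identical(s$flag, "suspect")
})

test_that("top-likelihood ranking restricts the evaluated genes", {
  qs <- qc_scenario()
  report <- velocity_qc(qs$sm, qs$fit, n_top = 3)
  expect_equal(nrow(report), 3)
  keep <- names(sort(qs$fit$log_likelihood, decreasing = TRUE))[1:3]
  expect_setequal(report$gene, keep)
  expect_error(velocity_qc(qs$sm, fit_steady_state(qs$sm)), "dynamical")
})

test_that("Mu explained variance degrades as noise increases", {
  med_mu <- sapply(c(1, 3, 5), function(nl) {
    median(sapply(1:10, function(s) {
      sim <- simulate_dataset(120, 4, noise_level = nl, seed = 200 + s)
      graph <- build_knn_graph(sim$spliced, k = 15)
      sm <- smooth_moments(sim, graph)
      fit <- fit_dynamical(sm, force_velocity_genes = TRUE,
                           grid_points = 150)
      glance(velocity_qc(sm, fit))$median_r2_mu
    }))
  })
  expect_true(all(diff(med_mu) <= 0))
})

test_that("estimated latent time overfits Ms more than Mu under the learned graph", {
  # the spliced matrix defines the k-NN graph, so smoothing + fitting can
  # explain Ms better under the estimated time than under the true time;
  # Mu, smoothed with the same (spliced-derived) graph, shows a smaller gap
  gaps_ms <- gaps_mu <- numeric(10)
  for (s in 1:10) {
    sim <- simulate_dataset(120, 4, noise_level = 5, seed = 300 + s)
    graph <- build_knn_graph(sim$spliced, k = 15)
    sm <- smooth_moments(sim, graph)
    fit <- fit_dynamical(sm, force_velocity_genes = TRUE, grid_points = 150)
    ok <- which(!is.na(fit$gamma_hat))
    r2 <- sapply(ok, function(g) c(
      ms_est = loess_r2(sm$Ms[g, ], fit$latent_time[g, ]),
      ms_true = loess_r2(sm$Ms[g, ], sim$latent_time[g, ]),
      mu_est = loess_r2(sm$Mu[g, ], fit$latent_time[g, ]),
      mu_true = loess_r2(sm$Mu[g, ], sim$latent_time[g, ])))
    gaps_ms[s] <- median(r2["ms_est", ] - r2["ms_true", ])
    gaps_mu[s] <- median(r2["mu_est", ] - r2["mu_true", ])
  }
  expect_gt(median(gaps_ms), 0)
  expect_gt(median(gaps_ms), median(gaps_mu))
})
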