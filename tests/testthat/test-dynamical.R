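# noiseless fixture shared by the recovery tests
noiseless_fit <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      sim <- simulate_dataset(250, 6, noise_level = 0, seed = 17)
      fit <- fit_dynamical(list(Ms = sim$spliced, Mu = sim$unspliced))
      val <<- list(sim = sim, fit = fit)
    }
    val
  }
})

test_that("steady-state ratios are recovered within 5% on noiseless data", {
  nf <- noiseless_fit()
  fit <- nf$fit
  expect_true(all(!is.na(fit$gamma_hat)))
  expect_true(all(abs(fit$alpha_hat / fit$beta_hat - 5 / 0.3) <
                    0.05 * 5 / 0.3))
  expect_true(all(abs(fit$alpha_hat / fit$gamma_hat - 5 / 0.5) <
                    0.05 * 5 / 0.5))
})

test_that("latent times are recovered in rank order on noiseless data", {
  nf <- noiseless_fit()
  for (g in 1:6) {
    expect_gte(cor(nf$fit$latent_time[g, ], nf$sim$latent_time[g, ],
                   method = "spearman"), 0.99)
  }
})

test_that("noiseless velocities match the truth closely", {
  nf <- noiseless_fit()
  for (g in 1:6) {
    expect_gte(pcc(nf$fit$velocity[g, ], nf$sim$true_velocity[g, ]), 0.99)
    # identity-graph smoothing: NRMSE below 0.1 per gene
    expect_lt(nrmse(nf$sim$true_velocity[g, ], nf$fit$velocity[g, ]), 0.1)
  }
})

test_that("the fit respects the rate/time scale invariance", {
  # scaling all rates by c and dividing all times by c leaves the phase
  # curve unchanged, so a dataset generated under (2*rates, t/2) has the
  # same count matrices; fitting with a halved time horizon must recover
  # doubled rates and identical ratio-normalized parameters.
  sim <- simulate_dataset(200, 3, noise_level = 0, seed = 23)
  sm <- list(Ms = sim$spliced, Mu = sim$unspliced)
  f1 <- fit_dynamical(sm, t_max_hat = 25)
  f2 <- fit_dynamical(sm, t_max_hat = 12.5)
  expect_equal(unname(f2$beta_hat), unname(2 * f1$beta_hat),
               tolerance = 0.02)
  expect_equal(unname(f1$alpha_hat / f1$beta_hat),
               unname(f2$alpha_hat / f2$beta_hat), tolerance = 0.02)
  expect_equal(unname(f1$gamma_hat / f1$beta_hat),
               unname(f2$gamma_hat / f2$beta_hat), tolerance = 0.02)
  # velocities scale by c; directions are unchanged
  for (g in 1:3)
    expect_gte(pcc(f1$velocity[g, ], f2$velocity[g, ]), 0.999)
})

test_that("degenerate genes are flagged unfit rather than erroring", {
  withr::with_seed(31, {
    Ms <- rbind(runif(100, 1, 10), 3)
    Mu <- rbind(0.4 * Ms[1, ], 3)
    rownames(Ms) <- rownames(Mu) <- c("ok", "flat")
    fit <- fit_dynamical(list(Ms = Ms, Mu = Mu))
    expect_false(fit$velocity_gene[["flat"]])
    expect_true(is.na(fit$gamma_hat[["flat"]]))
    expect_match(fit$excluded, "flat")
    # too few cells
    expect_match(
      fit_dynamical(list(Ms = Ms[, 1:5], Mu = Mu[, 1:5]))$excluded[1],
      "min_cells")
  })
})

test_that("gene-shared latent time is the across-gene quantile", {
  nf <- noiseless_fit()
  fit <- nf$fit
  shared <- gene_shared_latent_time(fit)
  expect_equal(shared,
               apply(fit$latent_time, 2, median))
  # single fitted gene: shared time equals that gene's latent time
  one <- fit
  one$gamma_hat[-1] <- NA
  expect_equal(gene_shared_latent_time(one),
               fit$latent_time[1, ])
  # hand-checked quantile across three genes
  toy <- fit
  toy$gamma_hat <- c(1, 1, 1)
  toy$latent_time <- matrix(c(0.1, 0.5, 0.9), 3, 1)
  expect_equal(gene_shared_latent_time(toy), 0.5)
  # all genes identical: shared equals the common time
  toy$latent_time <- matrix(rep(c(0.2, 0.7), each = 3), 3, 2)
  expect_equal(gene_shared_latent_time(toy), c(0.2, 0.7))
  none <- fit
  none$gamma_hat[] <- NA
  expect_error(gene_shared_latent_time(none), "no fitted genes")
})

test_that("tidy and glance summarize dynamical fits", {
  nf <- noiseless_fit()
  td <- tidy(nf$fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("alpha_hat", "beta_hat", "gamma_hat", "t_switch_hat",
                    "log_likelihood") %in% names(td)))
  gl <- glance(nf$fit)
  expect_equal(gl$n_fitted, 6L)
  expect_equal(gl$model, "dynamical")
})
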