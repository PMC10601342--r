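#' Explained variance of a loess fit, with a periodic variant
#'
#' Fits a local regression of `y` on the time covariate `t` and returns
#' \eqn{R^2 = 1 - SS_{res}/SS_{total}}, clamped to `[0, 1]` (out-of-sample
#' smoothing can push the residual sum above the total). In periodic mode —
#' for covariates that track a full cycle — the data are tripled with one
#' period shift on each side, `[y, y, y]` against `[t - P, t, t + P]`, the
#' loess is fitted to all three copies, and both sums of squares are
#' evaluated on the original (middle) copy only, so the fit wraps smoothly
#' across the period boundary.
#'
#' @param y Response values (at least 10).
#' @param t Time covariate, same length.
#' @param periodic Fit the tripled periodic variant?
#' @param period Period of `t` (required when `periodic = TRUE`).
#' @param span Loess span. Default 0.3.
#' @param degree Local polynomial degree passed to [stats::loess()].
#' @return Explained variance in `[0, 1]`; constant `y` returns 0 with a
#'   warning.
#' @examples
#' t <- seq(0, 1, length.out = 100)
#' loess_r2(sin(2 * pi * t), t, periodic = TRUE, period = 1)
#' @export
loess_r2 <- function(y, t, periodic = FALSE, period = NULL, span = 0.3,
                     degree = 2) {
  stopifnot(length(y) == length(t))
  if (length(y) < 10) stop("need at least 10 observations", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("constant response: returning R^2 = 0", call. = FALSE)
    return(0)
  }
  if (periodic) {
    if (is.null(period) || period <= 0)
      stop("periodic mode needs a positive period", call. = FALSE)
    y3 <- rep(y, 3)
    t3 <- c(t - period, t, t + period)
    fit <- stats::loess(y3 ~ t3, span = span, degree = degree,
                        family = "gaussian")
    yhat <- stats::predict(fit, newdata = data.frame(t3 = t))
  } else {
    fit <- stats::loess(y ~ t, span = span, degree = degree,
                        family = "gaussian")
    yhat <- stats::predict(fit, newdata = data.frame(t = t))
  }
  ss_res <- sum((y - yhat)^2)
  min(max(1 - ss_res / ss_tot, 0), 1)
}

#' Quality control of a velocity fit via latent-time explained variance
#'
#' For the top `n_top` fitted genes ranked by likelihood, computes the
#' explained variance of a (non-periodic) loess of Ms and of Mu against each
#' gene's estimated latent time. A trustworthy velocity fit should explain
#' the unspliced signal too: the unspliced matrix is smoothed with the
#' spliced-derived k-NN graph, so it is not subject to the same circularity
#' that inflates the spliced explained variance. The dataset is flagged
#' `"suspect"` when the median Mu explained variance falls below
#' `mu_threshold` (a poor model fit) or the median Ms-minus-Mu gap exceeds
#' `gap_threshold` (overfitting induced by the k-NN smoothing).
#'
#' @param smoothed List with matrices `Ms` and `Mu`.
#' @param fit A dynamical `velocity_fit` (provides per-gene latent times and
#'   likelihoods).
#' @param n_top Number of top-likelihood genes to evaluate. Default 300.
#' @param mu_threshold Suspect threshold on the median Mu explained
#'   variance. Default 0.1.
#' @param gap_threshold Suspect threshold on median(Ms R2) - median(Mu R2).
#'   Default 0.5.
#' @param span Loess span. Default 0.3.
#' @param time Per-gene time variable: `"gene"` (each gene's own estimated
#'   latent time, the default) or `"shared"` (the gene-shared latent time
#'   from [gene_shared_latent_time()]).
#' @return A `qc_report` tibble with one row per evaluated gene (`gene`,
#'   `r2_ms`, `r2_mu`, `log_likelihood`) and attributes `summary` (a one-row
#'   tibble with medians, gap and flag) and the thresholds used.
#' @export
velocity_qc <- function(smoothed, fit, n_top = 300, mu_threshold = 0.1,
                        gap_threshold = 0.5, span = 0.3,
                        time = c("gene", "shared")) {
  stopifnot(inherits(fit, "velocity_fit"))
  time <- match.arg(time)
  if (is.null(fit$latent_time))
    stop("velocity QC requires a dynamical fit with latent times",
         call. = FALSE)
  fitted <- which(!is.na(fit$gamma_hat) & fit$velocity_gene)
  if (length(fitted) == 0) stop("no fitted velocity genes", call. = FALSE)
  ranked <- fitted[order(fit$log_likelihood[fitted], decreasing = TRUE)]
  top <- ranked[seq_len(min(n_top, length(ranked)))]
  shared <- if (time == "shared") gene_shared_latent_time(fit) else NULL

  rows <- purrr::map_dfr(top, function(g) {
    tg <- if (time == "shared") shared else fit$latent_time[g, ]
    tibble::tibble(
      gene = names(fit$gamma_hat)[g],
      r2_ms = suppressWarnings(
        loess_r2(as.numeric(smoothed$Ms[g, ]), tg, span = span)),
      r2_mu = suppressWarnings(
        loess_r2(as.numeric(smoothed$Mu[g, ]), tg, span = span)),
      log_likelihood = fit$log_likelihood[[g]]
    )
  })
  median_ms <- stats::median(rows$r2_ms)
  median_mu <- stats::median(rows$r2_mu)
  gap <- median_ms - median_mu
  flag <- if (median_mu < mu_threshold || gap > gap_threshold)
    "suspect" else "trustworthy"
  summary <- tibble::tibble(
    n_top_genes = length(top), time_kind = "linear",
    median_r2_ms = median_ms, median_r2_mu = median_mu,
    gap = gap, flag = flag
  )
  class(rows) <- c("qc_report", class(rows))
  attr(rows, "summary") <- summary
  attr(rows, "thresholds") <- c(mu_threshold = mu_threshold,
                                gap_threshold = gap_threshold)
  rows
}

#' One-row summary of a QC report
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return The report's summary tibble: median explained variances for Ms
#'   and Mu, their gap, and the trustworthy/suspect flag.
#' @exportS3Method generics::glance
glance.qc_report <- function(x, ...) {
  attr(x, "summary")
}
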