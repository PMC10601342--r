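#' Steady-state model velocity estimation
#'
#' For each gene, fits a through-origin regression of smoothed unspliced on
#' smoothed spliced abundance using only the extreme cells — those in the top
#' and bottom `quantile_frac` of the combined magnitude `Ms + Mu`, where the
#' process is presumed closest to its steady states. The slope is the
#' estimated degradation ratio \eqn{\hat\gamma}; the velocity is the residual
#' \eqn{v_{gi} = Mu_{gi} - \hat\gamma_g Ms_{gi}}. The coefficient of
#' determination of the fitted line over all cells is reported, and genes
#' exceeding `r2_threshold` are flagged as velocity genes.
#'
#' @param smoothed A list with matrices `Ms` and `Mu` (see [smooth_moments()]).
#' @param quantile_frac Fraction of cells taken at each extreme, in (0, 0.5].
#'   Default 0.05.
#' @param r2_threshold Velocity-gene threshold on the fit's coefficient of
#'   determination. Default 0.01.
#' @param force_velocity_genes Flag every successfully fitted gene as a
#'   velocity gene regardless of its fit score (the convention for simulated
#'   data where all genes are velocity genes by construction).
#' @return A `velocity_fit` with `model = "steady_state"`: per-gene
#'   `gamma_hat`, `fit_r2`, `velocity_gene`, the genes x cells `velocity`
#'   matrix, and `excluded` (genes skipped, with reasons).
#' @examples
#' sim <- simulate_dataset(100, 5, noise_level = 0, seed = 1)
#' fit <- fit_steady_state(list(Ms = sim$spliced, Mu = sim$unspliced))
#' tidy(fit)
#' @export
fit_steady_state <- function(smoothed, quantile_frac = 0.05,
                             r2_threshold = 0.01,
                             force_velocity_genes = FALSE) {
  Ms <- as.matrix(smoothed$Ms)
  Mu <- as.matrix(smoothed$Mu)
  if (!all(dim(Ms) == dim(Mu)))
    stop("Ms and Mu must have the same shape", call. = FALSE)
  if (quantile_frac <= 0 || quantile_frac > 0.5)
    stop("quantile_frac must lie in (0, 0.5]", call. = FALSE)

  m <- nrow(Ms)
  n <- ncol(Ms)
  gene_ids <- rownames(Ms)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%03d", seq_len(m))

  gamma_hat <- fit_r2 <- rep(NA_real_, m)
  velocity <- matrix(NA_real_, m, n, dimnames = list(gene_ids, colnames(Ms)))
  excluded <- character(0)

  for (g in seq_len(m)) {
    ms <- Ms[g, ]
    mu <- Mu[g, ]
    if (all(ms == 0)) {
      excluded <- c(excluded, paste0(gene_ids[g], ": all-zero Ms"))
      next
    }
    mag <- ms + mu
    qs <- stats::quantile(mag, c(quantile_frac, 1 - quantile_frac),
                          names = FALSE)
    ext <- which(mag <= qs[1] | mag >= qs[2])
    if (sum(ms[ext]^2) == 0) {
      excluded <- c(excluded, paste0(gene_ids[g], ": zero Ms on extreme cells"))
      next
    }
    gam <- sum(ms[ext] * mu[ext]) / sum(ms[ext]^2)
    res <- mu - gam * ms
    ss_tot <- sum((mu - mean(mu))^2)
    gamma_hat[g] <- gam
    fit_r2[g] <- if (ss_tot == 0) 0 else 1 - sum(res^2) / ss_tot
    velocity[g, ] <- res
  }

  fitted <- !is.na(gamma_hat)
  velocity_gene <- fitted & (fit_r2 > r2_threshold)
  if (force_velocity_genes) velocity_gene <- fitted

  structure(
    list(model = "steady_state", velocity = velocity,
         gamma_hat = stats::setNames(gamma_hat, gene_ids),
         fit_r2 = stats::setNames(fit_r2, gene_ids),
         velocity_gene = stats::setNames(velocity_gene, gene_ids),
         excluded = excluded,
         quantile_frac = quantile_frac, r2_threshold = r2_threshold),
    class = "velocity_fit"
  )
}
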