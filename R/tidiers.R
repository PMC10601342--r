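#' @importFrom generics glance
#' @export
generics::glance

#' @export
generics::tidy

#' @export
print.velocity_fit <- function(x, ...) {
  n_fit <- sum(!is.na(x$gamma_hat))
  cat("<velocity_fit>  model =", x$model, "\n  ",
      length(x$gamma_hat), "genes,", n_fit, "fitted,",
      sum(x$velocity_gene, na.rm = TRUE), "velocity genes\n")
  if (length(x$excluded))
    cat("  excluded:", paste(x$excluded, collapse = "; "), "\n")
  invisible(x)
}

#' Per-gene summary of a velocity fit
#'
#' One row per gene with the estimated parameters, fit quality, and the
#' velocity-gene flag. Dynamical fits add `alpha_hat`, `beta_hat`,
#' `t_switch_hat` and `log_likelihood`.
#'
#' @param x A `velocity_fit`.
#' @param ... Unused.
#' @return A tibble with one row per gene.
#' @exportS3Method generics::tidy
tidy.velocity_fit <- function(x, ...) {
  out <- tibble::tibble(
    gene = names(x$gamma_hat),
    gamma_hat = unname(x$gamma_hat),
    fit_r2 = unname(x$fit_r2),
    velocity_gene = unname(x$velocity_gene)
  )
  if (x$model == "dynamical") {
    out$alpha_hat <- unname(x$alpha_hat)
    out$beta_hat <- unname(x$beta_hat)
    out$t_switch_hat <- unname(x$t_switch_hat)
    out$log_likelihood <- unname(x$log_likelihood)
  }
  out
}

#' One-row summary of a velocity fit
#'
#' @param x A `velocity_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model, gene counts, median fit score.
#' @exportS3Method generics::glance
glance.velocity_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_genes = length(x$gamma_hat),
    n_fitted = sum(!is.na(x$gamma_hat)),
    n_velocity_genes = sum(x$velocity_gene, na.rm = TRUE),
    median_fit_r2 = stats::median(x$fit_r2, na.rm = TRUE)
  )
}
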