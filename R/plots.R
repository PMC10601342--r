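#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a low-dimensional vector field
#'
#' Cell positions with their mapped velocity arrows; if the field has been
#' summarized with [grid_vector_field()], the grid-averaged arrows are drawn
#' instead of per-cell arrows.
#'
#' @param object A `vector_field`.
#' @param arrow_scale Multiplier applied to arrow lengths for readability.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.vector_field <- function(object, arrow_scale = 1, ...) {
  grid <- attr(object, "grid")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(colour = "grey70", size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "dim 1", y = "dim 2",
                  title = paste("vector field:", attr(object, "method")))
  arrows <- if (is.null(grid)) object else grid
  p + ggplot2::geom_segment(
    data = arrows,
    ggplot2::aes(xend = .data$x + arrow_scale * .data$dx,
                 yend = .data$y + arrow_scale * .data$dy),
    arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")),
    linewidth = 0.3)
}

#' Phase portraits of a simulated dataset
#'
#' Unspliced over spliced abundance per gene, colored by latent time; the
#' classic induction/repression loop.
#'
#' @param object A `velocity_sim`.
#' @param genes Gene names to show (default: first 4).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.velocity_sim <- function(object, genes = NULL, ...) {
  if (is.null(genes)) genes <- utils::head(object$gene_ids, 4)
  df <- dplyr::filter(tidy(object), .data$gene %in% genes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$spliced, y = .data$unspliced,
                                   colour = .data$latent_time)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::facet_wrap(~gene, scales = "free") +
    ggplot2::labs(x = "spliced", y = "unspliced", colour = "latent time")
}

#' Explained-variance scatter of a QC report
#'
#' Per-gene Ms versus Mu explained variance with the suspect thresholds; a
#' trustworthy dataset sits near the diagonal with high Mu values.
#'
#' @param object A `qc_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.qc_report <- function(object, ...) {
  th <- attr(object, "thresholds")
  s <- glance(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r2_mu, y = .data$r2_ms)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_vline(xintercept = th[["mu_threshold"]], linetype = 3,
                        colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = expression(R^2 ~ "(Mu | latent time)"),
                  y = expression(R^2 ~ "(Ms | latent time)"),
                  title = paste0("velocity QC: ", s$flag,
                                 " (gap = ", round(s$gap, 3), ")"))
}

#' @importFrom rlang .data
NULL
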