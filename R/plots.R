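#' Plot a fitted depletion profile
#'
#' Shows the per-guide mean Z-scores along the protein (points), the
#' piecewise-constant fit (step line), and, when supplied, called regions
#' (shaded) for one gene.
#'
#' @param object A `tile_step_fit`.
#' @param regions Optional regions tibble; rows for this gene are shaded.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tile_step_fit <- function(object, regions = NULL, ...) {
  pos <- if (!is.null(object$cut_aa)) object$cut_aa else object$positions
  xlab <- if (!is.null(object$cut_aa)) "amino acid" else "position"
  dat <- tibble::tibble(pos = pos, y = object$y, fit = object$x_hat)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y), alpha = 0.5, size = 1) +
    ggplot2::geom_step(ggplot2::aes(y = .data$fit), colour = "firebrick",
                       linewidth = 0.8) +
    ggplot2::labs(x = xlab, y = "mean Z", title = object$gene) +
    ggplot2::theme_minimal()
  if (!is.null(regions)) {
    r <- regions[regions$gene %in% object$gene, , drop = FALSE]
    if (nrow(r) > 0) {
      p <- p + ggplot2::geom_rect(
        data = tibble::as_tibble(r),
        ggplot2::aes(xmin = .data$aa_start, xmax = .data$aa_end),
        ymin = -Inf, ymax = Inf, fill = "steelblue", alpha = 0.15,
        inherit.aes = FALSE
      )
    }
  }
  p
}

#' Plot one gene's profile from a list of fits
#'
#' @param fits Named list from [fit_profiles()].
#' @param gene Gene name.
#' @param regions Optional regions tibble.
#' @return A ggplot object.
#' @export
plot_gene_profile <- function(fits, gene, regions = NULL) {
  abort_if(!gene %in% names(fits), paste("no fit for gene", gene))
  autoplot(fits[[gene]], regions = regions)
}

#' Heatmap of between-cell-line Z-score correlations
#'
#' @param object A `tile_cor` matrix from [cell_line_correlation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tile_cor <- function(object, ...) {
  m <- unclass(object)
  dat <- tibble::as_tibble(as.table(m), .name_repair = "minimal")
  names(dat) <- c("line_a", "line_b", "r")
  ggplot2::ggplot(dat, ggplot2::aes(.data$line_a, .data$line_b,
                                    fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' Plot precision/recall against the replacement fraction
#'
#' @param robustness Tibble from [robustness_experiment()].
#' @return A ggplot object.
#' @export
plot_robustness <- function(robustness) {
  summ <- summarize_robustness(robustness) |>
    tidyr::pivot_longer(c("mean_precision", "mean_recall"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = sub("mean_", "", .data$metric))
  ggplot2::ggplot(summ, ggplot2::aes(.data$fraction, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "NTC replacement fraction", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
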