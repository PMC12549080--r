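#' Plot a delta SNP-index scan
#'
#' Scatter of per-site delta SNP indices along the chromosome with the
#' sliding-window mean overlaid and candidate regions shaded — the standard
#' bulked-segregant mapping figure.
#'
#' @param object A [bsa_scan()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bsa_scan <- function(object, ...) {
  p <- ggplot2::ggplot(object$points,
                       ggplot2::aes(x = .data$pos / 1e6, y = .data$delta)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "grey40")
  if (nrow(object$regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, fill = "tomato", alpha = 0.15,
      inherit.aes = FALSE)
  }
  if (nrow(object$windows) > 0) {
    p <- p + ggplot2::geom_line(
      data = object$windows,
      ggplot2::aes(x = .data$center / 1e6, y = .data$mean_delta),
      colour = "steelblue", linewidth = 0.7, inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_hline(yintercept = object$thresholds$delta_min,
                        linetype = "dashed", colour = "tomato") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = expression(Delta ~ "SNP index")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.bsa_scan
#' @export
plot_delta_scan <- function(object, ...) autoplot.bsa_scan(object, ...)

#' Plot TE-genotype by phenotype composition
#'
#' Stacked proportion bars of phenotype within each TE class, mirroring the
#' usual panel-association figure.
#'
#' @param object A [contingency_summary()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contingency_summary <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$te_status, y = .data$n,
                                   fill = .data$phenotype)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "TE genotype", y = "Accessions", fill = "Phenotype") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
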