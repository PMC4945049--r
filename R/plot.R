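#' Genome-wide copy-ratio plot
#'
#' Scatter of per-bin copy ratios along the genome, faceted by chromosome,
#' with called CNV intervals highlighted and the euploid baseline drawn at 1.
#' `autoplot()` returns the ggplot object; [plot_genome()] additionally
#' writes it to a file.
#'
#' @param object Normalised coverage tibble from [gc_correct()].
#' @param calls Optional calls tibble from [call_cnvs()]; matching intervals
#'   are shaded.
#' @param point_alpha Point transparency.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plasma_coverage
#' @export
autoplot.plasma_coverage <- function(object, calls = NULL, point_alpha = 0.4, ...) {
  object <- tibble::as_tibble(object)
  object$mb <- (object$start + object$end) / 2 / 1e6
  object$chrom <- factor(object$chrom, levels = unique(object$chrom))
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$mb, y = .data$ratio)) +
    ggplot2::geom_point(size = 0.3, alpha = point_alpha, colour = "grey30") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "steelblue") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::coord_cartesian(ylim = c(0, 2)) +
    ggplot2::labs(x = "Position (Mb)", y = "Copy ratio") +
    ggplot2::theme_minimal(base_size = 9)
  if (!is.null(calls) && nrow(calls) > 0) {
    shade <- calls
    shade$chrom <- factor(shade$chrom, levels = levels(object$chrom))
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf, fill = .data$direction),
      alpha = 0.25, inherit.aes = FALSE
    ) +
      ggplot2::scale_fill_manual(values = c(gain = "firebrick", loss = "royalblue"))
  }
  p
}

#' @rdname autoplot.plasma_coverage
#' @param normalized Normalised coverage tibble.
#' @param out_path File to write (extension selects the device, e.g. `.png`).
#' @param width,height,dpi Passed to [ggplot2::ggsave()].
#' @return `out_path`, invisibly.
#' @export
plot_genome <- function(normalized, calls = NULL, out_path,
                        width = 10, height = 7, dpi = 120) {
  p <- autoplot.plasma_coverage(normalized, calls = calls)
  ggplot2::ggsave(out_path, plot = p, width = width, height = height, dpi = dpi)
  invisible(out_path)
}
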