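# ggplot2 views of the signals and calls.

#' Plot a copy-number track
#'
#' Per-bin CN points along the genome, faceted by chromosome, with the diploid
#' baseline marked.
#'
#' @param cn_track Track with a `cn` column.
#' @return A ggplot.
#' @export
plot_cn_track <- function(cn_track) {
  d <- dplyr::filter(cn_track, !is.na(.data$cn))
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2e6, y = .data$cn)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 2, linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "copy number") +
    ggplot2::theme_minimal()
}

#' Plot a BAF track
#'
#' Per-bin maximum-likelihood BAF (folded into \[0, 0.5\]); allelic imbalance
#' shows as a departure from the 0.5 band.
#'
#' @param baf_track BAF track tibble.
#' @return A ggplot.
#' @export
plot_baf_track <- function(baf_track) {
  d <- dplyr::filter(baf_track, .data$n_het > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2e6, y = .data$max_baf)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::ylim(0, 0.5) +
    ggplot2::labs(x = "position (Mb)", y = "max-likelihood BAF") +
    ggplot2::theme_minimal()
}

#' Plot a CNV fit: CN signal, segment means and calls
#'
#' @param object A `cnv_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.cnv_fit <- function(object, ...) {
  bs <- object$bin_size
  segs <- segment_coords(object$segments, object$cn_track)
  p <- plot_cn_track(object$cn_track) +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(
        x = .data$start / 1e6, xend = .data$end / 1e6,
        y = .data$cn_mean, yend = .data$cn_mean
      ),
      colour = "orange", linewidth = 1, inherit.aes = FALSE
    )
  if (nrow(object$calls) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$calls,
      ggplot2::aes(
        xmin = .data$start / 1e6, xmax = .data$end / 1e6,
        ymin = -Inf, ymax = Inf, fill = .data$type
      ),
      alpha = 0.15, inherit.aes = FALSE
    ) +
      ggplot2::scale_fill_manual(values = c(
        deletion = "red", duplication = "blue", cnnloh = "darkgreen"
      ))
  }
  p
}
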