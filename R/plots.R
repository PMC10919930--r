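# ggplot2 displays for scan and population-genomic results.

#' Plot a column scan as a -log10(p) profile
#'
#' @param object An `aln_scan` tibble from [scan_alignment()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot aln_scan
#' @export
autoplot.aln_scan <- function(object, ...) {
  d <- filter(as_tibble(unclass_first(object)), .data$tested)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$column,
                                  y = -log10(pmax(.data$p_value, 1e-300)))) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::facet_wrap(~model, ncol = 1) +
    ggplot2::labs(x = "alignment column", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' Plot windowed heterozygosity across scaffolds
#'
#' Barplot of per-window heterozygosity, scaffolds side by side in
#' alternating shades — the standard genome-wide diversity display.
#'
#' @param object A `het_windows` tibble from [window_heterozygosity()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot het_windows
#' @export
autoplot.het_windows <- function(object, ...) {
  d <- as_tibble(unclass_first(object))
  d$scaffold <- factor(d$scaffold, levels = unique(d$scaffold))
  d$shade <- as.integer(d$scaffold) %% 2 == 0
  ggplot2::ggplot(d, ggplot2::aes(x = .data$start, y = .data$het,
                                  fill = .data$shade)) +
    ggplot2::geom_col(width = attr(object, "window_size") %||% 1e6) +
    ggplot2::facet_grid(~scaffold, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(values = c("grey30", "grey60"),
                               guide = "none") +
    ggplot2::labs(x = "position (bp)", y = "heterozygosity per called site") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(0.1, "lines"))
}

#' Plot an ROH length-bin histogram
#'
#' @param object A `roh_summary` from [summarize_roh()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roh_summary
#' @export
autoplot.roh_summary <- function(object, ...) {
  ggplot2::ggplot(object$bins, ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(
      x = "run length bin", y = "number of runs",
      subtitle = sprintf("Froh(%s) = %.3f", format_bp(object$min_length),
                         object$froh)
    ) +
    ggplot2::theme_minimal()
}
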