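#' Manhattan plot of a genome scan
#'
#' Plots -log10(p) per marker against cumulative genome position with
#' chromosomes alternately coloured and a horizontal line at the
#' genome-wide threshold. Layout is deterministic given the inputs:
#' chromosome offsets come from the largest marker position per
#' chromosome, in chromosome order.
#'
#' @param scan a `scan_result` from [scan_genome()].
#' @param thr a `threshold_set`, or NULL for no threshold line.
#' @param out_path optional file path; when given the plot is also written
#'   with [ggplot2::ggsave()] (format from the extension).
#' @param point_size point size (default 0.8).
#' @return The ggplot object, invisibly.
#' @export
manhattan_plot <- function(scan, thr = NULL, out_path = NULL,
                           point_size = 0.8) {
  df <- as.data.frame(scan[!scan$skipped, , drop = FALSE])
  if (!nrow(df)) stop("empty scan: nothing to plot")
  chrs <- CHROMOSOMES[CHROMOSOMES %in% unique(df$chr)]
  span <- vapply(chrs, function(ch) max(df$pos_mbp[df$chr == ch]), 0)
  offset <- stats::setNames(cumsum(c(0, utils::head(span, -1))), chrs)
  df$genome_mbp <- df$pos_mbp + offset[df$chr]
  df$chr <- factor(df$chr, levels = chrs)
  centers <- offset + span / 2
  pl <- ggplot2::ggplot(df, ggplot2::aes(
    x = genome_mbp, y = neg_log10_p, colour = chr)) +
    ggplot2::geom_point(size = point_size, show.legend = FALSE) +
    ggplot2::scale_colour_manual(
      values = stats::setNames(rep(c("grey25", "steelblue4"),
                                   length.out = length(chrs)), chrs)) +
    ggplot2::scale_x_continuous(breaks = centers, labels = chrs,
                                expand = ggplot2::expansion(mult = 0.01)) +
    ggplot2::labs(x = "Chromosome", y = expression(-log[10](italic(p)))) +
    ggplot2::theme_classic()
  if (!is.null(thr))
    pl <- pl + ggplot2::geom_hline(yintercept = thr$threshold_neg_log10,
                                   linetype = "dashed", colour = "firebrick")
  if (!is.null(out_path))
    ggplot2::ggsave(out_path, pl, width = 9, height = 3.2, dpi = 150)
  invisible(pl)
}
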