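# Optional renderings of profiles and heatmap matrices.

#' Plot condition profile pairs
#'
#' Mean +/- SEM traces of one subject across conditions against the slice
#' axis (and, if a calibration is given, a secondary mass annotation at the
#' peaks is implied by the axis direction: slice 1 = largest mass).
#'
#' @param profiles a [ProfileSet].
#' @param subject subject to plot.
#' @param curve optional [CalibrationCurve]; when given the x axis is
#'   labelled in apparent mass.
#' @return a ggplot object.
#' @export
plotProfile <- function(profiles, subject, curve = NULL) {
  keys <- names(profiles@profiles)
  sel <- profiles@profiles[startsWith(keys, paste0(subject, "|"))]
  if (!length(sel))
    cplxError(sprintf("no profiles for subject '%s'", subject),
              "cplx_lookup_error")
  df <- do.call(rbind, lapply(sel, function(p)
    data.frame(condition = p@condition, slice = seq_along(p@values),
               mean = p@values, sem = p@sem)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$slice, y = .data$mean,
                                        colour = .data$condition,
                                        fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, .data$mean - .data$sem),
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(title = subject, y = "relative intensity",
                  x = if (is.null(curve)) "slice (1 = top of gel)"
                      else "slice (top = high apparent mass)") +
    ggplot2::theme_classic()
  if (!is.null(curve)) {
    at <- pretty(seq_len(nrow(df) / length(sel)))
    at <- at[at >= 1]
    p <- p + ggplot2::scale_x_continuous(
      breaks = at, labels = sprintf("%.0f", massAt(curve, at)),
      name = "apparent mass (kDa)")
  }
  p
}

#' Render a heatmap matrix
#'
#' Draws a [heatmapMatrix()] with the conventional anchors black = 0,
#' yellow = 0.5, red = 1 (rows in given order, no clustering). Requires the
#' pheatmap package.
#'
#' @param m matrix from [heatmapMatrix()].
#' @param file optional output path.
#' @return the pheatmap object, invisibly.
#' @export
plotHeatmap <- function(m, file = NA) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    cplxError("plotHeatmap requires the pheatmap package",
              "cplx_dependency_error")
  cols <- grDevices::colorRampPalette(c("black", "yellow", "red"))(101)
  invisible(pheatmap::pheatmap(
    m, cluster_rows = FALSE, cluster_cols = FALSE, color = cols,
    breaks = seq(0, 1, length.out = 102), show_colnames = FALSE,
    filename = file))
}
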