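# Array overlay plot: spots drawn at (x, -y), one panel per dataset,
# colored by class or group -- the stand-in for overlaying calls on the
# stained tissue image.

#' Plot spot classes or groups on the array layout
#'
#' @param spots A `data.table` with columns `dataset`, `x`, `y` and the
#'   column named by `color_by` (e.g. a label table, a predictions table
#'   with `predicted_label`, or a cluster-group table).
#' @param color_by Column to color by (default `"label"`).
#' @return A `ggplot` object (requires the ggplot2 package).
#' @export
plot_spots <- function(spots, color_by = "label") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_spots needs the ggplot2 package")
  }
  df <- as.data.frame(spots)
  df$.col <- factor(df[[color_by]])
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = -y, color = .col)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::facet_wrap(~dataset) +
    ggplot2::coord_equal() +
    ggplot2::labs(color = color_by, x = "array x", y = "array y") +
    ggplot2::theme_minimal()
}
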