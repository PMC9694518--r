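# ggplot2 views of results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of a tissue area table
#'
#' Percentages of each tissue within its reference region (%RT, %BT, %MT),
#' faceted by region, colored with the catalogue display colors.
#'
#' @param object a `tissue_area_table` from [tissue_areas()].
#' @param catalogue the catalogue used (for display colors).
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.tissue_area_table <- function(object, catalogue = tissue_catalogue(),
                                       ...) {
  df <- as.data.frame(object)
  df$name <- factor(df$name, levels = df$name)
  cols <- stats::setNames(catalogue$color_hex, catalogue$name)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$name, y = .data$pct_of_region,
                                   fill = .data$name)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = cols) +
    ggplot2::facet_wrap(~pct_region, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "% of region area") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Raster view of a label map
#'
#' @param object a `tissue_label_map` or `grouped_map`.
#' @param palette named color vector; defaults as in [colorize()].
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.tissue_label_map <- function(object, palette = NULL, ...) {
  img <- colorize(object, palette)
  px <- unclass(img)
  hexmap <- grDevices::rgb(px[, , 1], px[, , 2], px[, , 3],
                           maxColorValue = 255)
  d <- dim(px)
  df <- data.frame(x = rep(seq_len(d[2]), each = d[1]),
                   y = rep(rev(seq_len(d[1])), times = d[2]),
                   fill = as.vector(matrix(hexmap, d[1], d[2])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' @rdname autoplot.tissue_label_map
#' @export
autoplot.grouped_map <- autoplot.tissue_label_map

#' @importFrom ggplot2 .data
NULL
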