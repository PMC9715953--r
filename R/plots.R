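# ggplot2 visualization helpers.

#' Plot a cluster map on the sub-image grid
#'
#' Renders the continuous association (or label / silhouette) of a
#' clustered subset as a pseudo-color tile map, optionally after the
#' NA-preserving median filter; rejected sub-images stay blank.
#'
#' @param result A [cluster_subset()] tibble.
#' @param n_rows,n_cols Grid dimensions (e.g. `attr(features, "n_rows")`).
#' @param value Column to render: `"c_assoc"`, `"label"` or `"silhouette"`.
#' @param filtered Apply [median_filter_map()] first; default `TRUE` for
#'   `"c_assoc"`.
#' @return A ggplot object.
#' @export
plot_cluster_map <- function(result, n_rows, n_cols,
                             value = c("c_assoc", "label", "silhouette"),
                             filtered = value == "c_assoc") {
  value <- match.arg(value)
  m <- grid_map(result[[value]], result$tile_row, result$tile_col,
                n_rows, n_cols)
  if (isTRUE(filtered)) m <- median_filter_map(m)
  df <- tidyr::expand_grid(tile_row = seq_len(n_rows),
                           tile_col = seq_len(n_cols))
  df$value <- m[cbind(df$tile_row, df$tile_col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tile_col, y = .data$tile_row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(
      low = "#f2c14e", mid = "white", high = "#c02ba5",
      midpoint = if (value == "c_assoc") 1.5 else NA,
      na.value = "grey20", name = value) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "tile column", y = "tile row",
                  title = paste0("Subset ", result$subset[1]))
}

#' Scree plot of a fitted PCA
#'
#' Eigenvalues per component with the Kaiser threshold at 1.
#'
#' @param object A [run_pca()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pshg_pca <- function(object, ...) {
  df <- tidy.pshg_pca(object, "eigenvalues")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc, y = .data$eigenvalue)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "purple") +
    ggplot2::labs(x = "principal component", y = "eigenvalue",
                  title = "Covariance-matrix eigenvalues (Kaiser line at 1)")
}

#' Plot the vertical profile of a cluster map
#'
#' @param profile A [vertical_profile()] vector.
#' @param boundary Optional true boundary position in tile columns, drawn
#'   as a vertical line.
#' @return A ggplot object.
#' @export
plot_vertical_profile <- function(profile, boundary = NULL) {
  df <- tibble::tibble(tile_col = seq_along(profile) - 0.5,
                       c_assoc = profile)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tile_col,
                                        y = .data$c_assoc)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1.5, linetype = "dashed") +
    ggplot2::labs(x = "tile column", y = "mean continuous association")
  if (!is.null(boundary))
    p <- p + ggplot2::geom_vline(xintercept = boundary, colour = "red",
                                 linetype = "dotted")
  p
}
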