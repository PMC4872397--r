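#' Plot an index score against age
#'
#' Scatter of the index over age with the fitted age trend; points are
#' colored by group label when the table carries one.
#'
#' @param table cohort tibble with `age` and the score column.
#' @param score_col index column name.
#' @param label_col optional group-label column.
#' @return A ggplot object.
#' @export
plot_score_age <- function(table, score_col = "spare_ba", label_col = "group_label") {
  p <- ggplot2::ggplot(table, ggplot2::aes(x = .data$age, y = .data[[score_col]]))
  if (label_col %in% names(table)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data[[label_col]]),
                                 alpha = 0.7, na.rm = TRUE) +
      ggplot2::labs(color = NULL)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7, na.rm = TRUE)
  }
  p + ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           color = "black", linewidth = 0.4, na.rm = TRUE) +
    ggplot2::labs(x = "age (years)", y = score_col) +
    ggplot2::theme_minimal()
}

#' Per-region density distributions by group
#'
#' Overlaid histograms of per-subject regional mean density, faceted by
#' region — the view that shows whether two groups' gray-matter volumes
#' shift within a region.
#'
#' @param densities tibble with columns `region`, `density` and `group`.
#' @param bins histogram bin count.
#' @return A ggplot object.
#' @export
plot_region_density <- function(densities, bins = 25) {
  ggplot2::ggplot(densities,
                  ggplot2::aes(x = .data$density, fill = .data$group)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = bins) +
    ggplot2::facet_wrap(~region, scales = "free_x") +
    ggplot2::labs(x = "regional mean density", y = "subjects", fill = NULL) +
    ggplot2::theme_minimal()
}

slice_tibble <- function(arr, z) {
  d <- dim(arr)
  sl <- arr[, , z]
  tibble(x = rep(seq_len(d[1]), d[2]),
         y = rep(seq_len(d[2]), each = d[1]),
         value = as.vector(sl))
}

#' Plot an axial slice of a voxel statistic map
#'
#' @param object a `voxel_stat_map`.
#' @param what `"t"`, `"q"` or `"mask"`.
#' @param z axial slice index (default: middle slice).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.voxel_stat_map <- function(object, what = "t", z = NULL, ...) {
  arr <- object[[what]]
  stopifnot(is.array(arr))
  z <- z %||% ceiling(dim(arr)[3] / 2)
  df <- slice_tibble(arr * 1, z)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s, slice z=%d", what, z), fill = what) +
    ggplot2::theme_void()
}

#' Plot an axial slice of a SPARE model's weight map
#'
#' @param object a `spare_model`.
#' @param z axial slice index (default: middle slice).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.spare_model <- function(object, z = NULL, ...) {
  w <- weight_map(object)
  if (!is.array(w)) abort("model has no grid; cannot plot", class = "spareatlas_validation_error")
  z <- z %||% ceiling(dim(w)[3] / 2)
  df <- slice_tibble(w, z)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("SVM weight map, slice z=%d", z), fill = "w") +
    ggplot2::theme_void()
}
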