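#' @importFrom ggplot2 autoplot
NULL

#' Plot a perfusion (or any parameter) map
#'
#' @param map Numeric matrix (NA outside the mask), e.g. one entry of a
#'   `perf_map_fit`'s `maps` or a `perf_nn_map`'s `map`.
#' @param title Plot title.
#' @param limits Optional two-element color-scale limits, ml/min/100g.
#' @return A ggplot object.
#' @export
plot_perfusion_map <- function(map, title = "Perfusion (ml/min/100g)",
                               limits = NULL) {
  df <- tibble::tibble(row = as.vector(row(map)), col = as.vector(col(map)),
                       value = as.vector(map))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "black", limits = limits) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "F") +
    ggplot2::theme_minimal()
}

#' @rdname plot_perfusion_map
#' @param object A `perf_map_fit`.
#' @param ... Unused.
#' @export
autoplot.perf_map_fit <- function(object, ...) {
  plot_perfusion_map(object$maps$F,
                     title = sprintf("Perfusion map (%s fit)", object$mode))
}

#' @rdname plot_perfusion_map
#' @export
autoplot.perf_nn_map <- function(object, ...) {
  plot_perfusion_map(object$map, title = "Perfusion map (network)")
}

#' Plot error-versus-reference profiles
#'
#' @param profiles A [binned_error_profile()] tibble, or several bound
#'   together with a `method` column.
#' @return A ggplot object.
#' @export
plot_error_profile <- function(profiles) {
  has_method <- "method" %in% names(profiles)
  aes <- if (has_method) {
    ggplot2::aes(x = .data$bin_center, y = .data$mean_error,
                 color = .data$method)
  } else {
    ggplot2::aes(x = .data$bin_center, y = .data$mean_error)
  }
  ggplot2::ggplot(profiles, aes) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Reference perfusion (ml/min/100g)",
                  y = "Mean error (ml/min/100g)") +
    ggplot2::theme_minimal()
}

#' Plot a perfusion histogram
#'
#' @param hist A [perfusion_histogram()] tibble (optionally several with a
#'   `group` column).
#' @return A ggplot object.
#' @export
plot_perfusion_histogram <- function(hist) {
  has_group <- "group" %in% names(hist)
  aes <- if (has_group) {
    ggplot2::aes(x = .data$bin_center, y = .data$count, fill = .data$group)
  } else {
    ggplot2::aes(x = .data$bin_center, y = .data$count)
  }
  ggplot2::ggplot(hist, aes) +
    ggplot2::geom_col(position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "Perfusion (ml/min/100g)", y = "Voxels") +
    ggplot2::theme_minimal()
}

#' Training-loss curve of a network
#'
#' @param object A `perf_net`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perf_net <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Epoch", y = "Mean cross-entropy") +
    ggplot2::theme_minimal()
}
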