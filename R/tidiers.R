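#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted perfusion map
#'
#' @param x A `perf_map_fit`.
#' @param ... Unused.
#' @return The per-voxel tibble of fitted parameters.
#' @export
tidy.perf_map_fit <- function(x, ...) x$voxels

#' One-row summary of a fitted perfusion map
#'
#' @param x A `perf_map_fit`.
#' @param ... Unused.
#' @return Tibble with voxel count, mode, perfusion summaries, total
#'   residual and convergence fraction.
#' @export
glance.perf_map_fit <- function(x, ...) {
  v <- x$voxels
  tibble::tibble(mode = x$mode, n_voxels = nrow(v),
                 mean_F = mean(v$F), median_F = median(v$F), sd_F = sd(v$F),
                 total_rss = sum(v$rss),
                 converged_fraction = mean(v$converged))
}

#' Tidy a trained network's training log
#'
#' @param x A `perf_net`.
#' @param ... Unused.
#' @return Tibble with `epoch` and mean cross-entropy `loss`.
#' @export
tidy.perf_net <- function(x, ...) x$log

#' One-row summary of a trained network
#'
#' @param x A `perf_net`.
#' @param ... Unused.
#' @return Tibble with architecture, parameter count and final loss.
#' @export
glance.perf_net <- function(x, ...) {
  n_par <- sum(vapply(x$weights, length, numeric(1))) +
    sum(vapply(x$biases, length, numeric(1)))
  tibble::tibble(n_hidden_layers = x$config$n_hidden_layers,
                 nodes_per_layer = x$config$nodes_per_layer,
                 n_parameters = n_par,
                 n_epochs = nrow(x$log),
                 final_loss = x$log$loss[nrow(x$log)],
                 label_source = x$label_source)
}

#' Tidy a comparison report
#'
#' @param x A `method_comparison_report`.
#' @param ... Unused.
#' @return The per-method metrics tibble.
#' @export
tidy.method_comparison_report <- function(x, ...) x$metrics

#' One-row summary of a comparison report
#'
#' @param x A `method_comparison_report`.
#' @param ... Unused.
#' @return Tibble with reference, voxel and method counts.
#' @export
glance.method_comparison_report <- function(x, ...) {
  tibble::tibble(reference = x$reference, n_voxels = x$n_voxels,
                 n_methods = nrow(x$metrics), n_tests = nrow(x$tests))
}
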