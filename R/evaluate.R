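#' Summary and error statistics of one estimator against a reference
#'
#' Computes the comparison row used to benchmark perfusion estimators:
#' mean, SD and median of the estimates, plus mean (signed) error, RMSE,
#' MAE and the Pearson correlation against the reference. The power-mean
#' inequality `MAE <= RMSE` is asserted on every call.
#'
#' @param estimates,reference Equal-length numeric vectors of per-voxel
#'   perfusion, ml/min/100g.
#' @param method,reference_name Labels carried into the output row.
#' @return A one-row tibble of class `method_comparison` with columns
#'   `method`, `reference`, `n_voxels`, `mean`, `sd`, `median`,
#'   `mean_error`, `rmse`, `mae`, `pearson_r`.
#' @export
error_metrics <- function(estimates, reference, method = "estimate",
                          reference_name = "reference") {
  check_finite_numeric(estimates, "estimates")
  check_finite_numeric(reference, "reference")
  if (length(estimates) != length(reference) || length(estimates) == 0) {
    stop_invalid("`estimates` and `reference` must have equal nonzero length")
  }
  if (sd(estimates) == 0 || sd(reference) == 0) {
    rlang::abort("zero-variance input: correlation undefined",
                 class = "dceperf_degenerate_input")
  }
  err <- estimates - reference
  r <- cor(estimates, reference)
  out <- tibble::tibble(
    method = method, reference = reference_name,
    n_voxels = length(estimates),
    mean = mean(estimates), sd = sd(estimates), median = median(estimates),
    mean_error = mean(err),
    rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)),
    pearson_r = r)
  stopifnot(out$mae <= out$rmse + 1e-12, out$rmse >= abs(out$mean_error) - 1e-12)
  class(out) <- c("method_comparison", class(out))
  out
}

#' Paired test of estimation accuracy between two methods
#'
#' Two-sided paired t test on the per-voxel difference of absolute errors,
#' the paired quantity consistent with comparing MAEs.
#'
#' @param abs_err_a,abs_err_b Equal-length vectors of per-voxel absolute
#'   errors, paired by voxel.
#' @return A one-row tibble with `statistic` (t), `df`, `p_value` and
#'   `mean_difference` (a - b).
#' @export
paired_accuracy_test <- function(abs_err_a, abs_err_b) {
  check_finite_numeric(abs_err_a, "abs_err_a")
  check_finite_numeric(abs_err_b, "abs_err_b")
  if (length(abs_err_a) != length(abs_err_b) || length(abs_err_a) < 2) {
    stop_invalid("paired vectors must share length >= 2")
  }
  d <- abs_err_a - abs_err_b
  if (sd(d) == 0) {
    rlang::abort("all paired differences identical: test degenerate",
                 class = "dceperf_degenerate_input")
  }
  tt <- t.test(abs_err_a, abs_err_b, paired = TRUE)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_difference = mean(d))
}

#' Mean signed error binned by reference perfusion
#'
#' Discretizes the reference values into half-open bins `[b, b + width)` and
#' averages the signed estimation error within each bin; empty bins are
#' omitted. This is the table behind error-versus-reference profiles.
#'
#' @inheritParams error_metrics
#' @param bin_width Bin width, ml/min/100g.
#' @return Tibble with `bin_left`, `bin_center`, `n_voxels`, `mean_error`.
#' @export
binned_error_profile <- function(estimates, reference, bin_width = 10) {
  check_finite_numeric(estimates, "estimates")
  check_finite_numeric(reference, "reference")
  if (length(estimates) != length(reference) || length(estimates) == 0) {
    stop_invalid("`estimates` and `reference` must have equal nonzero length")
  }
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop_invalid("`bin_width` must be positive")
  }
  tibble::tibble(bin_left = floor(reference / bin_width) * bin_width,
                 error = estimates - reference) |>
    dplyr::group_by(.data$bin_left) |>
    dplyr::summarise(n_voxels = dplyr::n(),
                     mean_error = mean(.data$error), .groups = "drop") |>
    dplyr::mutate(bin_center = .data$bin_left + bin_width / 2,
                  .after = "bin_left") |>
    dplyr::arrange(.data$bin_left)
}

#' Histogram of perfusion values
#'
#' Counts per half-open bin `[b, b + width)`, with the sample mean and
#' median attached (attributes `"mean"` and `"median"`, also printed).
#'
#' @param values Perfusion values, ml/min/100g.
#' @param bin_width Bin width, ml/min/100g.
#' @return Tibble of class `perf_histogram` with `bin_left`, `bin_center`,
#'   `count`.
#' @export
perfusion_histogram <- function(values, bin_width = 10) {
  check_finite_numeric(values, "values")
  if (length(values) == 0) stop_invalid("`values` must be nonempty")
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop_invalid("`bin_width` must be positive")
  }
  out <- tibble::tibble(bin_left = floor(values / bin_width) * bin_width) |>
    dplyr::count(.data$bin_left, name = "count") |>
    dplyr::mutate(bin_center = .data$bin_left + bin_width / 2,
                  .after = "bin_left") |>
    dplyr::arrange(.data$bin_left)
  attr(out, "mean") <- mean(values)
  attr(out, "median") <- median(values)
  class(out) <- c("perf_histogram", class(out))
  out
}

#' @export
print.perf_histogram <- function(x, ...) {
  cat(sprintf("Perfusion histogram: mean %.1f, median %.1f ml/min/100g\n",
              attr(x, "mean"), attr(x, "median")))
  NextMethod()
}

#' Benchmark several estimators against a common reference
#'
#' Produces the full comparison report for a set of methods evaluated on
#' identical voxels: one [error_metrics()] row per method (the reference
#' compared against itself first), plus pairwise paired t tests on absolute
#' errors for every method pair.
#'
#' @param data A data frame with one numeric column per method.
#' @param reference Name of the reference column in `data`.
#' @return A `method_comparison_report`: list with `metrics` (tibble, one
#'   method per row), `tests` (tibble of pairwise `paired_accuracy_test`
#'   results among non-reference methods) and `reference`.
#' @export
compare_all <- function(data, reference) {
  data <- tibble::as_tibble(data)
  if (!reference %in% names(data)) {
    stop_invalid(sprintf("reference column `%s` not found", reference))
  }
  if (anyNA(data)) stop_invalid("method columns must be complete on a common voxel set")
  ref <- data[[reference]]
  methods <- names(data)
  metrics <- dplyr::bind_rows(purrr::map(methods, function(m) {
    error_metrics(data[[m]], ref, method = m, reference_name = reference)
  }))
  others <- setdiff(methods, reference)
  pairs <- if (length(others) >= 2) utils::combn(others, 2, simplify = FALSE) else list()
  tests <- dplyr::bind_rows(purrr::map(pairs, function(p) {
    res <- paired_accuracy_test(abs(data[[p[1]]] - ref), abs(data[[p[2]]] - ref))
    dplyr::bind_cols(tibble::tibble(method_a = p[1], method_b = p[2]), res)
  }))
  structure(list(metrics = metrics, tests = tests, reference = reference,
                 n_voxels = length(ref)),
            class = "method_comparison_report")
}

#' @export
print.method_comparison_report <- function(x, ...) {
  cat(sprintf("<method_comparison_report> %d methods vs %s on %d voxels\n",
              nrow(x$metrics), x$reference, x$n_voxels))
  print(x$metrics)
  invisible(x)
}

#' Serialize a comparison report
#'
#' Writes `metrics.csv`, `tests.csv` and `report.json` into a directory.
#'
#' @param report A [compare_all()] result.
#' @param directory Output directory.
#' @return `directory`, invisibly.
#' @export
write_comparison_report <- function(report, directory) {
  stopifnot(inherits(report, "method_comparison_report"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$metrics, file.path(directory, "metrics.csv"))
  if (nrow(report$tests) > 0) {
    readr::write_csv(report$tests, file.path(directory, "tests.csv"))
  }
  jsonlite::write_json(
    list(reference = report$reference, n_voxels = report$n_voxels,
         metrics = report$metrics, tests = report$tests),
    file.path(directory, "report.json"), digits = NA, auto_unbox = TRUE)
  invisible(directory)
}
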