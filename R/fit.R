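#' Configuration for voxelwise least-squares fitting
#'
#' Holds parameter bounds, the single-start ("regular") initial values, the
#' 5 x 5 multigrid of (F, t0) initializations, and optimizer tolerances.
#' The regular fit starts from F = 350 ml/min/100g, t0 = 2 s, minTT = 6 s,
#' E = 0.4, k = 0.15 1/s; the multigrid runs 25 optimizations from all
#' combinations of F in {100, 150, 200, 250, 300} and t0 in {2, 3, 4, 5, 6},
#' with minTT, E, k initialized at the regular-fit defaults, and keeps the
#' run with the lowest residual.
#'
#' @param init Named numeric vector of regular-fit initial values
#'   (F, t0, minTT, E, k).
#' @param F_grid,t0_grid Multigrid initial values for F (ml/min/100g) and
#'   t0 (s).
#' @param lower,upper Named numeric bounds for (F, t0, minTT, E, k). The
#'   defaults generously bracket exercise physiology; the minimal-transit
#'   lower bound of 2 s excludes sub-physiological vascular transits whose
#'   short-plateau fits are pure noise artifacts.
#' @param ftol Relative objective-decrease tolerance.
#' @param xtol Relative step-size tolerance.
#' @param max_iter Maximum optimizer iterations per start.
#' @param cell_scan The frame-sampled model is only piecewise smooth in
#'   (t0, minTT); when `TRUE` (default), each bolus-arrival basin's best
#'   run is finished with an exhaustive scan over the transit-time cell,
#'   local (within one frame) in the arrival cell, so descent cannot stall
#'   on a frame-boundary discontinuity.
#' @return A `fit_config` object.
#' @export
fit_config <- function(init = c(F = 350, t0 = 2, minTT = 6, E = 0.4, k = 0.15),
                       F_grid = c(100, 150, 200, 250, 300),
                       t0_grid = c(2, 3, 4, 5, 6),
                       lower = c(F = 1, t0 = 0, minTT = 2, E = 0.01, k = 0.001),
                       upper = c(F = 600, t0 = 15, minTT = 20, E = 1, k = 1),
                       ftol = 1e-10, xtol = 1e-10, max_iter = 300,
                       cell_scan = TRUE) {
  par_names <- c("F", "t0", "minTT", "E", "k")
  init <- init[par_names]; lower <- lower[par_names]; upper <- upper[par_names]
  check_finite_numeric(init, "init")
  check_finite_numeric(lower, "lower")
  check_finite_numeric(upper, "upper")
  if (length(F_grid) < 1 || length(t0_grid) < 1) {
    stop_invalid("multigrid initial-value grids must be non-empty")
  }
  if (any(init < lower) || any(init > upper)) {
    stop_invalid("bounds must contain the regular-fit initial values")
  }
  if (any(F_grid < lower["F"]) || any(F_grid > upper["F"]) ||
      any(t0_grid < lower["t0"]) || any(t0_grid > upper["t0"])) {
    stop_invalid("bounds must contain the multigrid initial values")
  }
  structure(list(init = init, F_grid = F_grid, t0_grid = t0_grid,
                 lower = lower, upper = upper, ftol = ftol, xtol = xtol,
                 max_iter = as.integer(max_iter),
                 cell_scan = isTRUE(cell_scan)),
            class = "fit_config")
}

# init matrix for a mode: 1 x 5 for regular, |F_grid| x |t0_grid| rows for
# multigrid (F varies fastest, matching row-wise grid enumeration)
init_matrix <- function(config, mode) {
  if (mode == "regular") {
    matrix(config$init, nrow = 1,
           dimnames = list(NULL, names(config$init)))
  } else {
    grid <- expand.grid(F = config$F_grid, t0 = config$t0_grid,
                        KEEP.OUT.ATTRS = FALSE)
    cbind(F = grid$F, t0 = grid$t0, minTT = config$init[["minTT"]],
          E = config$init[["E"]], k = config$init[["k"]])
  }
}

fit_stack <- function(tc, aif, dt, config, mode, keep_start_sse = FALSE) {
  inits <- init_matrix(config, mode)
  fit_voxels_cpp(tc, aif, dt, inits, config$lower, config$upper,
                 config$ftol, config$xtol, config$max_iter,
                 config$cell_scan %||% TRUE, keep_start_sse)
}

voxel_fit_tibble <- function(raw, mode) {
  params <- raw$params
  colnames(params) <- c("F", "t0", "minTT", "E", "k")
  out <- tibble::as_tibble(as.data.frame(params))
  out$rss <- as.numeric(raw$rss)
  # init_index: 0 for the regular fit, 1..25 for the winning multigrid start
  out$init_index <- if (mode == "regular") 0L else as.integer(raw$init_index)
  out$n_iter <- as.integer(raw$n_iter)
  out$converged <- as.logical(raw$converged)
  out
}

#' Fit one voxel from the single configured initialization
#'
#' Bounded Levenberg-Marquardt least squares minimizing the sum of squared
#' differences between the measured TC and [forward_model()] prediction,
#' started from `config$init`.
#'
#' @param tc Measured tissue concentration curve, mM.
#' @param aif Arterial input function, mM, same length and `dt` as `tc`.
#' @param dt Frame interval, s.
#' @param config A [fit_config()].
#' @return A one-row tibble with columns `F`, `t0`, `minTT`, `E`, `k`,
#'   `rss` (residual sum of squares, mM^2), `init_index` (0 for the regular
#'   fit), `n_iter` and `converged`.
#' @export
fit_voxel_regular <- function(tc, aif, dt = 1, config = fit_config()) {
  check_curve(tc, dt, "tc"); check_curve(aif, dt, "aif")
  if (length(tc) != length(aif)) stop_invalid("`tc` and `aif` must share length")
  raw <- fit_stack(matrix(tc, nrow = 1), aif, dt, config, "regular")
  voxel_fit_tibble(raw, "regular")
}

#' Fit one voxel with the 25-start multigrid strategy
#'
#' Runs one bounded least-squares optimization per (F, t0) pair of the
#' 5 x 5 initialization grid and returns the run with the lowest residual;
#' ties break toward the earlier grid entry. Restarting from a grid of
#' initial values escapes the local minima that trap the single-start fit
#' for high-perfusion voxels.
#'
#' @inheritParams fit_voxel_regular
#' @return A one-row tibble as in [fit_voxel_regular()]; `init_index` is the
#'   1-based index of the winning start (row-wise over the F-by-t0 grid,
#'   F varying fastest). The per-start residuals are attached as attribute
#'   `"start_rss"`.
#' @export
fit_voxel_multigrid <- function(tc, aif, dt = 1, config = fit_config()) {
  check_curve(tc, dt, "tc"); check_curve(aif, dt, "aif")
  if (length(tc) != length(aif)) stop_invalid("`tc` and `aif` must share length")
  raw <- fit_stack(matrix(tc, nrow = 1), aif, dt, config, "multigrid",
                   keep_start_sse = TRUE)
  out <- voxel_fit_tibble(raw, "multigrid")
  attr(out, "start_rss") <- as.numeric(raw$start_sse[1, ])
  out
}

#' Fit every masked voxel of a dynamic series
#'
#' @param series Either a 3-D array (rows x cols x frames) of voxel
#'   concentration curves, or a matrix with one masked voxel per row (in
#'   which case `mask` supplies the voxel positions).
#' @param mask Logical or 0/1 matrix marking muscle voxels.
#' @param aif Arterial input function, mM.
#' @param mode `"multigrid"` (default) or `"regular"`.
#' @param dt Frame interval, s.
#' @param config A [fit_config()].
#' @return A `perf_map_fit` object: list with `voxels` (tibble of per-voxel
#'   fits with `row`/`col` positions), `maps` (named list of matrices for
#'   F, t0, minTT, E, k and rss, `NA` outside the mask), `mode`, `config`,
#'   `dims`. Voxels are independent, so the result does not depend on
#'   processing order.
#' @export
fit_map <- function(series, mask, aif, mode = c("multigrid", "regular"),
                    dt = 1, config = fit_config()) {
  mode <- match.arg(mode)
  check_curve(aif, dt, "aif")
  mask <- as_mask(mask)
  tcmat <- series_to_matrix(series, mask, length(aif))
  raw <- if (nrow(tcmat$tc) > 0) {
    fit_stack(tcmat$tc, aif, dt, config, mode)
  } else NULL
  build_map_fit(raw, tcmat$pos, mask, mode, config, dt)
}

#' Fit all voxels of a (simulated or loaded) study
#'
#' Convenience wrapper around [fit_map()] for `perf_study` objects.
#'
#' @param study A `perf_study` (see [generate_cohort()] or [load_study()]).
#' @inheritParams fit_map
#' @return A `perf_map_fit` object.
#' @export
fit_study <- function(study, mode = c("multigrid", "regular"),
                      config = fit_config()) {
  mode <- match.arg(mode)
  stopifnot(inherits(study, "perf_study"))
  raw <- if (nrow(study$tc) > 0) {
    fit_stack(study$tc, study$aif, study$dt, config, mode)
  } else NULL
  pos <- study$voxels[, c("row", "col")]
  build_map_fit(raw, pos, study$mask, mode, config, study$dt)
}

as_mask <- function(mask) {
  if (!is.matrix(mask)) stop_invalid("`mask` must be a matrix")
  mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  mask
}

series_to_matrix <- function(series, mask, n_frames) {
  if (is.array(series) && length(dim(series)) == 3) {
    d <- dim(series)
    if (!all(d[1:2] == dim(mask))) {
      stop_invalid("mask shape must match the image slice shape")
    }
    if (d[3] < n_frames) stop_invalid("series has fewer frames than the AIF")
    idx <- which(mask, arr.ind = TRUE)
    tc <- matrix(0, nrow(idx), n_frames)
    for (v in seq_len(nrow(idx))) {
      tc[v, ] <- series[idx[v, 1], idx[v, 2], seq_len(n_frames)]
    }
    list(tc = tc, pos = tibble::tibble(row = idx[, 1], col = idx[, 2]))
  } else if (is.matrix(series)) {
    if (nrow(series) != sum(mask)) {
      stop_invalid("matrix series must have one row per masked voxel")
    }
    idx <- which(mask, arr.ind = TRUE)
    list(tc = series[, seq_len(n_frames), drop = FALSE],
         pos = tibble::tibble(row = idx[, 1], col = idx[, 2]))
  } else {
    stop_invalid("`series` must be a 3-D array or a voxel-by-frame matrix")
  }
}

build_map_fit <- function(raw, pos, mask, mode, config, dt) {
  dims <- dim(mask)
  if (is.null(raw)) {
    voxels <- tibble::tibble(
      row = integer(), col = integer(), F = numeric(), t0 = numeric(),
      minTT = numeric(), E = numeric(), k = numeric(), rss = numeric(),
      init_index = integer(), n_iter = integer(), converged = logical())
  } else {
    voxels <- dplyr::bind_cols(pos, voxel_fit_tibble(raw, mode))
  }
  maps <- lapply(c("F", "t0", "minTT", "E", "k", "rss"), function(nm) {
    m <- matrix(MAP_SENTINEL, dims[1], dims[2])
    if (nrow(voxels) > 0) m[cbind(voxels$row, voxels$col)] <- voxels[[nm]]
    m
  })
  names(maps) <- c("F", "t0", "minTT", "E", "k", "rss")
  structure(list(voxels = voxels, maps = maps, mode = mode, config = config,
                 dims = dims, dt = dt),
            class = "perf_map_fit")
}

#' @export
print.perf_map_fit <- function(x, ...) {
  cat(sprintf("<perf_map_fit> %s fit, %d voxels on a %d x %d slice\n",
              x$mode, nrow(x$voxels), x$dims[1], x$dims[2]))
  if (nrow(x$voxels) > 0) {
    cat(sprintf("  perfusion: mean %.1f, median %.1f ml/min/100g; %.1f%% converged\n",
                mean(x$voxels$F), median(x$voxels$F),
                100 * mean(x$voxels$converged)))
  }
  invisible(x)
}
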