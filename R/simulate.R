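#' Specification of a simulated arterial input function
#'
#' The first pass is a gamma-variate
#' `A * ((t - ta) / (alpha * beta))^alpha * exp(alpha - (t - ta) / beta)`
#' (peak value `A` at `t = ta + alpha * beta`), plus a dispersed
#' recirculation tail (the first pass convolved with an exponential of time
#' constant `recirculation_tau`, scaled by `recirculation_fraction`).
#' `cardiac_output_factor` models exercise intensity: the first-pass area
#' scales as its inverse, with the amplitude adjusted accordingly, mirroring
#' the inverse relation between cardiac output and first-pass AIF area.
#'
#' @param peak_amplitude First-pass peak amplitude at unit cardiac output
#'   factor, mM.
#' @param arrival_time Bolus arrival in the artery, s.
#' @param shape_alpha,shape_beta Gamma-variate shape (dimensionless) and
#'   timescale (s).
#' @param recirculation_fraction Fraction of the first pass recirculated,
#'   in \[0, 1).
#' @param recirculation_tau Dispersion time constant of the recirculation
#'   tail, s.
#' @param cardiac_output_factor Dimensionless exercise-intensity scaling;
#'   doubling it halves the first-pass area.
#' @return An `aif_spec` object.
#' @export
aif_spec <- function(peak_amplitude = 6, arrival_time = 2, shape_alpha = 3,
                     shape_beta = 2, recirculation_fraction = 0.15,
                     recirculation_tau = 12, cardiac_output_factor = 1) {
  vals <- c(peak_amplitude, arrival_time, shape_alpha, shape_beta,
            recirculation_fraction, recirculation_tau, cardiac_output_factor)
  check_finite_numeric(vals, "aif_spec")
  if (peak_amplitude <= 0 || shape_alpha <= 0 || shape_beta <= 0 ||
      recirculation_fraction < 0 || recirculation_fraction >= 1 ||
      recirculation_tau <= 0 || cardiac_output_factor <= 0 ||
      arrival_time < 0) {
    stop_invalid("invalid aif_spec parameter")
  }
  structure(list(peak_amplitude = peak_amplitude,
                 arrival_time = arrival_time, shape_alpha = shape_alpha,
                 shape_beta = shape_beta,
                 recirculation_fraction = recirculation_fraction,
                 recirculation_tau = recirculation_tau,
                 cardiac_output_factor = cardiac_output_factor),
            class = "aif_spec")
}

#' Generate a simulated arterial input function
#'
#' @param spec An [aif_spec()].
#' @param n Number of frames.
#' @param dt Frame interval, s.
#' @param first_pass_only If `TRUE`, omit the recirculation tail (used e.g.
#'   to integrate the first-pass area).
#' @return Non-negative concentration curve, mM, length `n`.
#' @export
generate_aif <- function(spec, n = 40, dt = 1, first_pass_only = FALSE) {
  stopifnot(inherits(spec, "aif_spec"))
  t <- (seq_len(n) - 1) * dt
  u <- t - spec$arrival_time
  A <- spec$peak_amplitude / spec$cardiac_output_factor
  ab <- spec$shape_alpha * spec$shape_beta
  fp <- ifelse(u > 0,
               A * (u / ab)^spec$shape_alpha *
                 exp(spec$shape_alpha - u / spec$shape_beta),
               0)
  if (first_pass_only || spec$recirculation_fraction == 0) return(fp)
  # recirculation: first pass convolved with a normalized exponential
  h <- exp(-t / spec$recirculation_tau) / spec$recirculation_tau
  tail_len <- length(fp)
  recirc <- dt * vapply(seq_len(tail_len), function(i) {
    sum(fp[1:i] * h[i:1])
  }, numeric(1))
  fp + spec$recirculation_fraction * recirc
}

#' Simulate one voxel's tissue curve with measurement noise
#'
#' Forward-model prediction plus zero-mean Gaussian noise whose standard
#' deviation is `max(clean TC) / snr`; noiseless when `snr` is infinite.
#' Uses R's RNG, so results are reproducible under `set.seed()`.
#'
#' @param params An [irf_params()] object.
#' @param aif Arterial input function, mM.
#' @param snr Signal-to-noise ratio (> 0), or `Inf` for noiseless.
#' @param dt Frame interval, s.
#' @return Noisy TC curve, mM.
#' @export
generate_voxel_tc <- function(params, aif, snr = Inf, dt = 1) {
  if (!is.numeric(snr) || length(snr) != 1 || is.na(snr) || snr <= 0) {
    stop_invalid("`snr` must be positive (possibly Inf)")
  }
  clean <- forward_model(params, aif, dt)
  if (is.infinite(snr)) return(clean)
  clean + rnorm(length(clean), 0, max(clean) / snr)
}

#' Load a cohort specification
#'
#' Bundled presets emulate the cohort structure of an exercise-stimulated
#' DCE-MRI study: `"diverse"` (20 datasets mixing young healthy, elderly
#' healthy and peripheral-artery-disease subjects over several exercise
#' loads), `"homogeneous"` (20 datasets of young healthy subjects at a
#' single moderate load) and `"testing"` (8 held-out datasets with the
#' diverse composition).
#'
#' @param preset Preset name, or a path to a cohort JSON file.
#' @return A `cohort_spec` object (named list).
#' @export
cohort_spec <- function(preset = "diverse") {
  path <- if (file.exists(preset)) preset else
    system.file("extdata", "presets", paste0(preset, ".json"),
                package = "dceperf")
  if (!nzchar(path) || !file.exists(path)) {
    stop_invalid(sprintf("unknown cohort preset or file: %s", preset))
  }
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(spec$n_datasets)) {
    spec$n_datasets <- sum(vapply(seq_len(nrow(spec$groups)), function(i) {
      spec$groups$n_subjects[i] * length(spec$groups$loads[[i]])
    }, numeric(1)))
  }
  if (spec$n_datasets < 1 || spec$snr <= 0) {
    stop_invalid("cohort must have >= 1 dataset and positive SNR")
  }
  structure(spec, class = "cohort_spec")
}

# elliptical multi-region mask; returns integer matrix (0 = background)
region_mask <- function(dims, regions) {
  m <- matrix(0L, dims[1], dims[2])
  rr <- row(m) / dims[1]
  cc <- col(m) / dims[2]
  for (i in seq_len(nrow(regions))) {
    inside <- ((rr - regions$center_row[i]) / regions$radius_row[i])^2 +
      ((cc - regions$center_col[i]) / regions$radius_col[i])^2 <= 1
    m[inside & m == 0L] <- i
  }
  m
}

runif_range <- function(n, range) runif(n, range[1], range[2])

#' Generate a synthetic cohort of simulated studies
#'
#' Each dataset draws an exercise-load-dependent AIF (first-pass area
#' inversely proportional to the cardiac-output factor), a multi-region
#' elliptical muscle mask, per-region median perfusion (base median scaled
#' by exercise load, subject type, region activation and lognormal
#' between-dataset variability), per-voxel true perfusion from a lognormal
#' around the region median, nuisance kinetic parameters from uniform
#' ranges, and finally noisy voxel TC curves via the convolution forward
#' model. Fully reproducible from `(spec, seed)`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer RNG seed; defaults to the preset's `rng_seed`.
#' @param voxels_per_dataset Override the preset's masked-voxel count per
#'   dataset (subsampled from the full mask); `NULL` keeps the preset value,
#'   and `NA` or a value >= the full mask size keeps every masked voxel.
#' @return List of `perf_study` objects, one per dataset. Each holds the
#'   `aif`, the voxel-by-frame `tc` matrix, the logical `mask`, a `voxels`
#'   tibble with positions, region ids and true kinetic parameters, and
#'   provenance (cohort, dataset id, seed, snr).
#' @export
generate_cohort <- function(spec, seed = NULL, voxels_per_dataset = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- as.integer(seed %||% spec$rng_seed)
  n_want <- voxels_per_dataset %||% spec$voxels_per_dataset
  dims <- as.integer(spec$dims)
  regions <- as.data.frame(spec$regions)
  region_map <- region_mask(dims, regions)
  datasets <- expand_datasets(spec)
  withr::with_seed(seed, {
    purrr::map(seq_len(nrow(datasets)), function(i) {
      simulate_dataset(spec, datasets[i, ], region_map, n_want, seed, i)
    })
  })
}

expand_datasets <- function(spec) {
  groups <- spec$groups
  rows <- purrr::map(seq_len(nrow(groups)), function(g) {
    loads <- unlist(groups$loads[[g]])
    tidyr::expand_grid(subject = seq_len(groups$n_subjects[g]),
                       load = loads) |>
      dplyr::mutate(subject_type = groups$subject_type[g])
  })
  out <- dplyr::bind_rows(rows)
  out$dataset_id <- sprintf("%s_%s_s%02d_%s", spec$name, out$subject_type,
                            cumsum(!duplicated(paste(out$subject_type, out$subject))),
                            out$load)
  out$dataset_id <- make.unique(out$dataset_id, sep = "_r")
  out
}

simulate_dataset <- function(spec, meta, region_map, n_want, seed, index) {
  load_factor <- spec$load_factors[[meta$load]]
  subject_factor <- spec$subject_factors[[meta$subject_type]]
  aif_rng <- spec$aif
  cof <- (aif_rng$cof_base + aif_rng$cof_slope * load_factor) *
    rlnorm(1, 0, aif_rng$cof_sdlog)
  aspec <- aif_spec(
    peak_amplitude = runif_range(1, aif_rng$amplitude),
    arrival_time = runif_range(1, aif_rng$arrival),
    shape_alpha = runif_range(1, aif_rng$alpha),
    shape_beta = runif_range(1, aif_rng$beta),
    recirculation_fraction = runif_range(1, aif_rng$recirculation_fraction),
    recirculation_tau = aif_rng$recirculation_tau,
    cardiac_output_factor = cof)
  aif <- generate_aif(aspec, spec$n_frames, spec$dt)

  idx <- which(region_map > 0L, arr.ind = TRUE)
  region <- region_map[region_map > 0L]
  n_full <- nrow(idx)
  if (!is.null(n_want) && !is.na(n_want) && n_want < n_full) {
    keep <- sort(sample.int(n_full, n_want))
    idx <- idx[keep, , drop = FALSE]
    region <- region[keep]
  }
  nv <- nrow(idx)

  dataset_scale <- rlnorm(1, 0, spec$sdlog_dataset)
  region_medians <- spec$base_median_perfusion * load_factor *
    subject_factor * dataset_scale * unlist(spec$region_factors) *
    rlnorm(length(spec$region_factors), 0, spec$sdlog_region)
  F_true <- rlnorm(nv, log(region_medians[region]), spec$sdlog_voxel)
  F_true <- pmin(pmax(F_true, spec$perfusion_clip[1]), spec$perfusion_clip[2])

  nu <- spec$nuisance
  params <- cbind(F = F_true,
                  t0 = runif_range(nv, nu$t0),
                  minTT = runif_range(nv, nu$minTT),
                  E = runif_range(nv, nu$E),
                  k = runif_range(nv, nu$k))
  clean <- forward_model_stack_cpp(params, aif, spec$dt)
  noise_sd <- apply(clean, 1, max) / spec$snr
  tc <- clean + matrix(rnorm(length(clean)), nrow(clean)) * noise_sd

  mask <- matrix(FALSE, dim(region_map)[1], dim(region_map)[2])
  mask[idx] <- TRUE
  voxels <- tibble::tibble(row = idx[, 1], col = idx[, 2], region = region,
                           F = params[, "F"], t0 = params[, "t0"],
                           minTT = params[, "minTT"], E = params[, "E"],
                           k = params[, "k"])
  structure(list(aif = aif, tc = tc, mask = mask, voxels = voxels,
                 dims = dim(region_map), dt = spec$dt,
                 n_frames = spec$n_frames, snr = spec$snr,
                 aif_spec = aspec, cohort = spec$name,
                 dataset_id = meta$dataset_id, subject_type = meta$subject_type,
                 load = meta$load, seed = seed, dataset_index = index),
            class = "perf_study")
}

#' @export
print.perf_study <- function(x, ...) {
  cat(sprintf(
    "<perf_study> %s (%s): %d voxels, %d frames at %g s, SNR %g\n",
    x$dataset_id, x$cohort %||% "?", nrow(x$tc), x$n_frames, x$dt, x$snr))
  invisible(x)
}

#' Pooled true-perfusion values of a cohort
#'
#' @param studies List of `perf_study` objects.
#' @return Numeric vector of all masked voxels' true perfusion.
#' @export
cohort_truth <- function(studies) {
  unlist(purrr::map(studies, function(s) s$voxels$F), use.names = FALSE)
}
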