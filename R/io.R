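#' Write an AIF as a two-column CSV
#'
#' Columns `time_s` and `concentration_mM`, with header. The AIF carries
#' concentration, not raw signal: arterial conversion happens upstream at
#' sampling time.
#'
#' @param aif Concentration curve, mM.
#' @param path Output CSV path.
#' @param dt Frame interval, s.
#' @return `path`, invisibly.
#' @export
write_aif_csv <- function(aif, path, dt = 1) {
  check_curve(aif, dt, "aif")
  readr::write_csv(tibble::tibble(time_s = (seq_along(aif) - 1) * dt,
                                  concentration_mM = aif), path)
  invisible(path)
}

#' Read an AIF CSV
#'
#' @param path CSV with columns `time_s`, `concentration_mM`.
#' @return List with `aif` (numeric) and `dt` (s).
#' @export
read_aif_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_s", "concentration_mM") %in% names(x))) {
    stop_invalid("AIF CSV needs columns time_s and concentration_mM")
  }
  dt <- if (nrow(x) > 1) diff(x$time_s[1:2]) else 1
  list(aif = x$concentration_mM, dt = dt)
}

write_map_nifti <- function(map, path) {
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(map), dim = dim(map))),
                     path, datatype = "float")
  invisible(path)
}

read_map_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) > 2) dim(arr) <- dim(arr)[1:2]
  arr
}

#' Export a simulated study to disk
#'
#' Writes the full on-disk form of a study: the dynamic NIfTI series in
#' signal units (converted with [concentration_to_signal()] against a
#' constant proton-density image, so re-loading exercises the whole
#' conversion pipeline), the proton-density and mask NIfTIs, the AIF CSV,
#' per-parameter truth maps, and a JSON manifest with seed, acquisition
#' parameters and provenance.
#'
#' @param study A `perf_study`.
#' @param directory Output directory (created if missing).
#' @param acq An [acquisition_params()] object.
#' @param proton_density Constant proton-density value for the synthetic
#'   reference image.
#' @return `directory`, invisibly.
#' @export
export_study <- function(study, directory, acq = acquisition_params(),
                         proton_density = 1000) {
  stopifnot(inherits(study, "perf_study"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  dims <- study$dims
  n <- study$n_frames

  series <- array(0, dim = c(dims[1], dims[2], n))
  conc <- array(0, dim = c(dims[1], dims[2], n))
  vox <- cbind(study$voxels$row, study$voxels$col)
  for (fr in seq_len(n)) {
    sl <- matrix(0, dims[1], dims[2])
    sl[vox] <- pmax(study$tc[, fr], 0) # signal model needs C >= 0
    conc[, , fr] <- sl
    series[, , fr] <- concentration_to_signal(sl, proton_density, acq)
  }
  RNifti::writeNifti(RNifti::asNifti(series),
                     file.path(directory, "dynamic.nii"), datatype = "float")
  pd <- matrix(proton_density, dims[1], dims[2])
  write_map_nifti(pd, file.path(directory, "pd.nii"))
  write_map_nifti(study$mask * 1, file.path(directory, "mask.nii"))
  write_aif_csv(study$aif, file.path(directory, "aif.csv"), study$dt)
  for (nm in c("F", "t0", "minTT", "E", "k")) {
    m <- matrix(NA_real_, dims[1], dims[2])
    m[vox] <- study$voxels[[nm]]
    write_map_nifti(m, file.path(directory, paste0("truth_", nm, ".nii")))
  }
  manifest <- list(format = "dceperf_study", version = 1L,
                   cohort = study$cohort, dataset_id = study$dataset_id,
                   seed = study$seed, dataset_index = study$dataset_index,
                   snr = study$snr, dt = study$dt, n_frames = n,
                   dims = dims, proton_density = proton_density,
                   acquisition = unclass(acq),
                   software = as.character(utils::packageVersion("dceperf")))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(directory)
}

#' Load a study directory
#'
#' Reads the dynamic series, proton-density image, mask and AIF written by
#' [export_study()] (or assembled by hand in the same layout), converts
#' voxel signals to concentration with [signal_to_concentration()], and
#' truncates the series to the first 40 frames (a warning is logged when
#' more are present). Truth maps, when present, are attached to the voxel
#' table.
#'
#' @param directory Study directory containing `manifest.json`.
#' @return A `perf_study`.
#' @export
load_study <- function(directory) {
  manifest_path <- file.path(directory, "manifest.json")
  if (!file.exists(manifest_path)) {
    rlang::abort(sprintf("no manifest.json in %s", directory),
                 class = "dceperf_missing_file")
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  acq <- as_acquisition_params(manifest$acquisition)
  n_frames <- manifest$n_frames %||% 40

  series <- as.array(RNifti::readNifti(file.path(directory, "dynamic.nii")))
  if (dim(series)[3] > n_frames) {
    rlang::warn(sprintf("series has %d frames; using the first %d",
                        dim(series)[3], n_frames))
  } else if (dim(series)[3] < n_frames) {
    rlang::abort("dynamic series has fewer frames than the manifest declares",
                 class = "dceperf_invalid_argument")
  }
  series <- series[, , seq_len(n_frames), drop = FALSE]
  mask <- read_map_nifti(file.path(directory, "mask.nii")) > 0
  pd <- read_map_nifti(file.path(directory, "pd.nii"))
  if (!all(dim(mask) == dim(series)[1:2]) || !all(dim(pd) == dim(mask))) {
    stop_invalid("mask/proton-density shape does not match the dynamic series")
  }
  aif_in <- read_aif_csv(file.path(directory, "aif.csv"))
  aif <- aif_in$aif[seq_len(min(n_frames, length(aif_in$aif)))]

  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) rlang::warn("mask excludes every voxel")
  tc <- matrix(0, nrow(idx), n_frames)
  for (fr in seq_len(n_frames)) {
    sl <- signal_to_concentration(series[, , fr][idx], pd[idx], acq)
    tc[, fr] <- sl
  }
  voxels <- tibble::tibble(row = idx[, 1], col = idx[, 2])
  for (nm in c("F", "t0", "minTT", "E", "k")) {
    p <- file.path(directory, paste0("truth_", nm, ".nii"))
    if (file.exists(p)) voxels[[nm]] <- read_map_nifti(p)[idx]
  }
  structure(list(aif = aif, tc = tc, mask = mask, voxels = voxels,
                 dims = dim(mask), dt = aif_in$dt, n_frames = n_frames,
                 snr = manifest$snr %||% NA_real_,
                 aif_spec = NULL, cohort = manifest$cohort,
                 dataset_id = manifest$dataset_id, seed = manifest$seed,
                 dataset_index = manifest$dataset_index),
            class = "perf_study")
}

#' Write fitted parameter maps and a provenance sidecar
#'
#' One float32 NIfTI per kinetic parameter plus the residual map, and a
#' JSON sidecar recording the fit configuration, mode and software version.
#'
#' @param fit A `perf_map_fit`.
#' @param directory Output directory.
#' @return `directory`, invisibly.
#' @export
write_fit_maps <- function(fit, directory) {
  stopifnot(inherits(fit, "perf_map_fit"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(fit$maps)) {
    write_map_nifti(fit$maps[[nm]], file.path(directory, paste0(nm, ".nii")))
  }
  sidecar <- list(format = "dceperf_fit", mode = fit$mode,
                  config = lapply(unclass(fit$config), unname),
                  n_voxels = nrow(fit$voxels),
                  software = as.character(utils::packageVersion("dceperf")))
  jsonlite::write_json(sidecar, file.path(directory, "fit.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(directory)
}

#' Save / load a training set container
#'
#' Single-file container holding the feature matrix, labels, provenance and
#' grid of a [assemble_training_set()] result.
#'
#' @param train A `perf_training_set`.
#' @param path Output file (RDS).
#' @return `path` (write) or the training set (read).
#' @export
write_training_set <- function(train, path) {
  stopifnot(inherits(train, "perf_training_set"))
  saveRDS(train, path)
  invisible(path)
}

#' @rdname write_training_set
#' @export
read_training_set <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "perf_training_set"))
  x
}
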