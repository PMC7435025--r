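#' End-to-end training-strategy benchmark on synthetic cohorts
#'
#' Reproduces, at a configurable synthetic scale, the comparison of
#' perfusion estimators: multigrid fitting (the reference, `F0`), regular
#' single-start fitting (`F1`), and networks trained on the diverse cohort
#' with multigrid labels (`N1`), the homogeneous cohort with multigrid
#' labels (`N2`), the combined cohorts (`N3`), and the diverse cohort with
#' regular-fit labels (`N4`). All networks are evaluated on the held-out
#' testing cohort against its multigrid reference.
#'
#' @param seed Integer seed controlling cohort generation and network
#'   training.
#' @param voxels_per_dataset Masked voxels simulated per dataset; `NA`
#'   keeps the full ~2,600-voxel mask of each preset.
#' @param include_n3 Train the combined-cohort network as well (slightly
#'   slower).
#' @param config Fit configuration for all model fitting.
#' @param net_config Base network configuration; its `rng_seed` is replaced
#'   by seeds derived from `seed`.
#' @return List with `estimates` (tibble of per-voxel truth and every
#'   method's estimate on the testing cohort), `report`
#'   ([compare_all()] result against `F0`), `profiles` (binned error
#'   profiles per method vs `F0`), `nets` (the trained `perf_net`s) and
#'   `cohorts` (pooled truth summaries).
#' @export
run_training_benchmark <- function(seed = 1L, voxels_per_dataset = 250,
                                   include_n3 = TRUE,
                                   config = fit_config(),
                                   net_config = network_config()) {
  seed <- as.integer(seed)
  sub <- function(k) as.integer((as.numeric(seed) * 1000 + k) %% 2147483629L)

  diverse <- generate_cohort(cohort_spec("diverse"), seed = sub(1),
                             voxels_per_dataset = voxels_per_dataset)
  homog <- generate_cohort(cohort_spec("homogeneous"), seed = sub(2),
                           voxels_per_dataset = voxels_per_dataset)
  testing <- generate_cohort(cohort_spec("testing"), seed = sub(3),
                             voxels_per_dataset = voxels_per_dataset)

  fits_div_mg <- lapply(diverse, fit_study, mode = "multigrid", config = config)
  fits_div_reg <- lapply(diverse, fit_study, mode = "regular", config = config)
  fits_hom_mg <- lapply(homog, fit_study, mode = "multigrid", config = config)
  fits_test_mg <- lapply(testing, fit_study, mode = "multigrid", config = config)
  fits_test_reg <- lapply(testing, fit_study, mode = "regular", config = config)

  train_n1 <- assemble_training_set(diverse, fits_div_mg, "multigrid")
  train_n2 <- assemble_training_set(homog, fits_hom_mg, "multigrid")
  train_n4 <- assemble_training_set(diverse, fits_div_reg, "regular")

  with_seed_cfg <- function(k) {
    cfg <- net_config
    cfg$rng_seed <- sub(10 + k)
    cfg
  }
  nets <- list(N1 = train_network(train_n1, with_seed_cfg(1)),
               N2 = train_network(train_n2, with_seed_cfg(2)),
               N4 = train_network(train_n4, with_seed_cfg(4)))
  if (include_n3) {
    train_n3 <- structure(list(
      features = rbind(train_n1$features, train_n2$features),
      labels = c(train_n1$labels, train_n2$labels),
      provenance = dplyr::bind_rows(train_n1$provenance, train_n2$provenance),
      label_source = "multigrid", grid = train_n1$grid),
      class = "perf_training_set")
    nets$N3 <- train_network(train_n3, with_seed_cfg(3))
  }

  estimates <- dplyr::bind_rows(purrr::map(seq_along(testing), function(i) {
    s <- testing[[i]]
    out <- tibble::tibble(dataset_id = s$dataset_id,
                          truth = s$voxels$F,
                          F0 = fits_test_mg[[i]]$voxels$F,
                          F1 = fits_test_reg[[i]]$voxels$F)
    for (nm in names(nets)) {
      out[[nm]] <- predict_study(nets[[nm]], s)$voxels$F
    }
    out
  }))

  method_cols <- c("F0", "F1", names(nets))
  report <- compare_all(estimates[method_cols], reference = "F0")
  profiles <- dplyr::bind_rows(purrr::map(setdiff(method_cols, "F0"), function(m) {
    dplyr::mutate(binned_error_profile(estimates[[m]], estimates$F0),
                  method = m)
  }))
  cohorts <- tibble::tibble(
    cohort = c("diverse", "homogeneous", "testing"),
    n_voxels = c(length(cohort_truth(diverse)), length(cohort_truth(homog)),
                 length(cohort_truth(testing))),
    mean_F = c(mean(cohort_truth(diverse)), mean(cohort_truth(homog)),
               mean(cohort_truth(testing))),
    median_F = c(median(cohort_truth(diverse)), median(cohort_truth(homog)),
                 median(cohort_truth(testing))))

  list(estimates = estimates, report = report, profiles = profiles,
       nets = nets, cohorts = cohorts, seed = seed)
}
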