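# shared fixtures: small deterministic inputs built in code

fixture_aif <- function(n = 40, dt = 1) {
  generate_aif(aif_spec(), n = n, dt = dt)
}

# n voxels of ground-truth kinetic parameters in the simulator's ranges
fixture_params <- function(n, seed = 42) {
  withr::with_seed(seed, {
    cbind(F = runif(n, 20, 380), t0 = runif(n, 1.5, 6.5),
          minTT = runif(n, 3, 10), E = runif(n, 0.2, 0.6),
          k = runif(n, 0.05, 0.3))
  })
}

fixture_tc_stack <- function(params, aif, snr = Inf, seed = 1, dt = 1) {
  clean <- t(vapply(seq_len(nrow(params)), function(i) {
    forward_model(do.call(irf_params, as.list(params[i, ])), aif, dt)
  }, numeric(length(aif))))
  if (is.infinite(snr)) return(clean)
  withr::with_seed(seed, {
    clean + matrix(rnorm(length(clean)), nrow(clean)) *
      apply(clean, 1, max) / snr
  })
}

# small learnable classification set: label index is a simple smooth
# function of the first half of the feature vector
fixture_training_set <- function(n = 2000, seed = 3) {
  withr::with_seed(seed, {
    X <- matrix(runif(n * 80), n, 80)
    y <- pmin(39L, pmax(0L, as.integer(round(rowMeans(X[, 1:40]) * 39))))
    list(features = X, labels = y, grid = perfusion_class_grid())
  })
}

# tiny one-study cohort for io / pipeline tests
fixture_study <- function(voxels = 25, seed = 5) {
  spec <- cohort_spec("testing")
  generate_cohort(spec, seed = seed, voxels_per_dataset = voxels)[[1]]
}
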