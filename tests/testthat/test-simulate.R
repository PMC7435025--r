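test_that("simulated AIF has the stated gamma-variate first-pass shape", {
  spec <- aif_spec(peak_amplitude = 6, arrival_time = 3, shape_alpha = 3,
                   shape_beta = 2, recirculation_fraction = 0)
  aif <- generate_aif(spec, n = 80, dt = 0.25)
  # zero before arrival
  expect_true(all(aif[(0:79) * 0.25 <= 3] == 0))
  # peak equals the amplitude, at arrival + alpha*beta, within the grid
  expect_equal(max(aif), 6, tolerance = 0.01)
  expect_equal((which.max(aif) - 1) * 0.25, 3 + 3 * 2, tolerance = 0.25)
  expect_true(all(aif >= 0))
  # recirculation adds a non-negative tail
  spec2 <- aif_spec(arrival_time = 3, recirculation_fraction = 0.2)
  full <- generate_aif(spec2, n = 80, dt = 0.25)
  fp <- generate_aif(spec2, n = 80, dt = 0.25, first_pass_only = TRUE)
  expect_true(all(full >= fp - 1e-12))
})

test_that("doubling the cardiac-output factor halves the first-pass area", {
  base <- aif_spec(cardiac_output_factor = 1, recirculation_fraction = 0)
  fast <- aif_spec(cardiac_output_factor = 2, recirculation_fraction = 0)
  dt <- 0.1
  a1 <- generate_aif(base, n = 400, dt = dt)
  a2 <- generate_aif(fast, n = 400, dt = dt)
  # numeric integration oracle over the whole (first-pass-only) curve
  expect_equal(sum(a2) * dt / (sum(a1) * dt), 0.5, tolerance = 0.02)
})

test_that("voxel TC noise has the prescribed standard deviation", {
  p <- irf_params(200, 2, 6, 0.4, 0.15)
  aif <- fixture_aif(n = 40)
  clean <- generate_voxel_tc(p, aif, snr = Inf)
  expect_equal(clean, forward_model(p, aif))
  # law-of-large-numbers check of the noise scale over many frames
  long_aif <- rep(aif, length.out = 10000)
  withr::with_seed(12, {
    # draw many replicates of the 40-frame curve and pool the residuals
    resid <- unlist(lapply(1:250, function(i) {
      generate_voxel_tc(p, aif, snr = 20) - clean
    }))
  })
  expect_equal(sd(resid), max(clean) / 20, tolerance = 0.05)
  # seeded reproducibility
  a <- withr::with_seed(99, generate_voxel_tc(p, aif, snr = 10))
  b <- withr::with_seed(99, generate_voxel_tc(p, aif, snr = 10))
  expect_identical(a, b)
  expect_error(generate_voxel_tc(p, aif, snr = 0),
               class = "dceperf_invalid_argument")
})

test_that("cohorts have the documented structure and counts", {
  spec <- cohort_spec("testing")
  studies <- generate_cohort(spec, seed = 4, voxels_per_dataset = 16)
  expect_length(studies, 8) # 4 + 2 + 2 scans
  st <- studies[[1]]
  expect_s3_class(st, "perf_study")
  expect_equal(nrow(st$tc), 16)
  expect_equal(ncol(st$tc), 40)
  expect_equal(sum(st$mask), 16)
  expect_equal(nrow(st$voxels), 16)
  expect_true(all(c("F", "t0", "minTT", "E", "k") %in% names(st$voxels)))
  # diverse preset: 20 datasets
  expect_length(generate_cohort(cohort_spec("diverse"), seed = 1,
                                voxels_per_dataset = 4), 20)
})

test_that("cohort generation is exactly reproducible from (spec, seed)", {
  spec <- cohort_spec("diverse")
  a <- generate_cohort(spec, seed = 123, voxels_per_dataset = 30)
  b <- generate_cohort(spec, seed = 123, voxels_per_dataset = 30)
  expect_identical(lapply(a, function(s) s$tc), lapply(b, function(s) s$tc))
  expect_identical(lapply(a, function(s) s$voxels), lapply(b, function(s) s$voxels))
  c <- generate_cohort(spec, seed = 124, voxels_per_dataset = 30)
  expect_false(identical(a[[1]]$tc, c[[1]]$tc))
})

test_that("preset perfusion distributions land in their calibration windows", {
  # pooled statistics at full cohort size concentrate tightly; windows per
  # the calibration targets (diverse mean 95-120 / median 70-95;
  # homogeneous mean 80-105 / median 50-75)
  div <- cohort_truth(generate_cohort(cohort_spec("diverse"), seed = 2025,
                                      voxels_per_dataset = 600))
  hom <- cohort_truth(generate_cohort(cohort_spec("homogeneous"), seed = 2025,
                                      voxels_per_dataset = 600))
  expect_gte(length(div), 10000)
  expect_gt(mean(div), 95); expect_lt(mean(div), 120)
  expect_gt(median(div), 70); expect_lt(median(div), 95)
  expect_gt(mean(hom), 80); expect_lt(mean(hom), 105)
  expect_gt(median(hom), 50); expect_lt(median(hom), 75)
  # diversity contract: the diverse cohort has the fatter high-flow tail
  expect_gt(mean(div > 200), mean(hom > 200))
})

test_that("exercise load scales down the first-pass AIF area across a cohort", {
  studies <- generate_cohort(cohort_spec("diverse"), seed = 31,
                             voxels_per_dataset = 4)
  spec <- cohort_spec("diverse")
  area <- vapply(studies, function(s) {
    fp <- generate_aif(s$aif_spec, spec$n_frames, spec$dt,
                       first_pass_only = TRUE)
    sum(fp) * spec$dt
  }, numeric(1))
  load <- vapply(studies, function(s) spec$load_factors[[s$load]], numeric(1))
  # high-load scans have, on average, smaller first-pass area
  expect_lt(mean(area[load >= 2.6]), mean(area[load <= 1.0]))
})
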