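test_that("perfusion grid has the stated endpoints and spacing", {
  g <- perfusion_class_grid()
  expect_length(g$values, 40)
  expect_equal(g$values[1], 10)
  expect_equal(g$values[40], 400)
  expect_equal(g$spacing, 10)
  expect_error(perfusion_class_grid(seq(10, 400, length.out = 39)),
               class = "dceperf_invalid_argument")
})

test_that("discretization maps to nearest grid value with ties rounding up", {
  expect_equal(discretize_perfusion(10), 0L)
  expect_equal(discretize_perfusion(400), 39L)
  expect_equal(discretize_perfusion(72.4), 6L)  # nearest of {70, 80} is 70
  expect_equal(discretize_perfusion(75), 7L)    # tie rounds up to 80
  # clipping outside the range
  expect_equal(discretize_perfusion(3), 0L)
  expect_equal(discretize_perfusion(1500), 39L)
  expect_error(discretize_perfusion(Inf), class = "dceperf_invalid_argument")
  expect_error(discretize_perfusion(-5), class = "dceperf_invalid_argument")
})

test_that("class decoding round-trips over all 40 classes", {
  g <- perfusion_class_grid()
  expect_equal(class_to_perfusion(0L), 10)
  expect_equal(class_to_perfusion(39L), 400)
  for (i in 0:39) {
    expect_identical(discretize_perfusion(class_to_perfusion(i, g), g), i)
  }
  expect_error(class_to_perfusion(40L), class = "dceperf_invalid_argument")
  expect_error(class_to_perfusion(-1L), class = "dceperf_invalid_argument")
})

test_that("feature vectors concatenate TC then AIF in frame order", {
  expect_equal(build_feature_vector(1:40, 41:80), 1:80)
  expect_equal(build_feature_vector(rep(0, 40), rep(0, 40)), rep(0, 80))
  expect_error(build_feature_vector(1:39, 1:40),
               class = "dceperf_invalid_argument")
})

test_that("training reduces the loss, is seeded-reproducible, and learns a
           constant-label set", {
  train <- fixture_training_set(n = 1500)
  cfg <- network_config(n_epochs = 6, rng_seed = 7)
  net <- train_network(train, cfg)
  expect_equal(nrow(net$log), 6)
  expect_lt(net$log$loss[6], net$log$loss[1])
  net2 <- train_network(train, cfg)
  expect_identical(net$weights, net2$weights)
  # different seed gives different weights
  net3 <- train_network(train, network_config(n_epochs = 6, rng_seed = 8))
  expect_false(identical(net$weights, net3$weights))
  # degenerate learnability
  const <- list(features = train$features[1:400, ],
                labels = rep(23L, 400), grid = perfusion_class_grid())
  netc <- train_network(const, network_config(n_epochs = 8, rng_seed = 1))
  cls <- apply(train$features[1:400, ], 1,
               function(f) predict_voxel(netc, f)$class)
  expect_true(all(cls == 23L))
  expect_error(train_network(list(features = matrix(0, 0, 80), labels = integer())),
               class = "dceperf_invalid_argument")
})

test_that("prediction yields normalized probabilities and grid-valued output", {
  train <- fixture_training_set(n = 800)
  net <- train_network(train, network_config(n_epochs = 3, rng_seed = 2))
  withr::with_seed(9, feats <- matrix(runif(20 * 80), 20, 80))
  for (i in 1:5) {
    p <- predict_voxel(net, feats[i, ])
    expect_equal(sum(p$probabilities), 1, tolerance = 1e-6)
    expect_true(all(p$probabilities >= 0))
    expect_true(p$perfusion %in% net$grid$values)
    expect_equal(p$perfusion, class_to_perfusion(p$class, net$grid))
  }
  # inference is deterministic
  expect_identical(predict_voxel(net, feats[1, ]),
                   predict_voxel(net, feats[1, ]))
  expect_error(predict_voxel(net, feats[1, 1:79]),
               class = "dceperf_invalid_argument")
})

test_that("map prediction is masked, grid-valued and order-independent", {
  train <- fixture_training_set(n = 800)
  net <- train_network(train, network_config(n_epochs = 3, rng_seed = 2))
  study <- fixture_study(voxels = 30)
  pred <- predict_study(net, study)
  expect_equal(nrow(pred$voxels), 30)
  expect_true(all(pred$voxels$F %in% net$grid$values))
  expect_equal(sum(!is.na(pred$map)), 30)
  expect_true(all(is.na(pred$map[!study$mask])))
  # permuting voxel order leaves per-voxel predictions unchanged
  perm <- rev(seq_len(nrow(study$tc)))
  probs1 <- dceperf:::net_probabilities(net, cbind(
    study$tc, matrix(study$aif, nrow(study$tc), 40, byrow = TRUE)))
  probs2 <- dceperf:::net_probabilities(net, cbind(
    study$tc, matrix(study$aif, nrow(study$tc), 40, byrow = TRUE))[perm, ])
  expect_equal(probs1[perm, ], probs2, tolerance = 1e-12)
  # empty mask gives an all-sentinel map
  empty <- predict_map(net, matrix(0, 0, 40),
                       matrix(FALSE, study$dims[1], study$dims[2]), study$aif)
  expect_equal(nrow(empty$voxels), 0)
  expect_true(all(is.na(empty$map)))
})

test_that("training sets assemble one record per voxel with chosen labels", {
  studies <- generate_cohort(cohort_spec("testing"), seed = 21,
                             voxels_per_dataset = 20)[1:2]
  fits_mg <- lapply(studies, fit_study, mode = "multigrid")
  fits_reg <- lapply(studies, fit_study, mode = "regular")
  tr_mg <- assemble_training_set(studies, fits_mg, "multigrid")
  tr_reg <- assemble_training_set(studies, fits_reg, "regular")
  expect_equal(length(tr_mg$labels), 40)
  expect_equal(dim(tr_mg$features), c(40, 80))
  expect_equal(nrow(tr_mg$provenance), 2)
  # same features, generally different labels across label sources
  expect_identical(tr_mg$features, tr_reg$features)
  expect_equal(tr_mg$labels,
               discretize_perfusion(unlist(lapply(fits_mg, function(f) f$voxels$F))))
  # voxels of one study share the AIF block of the feature matrix
  expect_equal(tr_mg$features[1, 41:80], tr_mg$features[2, 41:80])
  # cohort merge concatenates records
  merged <- assemble_training_set(c(studies, studies),
                                  c(fits_mg, fits_mg), "multigrid")
  expect_equal(length(merged$labels), 80)
  expect_error(assemble_training_set(studies, fits_reg, "multigrid"),
               class = "dceperf_invalid_argument")
})

test_that("network serialization round-trips weights and metadata", {
  train <- fixture_training_set(n = 500)
  net <- train_network(train, network_config(n_epochs = 2, rng_seed = 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_perf_net(net, path)
  back <- read_perf_net(path)
  expect_equal(back$weights, net$weights, tolerance = 1e-12)
  expect_equal(back$grid$values, net$grid$values)
  withr::with_seed(10, f <- runif(80))
  expect_equal(predict_voxel(back, f)$probabilities,
               predict_voxel(net, f)$probabilities, tolerance = 1e-9)
})
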