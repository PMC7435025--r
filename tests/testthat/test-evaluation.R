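test_that("error metrics match a brute-force oracle on random data", {
  withr::with_seed(11, {
    est <- runif(1000, 10, 400)
    ref <- est + rnorm(1000, 2, 25)
  })
  m <- error_metrics(est, ref, method = "x")
  # independent elementwise recomputation
  d <- est - ref
  expect_equal(m$mean_error, sum(d) / 1000, tolerance = 1e-12)
  expect_equal(m$rmse, sqrt(sum(d^2) / 1000), tolerance = 1e-12)
  expect_equal(m$mae, sum(abs(d)) / 1000, tolerance = 1e-12)
  expect_equal(m$pearson_r,
               sum((est - mean(est)) * (ref - mean(ref))) /
                 sqrt(sum((est - mean(est))^2) * sum((ref - mean(ref))^2)),
               tolerance = 1e-12)
  expect_lte(m$mae, m$rmse)
  expect_gte(m$rmse, abs(m$mean_error))
})

test_that("identical estimates give zero errors and perfect correlation", {
  x <- c(10, 50, 90, 200)
  m <- error_metrics(x, x)
  expect_equal(m$mean_error, 0)
  expect_equal(m$rmse, 0)
  expect_equal(m$mae, 0)
  expect_equal(m$pearson_r, 1)
  m2 <- error_metrics(c(110, 190), c(100, 200))
  expect_equal(m2$mean_error, 0)
  expect_equal(m2$mae, 10)
  expect_equal(m2$rmse, 10)
})

test_that("error metrics reject degenerate input", {
  expect_error(error_metrics(1:3, 1:4), class = "dceperf_invalid_argument")
  expect_error(error_metrics(numeric(0), numeric(0)),
               class = "dceperf_invalid_argument")
  expect_error(error_metrics(rep(5, 4), 1:4),
               class = "dceperf_degenerate_input")
})

test_that("metrics are invariant under simultaneous permutation", {
  withr::with_seed(2, {
    est <- runif(300, 0, 300); ref <- runif(300, 0, 300)
    perm <- sample(300)
  })
  m1 <- error_metrics(est, ref)
  m2 <- error_metrics(est[perm], ref[perm])
  expect_equal(m1[-(1:2)], m2[-(1:2)], tolerance = 1e-12)
})

test_that("paired accuracy test matches theory and is antisymmetric", {
  withr::with_seed(3, {
    a <- abs(rnorm(100, 20, 5))
  })
  b <- a + 3 # constant accuracy gap
  # no variance in the gap -> degenerate
  expect_error(paired_accuracy_test(a, a), class = "dceperf_degenerate_input")
  b <- a + 3 + rnorm(100, 0, 0.01)
  res <- paired_accuracy_test(a, b)
  expect_lt(res$p_value, 1e-6)
  # matches stats::t.test directly
  tt <- t.test(a - b)
  expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
  # swapping negates t, preserves p
  res2 <- paired_accuracy_test(b, a)
  expect_equal(res2$statistic, -res$statistic, tolerance = 1e-12)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-12)
})

test_that("binned error profile matches a group-by oracle", {
  withr::with_seed(4, {
    ref <- runif(800, 5, 320)
    est <- ref + rnorm(800, 0, 15)
  })
  prof <- binned_error_profile(est, ref, bin_width = 10)
  oracle <- tapply(est - ref, floor(ref / 10) * 10, mean)
  expect_equal(prof$mean_error, as.numeric(oracle[as.character(prof$bin_left)]),
               tolerance = 1e-12)
  expect_equal(prof$bin_center, prof$bin_left + 5)
  expect_equal(sum(prof$n_voxels), 800)
  # voxel-count-weighted mean of bin errors equals the global mean error
  expect_equal(sum(prof$mean_error * prof$n_voxels) / 800, mean(est - ref),
               tolerance = 1e-9)
  # single-bin case collapses to the global mean error
  one <- binned_error_profile(est[1:5], rep(42, 5))
  expect_equal(nrow(one), 1)
  expect_equal(one$mean_error, mean(est[1:5] - 42))
  expect_error(binned_error_profile(est, ref, bin_width = 0),
               class = "dceperf_invalid_argument")
})

test_that("perfusion histogram counts, mean and median are exact", {
  withr::with_seed(5, values <- runif(500, 0, 350))
  h <- perfusion_histogram(values)
  expect_equal(sum(h$count), 500)
  expect_equal(attr(h, "mean"), mean(values))
  expect_equal(attr(h, "median"), median(values))
  oracle <- table(floor(values / 10) * 10)
  expect_equal(h$count, unname(as.integer(oracle[as.character(h$bin_left)])))
  hc <- perfusion_histogram(rep(77, 9))
  expect_equal(nrow(hc), 1)
  expect_equal(hc$bin_left, 70)
  expect_equal(attr(hc, "mean"), 77)
  expect_error(perfusion_histogram(numeric(0)),
               class = "dceperf_invalid_argument")
})

test_that("compare_all emits one row per method and pairwise tests", {
  withr::with_seed(6, {
    ref <- runif(400, 20, 300)
    df <- tibble::tibble(F0 = ref,
                         A = ref + rnorm(400, 0, 10),
                         B = ref + rnorm(400, 5, 20))
  })
  rep <- compare_all(df, reference = "F0")
  expect_equal(nrow(rep$metrics), 3)
  self <- rep$metrics[rep$metrics$method == "F0", ]
  expect_equal(self$mae, 0)
  expect_equal(self$pearson_r, 1)
  expect_equal(nrow(rep$tests), 1) # A vs B
  expect_true(all(rep$metrics$mae <= rep$metrics$rmse + 1e-12))
  # serialization round trip
  dir <- withr::local_tempdir()
  write_comparison_report(rep, dir)
  expect_true(file.exists(file.path(dir, "metrics.csv")))
  back <- readr::read_csv(file.path(dir, "metrics.csv"), show_col_types = FALSE)
  expect_equal(back$mae, rep$metrics$mae, tolerance = 1e-9)
})
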