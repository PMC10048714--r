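test_that("reflectance calibration obeys the reference identities", {
  W <- c(100, 200, 300)
  B <- c(10, 20, 30)
  expect_equal(compute_reflectance(W, W, B), rep(1, 3))
  expect_equal(compute_reflectance(B, W, B), rep(0, 3))
  expect_equal(compute_reflectance((W + B) / 2, W, B), rep(0.5, 3))
})

test_that("degenerate calibration names the offending band", {
  W <- c(100, 50, 300)
  B <- c(10, 50, 30)
  expect_error(compute_reflectance(c(1, 2, 3), W, B), "band index 2")
  expect_error(compute_reflectance(c(1, 2), W, B), "same length")
})

test_that("scan averaging is the elementwise mean with strict input checks", {
  s <- c(0.2, 0.4, 0.6)
  expect_equal(average_scans(list(s, s, s, s, s)), s)
  expect_equal(average_scans(list(rep(0, 4), rep(1, 4))), rep(0.5, 4))
  expect_error(average_scans(list()), "non-empty")
  expect_error(average_scans(list(1:3, 1:4)), "same length")
})

test_that("averaging five noisy scans shrinks the noise sd by sqrt(5)", {
  sigma <- 0.05
  dev <- withr::with_seed(99, {
    truth <- runif(10000)
    scans <- lapply(1:5, function(i) truth + rnorm(10000, 0, sigma))
    average_scans(scans) - truth
  })
  expect_equal(sd(dev), sigma / sqrt(5), tolerance = 0.05)
})

test_that("the 7:3 split of 480 balanced samples is 336/144, stratified 168/72", {
  ds <- generate_paired_dataset(synthetic_config(
    n_per_class = 240, n_bands = 4L, image_size_px = 16L,
    spectral_noise_sd = 0, image_noise_sd = 0, scatter_sd = 0,
    blotches = FALSE, seed = 1
  ))
  sp <- split_dataset(ds, 0.7, seed = 3)
  expect_equal(nrow(sp$train), 336L)
  expect_equal(nrow(sp$validation), 144L)
  expect_equal(unname(c(table(sp$train$label))), c(168L, 168L))
  expect_equal(unname(c(table(sp$validation$label))), c(72L, 72L))
  # exact partition
  expect_length(intersect(sp$train$sample_id, sp$validation$sample_id), 0L)
  expect_setequal(c(sp$train$sample_id, sp$validation$sample_id),
                  ds$sample_id)
})

test_that("splits are seed-deterministic and stratified to within one sample", {
  ds <- generate_paired_dataset(tiny_config(n_per_class = 11L))
  a <- split_dataset(ds, 0.7, seed = 5)
  b <- split_dataset(ds, 0.7, seed = 5)
  expect_identical(a$train$sample_id, b$train$sample_id)
  c_ <- split_dataset(ds, 0.7, seed = 6)
  expect_equal(nrow(c_$train), nrow(a$train))
  expect_false(identical(a$train$sample_id, c_$train$sample_id))
  # per-class train fraction within 1 sample of the target
  for (lv in levels(ds$label)) {
    n_lv <- sum(ds$label == lv)
    got <- sum(a$train$label == lv)
    expect_lt(abs(got - 0.7 * n_lv), 1)
  }
})

test_that("two samples split at one half give one of each label per side", {
  ds <- generate_paired_dataset(tiny_config(n_per_class = 1L))
  sp <- split_dataset(ds, 0.5, seed = 1)
  expect_equal(nrow(sp$train), 1L)
  expect_equal(nrow(sp$validation), 1L)
  expect_false(sp$train$label == sp$validation$label)
  expect_error(split_dataset(ds, 1.2), "between 0 and 1")
})
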