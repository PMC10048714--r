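test_that("identical config and seed give a bit-identical dataset", {
  cfg <- tiny_config(seed = 42L)
  d1 <- generate_paired_dataset(cfg)
  d2 <- generate_paired_dataset(cfg)
  expect_identical(d1$spectrum, d2$spectrum)
  expect_identical(d1$image, d2$image)
  expect_identical(d1$sample_id, d2$sample_id)
  d3 <- generate_paired_dataset(tiny_config(seed = 43L))
  expect_false(identical(d1$spectrum, d3$spectrum))
})

test_that("generated datasets are exactly class-balanced", {
  for (n in c(1L, 3L)) {
    ds <- generate_paired_dataset(tiny_config(n_per_class = n))
    expect_equal(nrow(ds), 2L * n)
    expect_equal(unname(c(table(ds$label))), c(n, n))
    expect_equal(anyDuplicated(ds$sample_id), 0L)
  }
})

test_that("zero effect and zero noise make the classes indistinguishable", {
  cfg <- tiny_config(spectral_effect_size = 0, spectral_noise_sd = 0,
                     scatter_sd = 0)
  s_h <- withr::with_seed(5, generate_spectrum(cfg, "healthy"))
  s_d <- withr::with_seed(5, generate_spectrum(cfg, "diseased"))
  expect_identical(s_h, s_d)
  # determinism: repeated calls under the same stream state are identical
  expect_identical(withr::with_seed(9, generate_spectrum(cfg, "diseased")),
                   withr::with_seed(9, generate_spectrum(cfg, "diseased")))
})

test_that("class separation concentrates at the 1450 nm absorption band", {
  cfg <- synthetic_config(n_per_class = 1, spectral_effect_size = 0.2,
                          seed = 1)
  wl <- wavelength_grid(cfg)
  i_dip <- which.min(abs(wl - 1450))
  i_far <- i_dip - 100L
  draws <- withr::with_seed(31, {
    mh <- rowMeans(vapply(1:1000, function(i) generate_spectrum(cfg, "healthy"),
                          numeric(cfg$n_bands)))
    md <- rowMeans(vapply(1:1000, function(i) generate_spectrum(cfg, "diseased"),
                          numeric(cfg$n_bands)))
    abs(mh - md)
  })
  expect_gt(draws[i_dip], draws[i_far])
  # and the dip-band separation is close to the nominal effect size
  expect_gt(draws[i_dip], 0.1)
})

test_that("between-class spectral distance grows with the effect size", {
  dist_at <- function(eff) {
    cfg <- tiny_config(n_per_class = 1, spectral_effect_size = eff,
                       spectral_noise_sd = 0.01, scatter_sd = 0.01)
    withr::with_seed(7, {
      mh <- rowMeans(vapply(1:200, function(i) generate_spectrum(cfg, "healthy"),
                            numeric(cfg$n_bands)))
      md <- rowMeans(vapply(1:200, function(i) generate_spectrum(cfg, "diseased"),
                            numeric(cfg$n_bands)))
      mean(abs(mh - md))
    })
  }
  d <- vapply(c(0, 0.1, 0.3), dist_at, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("raw scan sets calibrate and average back to the generator spectrum", {
  cfg0 <- tiny_config(spectral_noise_sd = 0)
  raw <- withr::with_seed(3, generate_raw_scan_set(cfg0, "diseased"))
  direct <- withr::with_seed(3, generate_spectrum(cfg0, "diseased"))
  expect_equal(calibrate_scan_set(raw), direct, tolerance = 1e-12)
  expect_length(raw$scans, cfg0$scans_per_region)
  expect_true(all(raw$white_reference > raw$dark_reference))

  # single scan: averaging is the identity
  cfg1 <- tiny_config(scans_per_region = 1L, spectral_noise_sd = 0)
  raw1 <- withr::with_seed(4, generate_raw_scan_set(cfg1, "healthy"))
  expect_equal(
    calibrate_scan_set(raw1),
    compute_reflectance(raw1$scans[[1]], raw1$white_reference,
                        raw1$dark_reference)
  )
})

test_that("acquisition round-trip error stays within the averaged noise level", {
  cfg <- synthetic_config(n_per_class = 1, seed = 7)
  sigma <- cfg$spectral_noise_sd
  frac_ok <- withr::with_seed(7, {
    errs <- unlist(lapply(1:100, function(i) {
      seed_i <- sample.int(1e6, 1)
      raw <- withr::with_seed(seed_i, generate_raw_scan_set(cfg, "healthy"))
      clean <- withr::with_seed(seed_i,
                                pearfusion:::spectrum_core(cfg, "healthy"))
      abs(calibrate_scan_set(raw) - clean)
    }))
    mean(errs < 3 * sigma / sqrt(cfg$scans_per_region))
  })
  expect_gte(frac_ok, 0.99)
})

test_that("image generation is deterministic and class-shifted in colour", {
  cfg <- tiny_config(image_size_px = 24L)
  i1 <- withr::with_seed(11, generate_image(cfg, "diseased"))
  i2 <- withr::with_seed(11, generate_image(cfg, "diseased"))
  expect_identical(i1, i2)
  expect_true(all(i1 >= 0 & i1 <= 1))

  # with the defaults, the diseased fruit is bluer-poor: mean blue intensity
  # in the fruit interior drops relative to healthy
  cfgc <- synthetic_config(n_per_class = 1, image_size_px = 48L, seed = 1)
  ctr <- 17:32
  blue <- withr::with_seed(21, {
    vapply(c("healthy", "diseased"), function(lv) {
      mean(vapply(1:200, function(i) {
        mean(generate_image(cfgc, lv)[ctr, ctr, 3])
      }, numeric(1)))
    }, numeric(1))
  })
  expect_gt(blue[["healthy"]], blue[["diseased"]])
  expect_gt(blue[["healthy"]] - blue[["diseased"]], 0.03)
})

test_that("zero image effect with blotches disabled removes the class signal", {
  cfg <- tiny_config(image_effect_size = 0, blotches = FALSE,
                     image_size_px = 24L)
  ih <- withr::with_seed(13, generate_image(cfg, "healthy"))
  id <- withr::with_seed(13, generate_image(cfg, "diseased"))
  expect_identical(ih, id)
})

test_that("invalid generator configurations are rejected", {
  expect_error(tiny_config(spectral_effect_size = -0.1), "spectral_effect_size")
  expect_error(tiny_config(image_size_px = 8L), "image_size_px")
  expect_error(synthetic_config(n_per_class = 2, n_bands = 1), "n_bands")
})

test_that("datasets round-trip through the on-disk manifest format", {
  dir <- withr::local_tempdir()
  ds <- generate_paired_dataset(tiny_config(n_per_class = 2L, seed = 8L),
                                write_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_paired_dataset(dir)
  expect_equal(back$sample_id, ds$sample_id)
  expect_equal(back$label, ds$label)
  # spectra survive CSV with full precision; PNG quantises to 8-bit
  expect_equal(back$spectrum, ds$spectrum, tolerance = 1e-12)
  expect_lt(max(abs(back$image[[1]] - ds$image[[1]])), 1 / 255)

  # byte-identical files on re-write
  dir2 <- withr::local_tempdir()
  write_paired_dataset(ds, dir2)
  f1 <- file.path(dir, "images", paste0(ds$sample_id[1], ".png"))
  f2 <- file.path(dir2, "images", paste0(ds$sample_id[1], ".png"))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
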