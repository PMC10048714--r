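# Fixtures are generated in code; nothing is read from disk.

# Small, fast generator config for structural tests.
tiny_config <- function(n_per_class = 4L, seed = 1L, image_size_px = 16L,
                        ...) {
  synthetic_config(n_per_class = n_per_class, n_bands = 12L,
                   image_size_px = image_size_px, seed = seed, ...)
}

# Linearly separable two-class "spectra" on a short wavelength grid:
# class prototypes mirrored across the band axis plus a little jitter.
separable_spectral_dataset <- function(n_per_class = 10L, n_bands = 10L,
                                       jitter = 0.01, seed = 1L) {
  withr::with_seed(seed, {
    protos <- list(
      healthy = seq(0.1, 0.9, length.out = n_bands),
      diseased = seq(0.9, 0.1, length.out = n_bands)
    )
    labels <- rep(c("healthy", "diseased"), each = n_per_class)
    spectra <- lapply(labels, function(lv) {
      pmax(protos[[lv]] + rnorm(n_bands, 0, jitter), 0)
    })
    tbl <- tibble::tibble(
      sample_id = sprintf("T%03d", seq_along(labels)),
      label = factor(labels, levels = c("healthy", "diseased")),
      spectrum = spectra
    )
    pearfusion:::new_pf_dataset(tbl, wavelengths = seq(900, 1700,
                                                       length.out = n_bands))
  })
}

# Tiny paired dataset with a strong, easy image signal for quick CNN tests.
easy_image_dataset <- function(n_per_class = 10L, seed = 1L,
                               image_size_px = 32L) {
  generate_paired_dataset(synthetic_config(
    n_per_class = n_per_class, n_bands = 12L,
    image_size_px = image_size_px, image_effect_size = 0.45,
    image_noise_sd = 0.02, colour_jitter_sd = 0.01,
    spectral_effect_size = 0.1, seed = seed
  ))
}

# Independent brute-force metrics oracle: per-sample enumeration, macro
# averaging computed directly from per-class one-vs-rest counts.
oracle_macro_metrics <- function(truth, predicted) {
  classes <- c("healthy", "diseased")
  acc <- mean(truth == predicted)
  per <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    prec <- if (tp + fp == 0) (if (tp + fn == 0) 1 else 0) else tp / (tp + fp)
    rec <- if (tp + fn == 0) 1 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(prec, rec, f1)
  })
  m <- (per[[1]] + per[[2]]) / 2
  list(accuracy = acc, precision = m[1], recall = m[2], f1 = m[3])
}
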