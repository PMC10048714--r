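#' Configuration for the synthetic paired spectra + image generator
#'
#' The generator emulates a paired near-infrared reflectance / RGB-image
#' collection of healthy and woolliness-disordered pears: per-sample
#' reflectance spectra over an evenly spaced wavelength grid, acquired as
#' several raw luminance scans per fruit region against white/dark
#' references, paired with a photograph of a single fruit on a light
#' background. Class separation is controlled independently per modality so
#' that either branch, or their fusion, can be made easy, hard, or entirely
#' uninformative (the null).
#'
#' Spectra are a smooth baseline minus Gaussian absorption dips (defaults at
#' 1200 nm and 1450 nm, the second overtone / water-association region where
#' moisture loss shows up); the dip depth at 1450 nm differs between classes
#' by `spectral_effect_size` (and by half of it at 1200 nm). Each sample gets
#' a multiplicative scatter factor near 1 (`scatter_sd`), the classic
#' light-scattering nuisance of diffuse-reflectance measurements, plus
#' additive band noise. Images are a filled ellipse (the fruit) on a white
#' background; the diseased class shifts the base colour toward a darker,
#' duller yellow by `image_effect_size` and receives darker blotches
#' concentrated near the fruit rim.
#'
#' @param n_per_class Samples per class (the emulated study used 240 + 240).
#' @param n_bands Number of spectral bands (default 228).
#' @param wavelength_start_nm,wavelength_end_nm Wavelength grid limits in nm
#'   (defaults 900 and 1700).
#' @param image_size_px Side of the square generated image in pixels
#'   (default 128; must be >= 16).
#' @param spectral_effect_size Between-class difference in absorption-dip
#'   depth, in reflectance units (default 0.08; 0 gives the null).
#' @param image_effect_size Magnitude of the class colour shift in RGB units
#'   (default 0.2; 0 plus `blotches = FALSE` gives the null).
#' @param spectral_noise_sd Additive per-band, per-scan noise sd in
#'   reflectance units (default 0.02).
#' @param dip_depth_sd Sd of the per-sample (biological) variability of each
#'   absorption-dip depth (default 0.05); this overlap between the class
#'   depth distributions is what keeps the spectral branch from being
#'   perfectly separable.
#' @param scatter_sd Sd of the per-sample multiplicative scatter factor
#'   (default 0.05; 0 disables scatter).
#' @param image_noise_sd Per-pixel, per-channel additive noise sd
#'   (default 0.06).
#' @param colour_jitter_sd Sd of the per-sample base-colour jitter
#'   (default 0.05).
#' @param blotches Whether diseased fruit receive rim-concentrated dark
#'   blotches (default TRUE).
#' @param scans_per_region Raw scans averaged per measured region
#'   (default 5).
#' @param seed Integer seed; identical config + seed gives a bit-identical
#'   dataset.
#'
#' @return An object of class `pf_synthetic_config` (a named list).
#' @export
synthetic_config <- function(n_per_class,
                             n_bands = 228L,
                             wavelength_start_nm = 900,
                             wavelength_end_nm = 1700,
                             image_size_px = 128L,
                             spectral_effect_size = 0.08,
                             image_effect_size = 0.2,
                             spectral_noise_sd = 0.02,
                             dip_depth_sd = 0.05,
                             scatter_sd = 0.05,
                             image_noise_sd = 0.06,
                             colour_jitter_sd = 0.05,
                             blotches = TRUE,
                             scans_per_region = 5L,
                             seed = 1L) {
  cfg <- list(
    n_per_class = as.integer(n_per_class),
    n_bands = as.integer(n_bands),
    wavelength_start_nm = wavelength_start_nm,
    wavelength_end_nm = wavelength_end_nm,
    image_size_px = as.integer(image_size_px),
    spectral_effect_size = spectral_effect_size,
    image_effect_size = image_effect_size,
    spectral_noise_sd = spectral_noise_sd,
    dip_depth_sd = dip_depth_sd,
    scatter_sd = scatter_sd,
    image_noise_sd = image_noise_sd,
    colour_jitter_sd = colour_jitter_sd,
    blotches = isTRUE(blotches),
    scans_per_region = as.integer(scans_per_region),
    seed = as.integer(seed)
  )
  class(cfg) <- "pf_synthetic_config"
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  stopifnot_scalar_number(cfg$n_per_class, "n_per_class", min = 1)
  stopifnot_scalar_number(cfg$n_bands, "n_bands", min = 2)
  if (cfg$wavelength_end_nm <= cfg$wavelength_start_nm) {
    abort("`wavelength_end_nm` must exceed `wavelength_start_nm`.")
  }
  if (cfg$image_size_px < 16L) abort("`image_size_px` must be >= 16.")
  stopifnot_scalar_number(cfg$spectral_effect_size, "spectral_effect_size", min = 0)
  stopifnot_scalar_number(cfg$image_effect_size, "image_effect_size", min = 0)
  stopifnot_scalar_number(cfg$spectral_noise_sd, "spectral_noise_sd", min = 0)
  stopifnot_scalar_number(cfg$dip_depth_sd, "dip_depth_sd", min = 0)
  stopifnot_scalar_number(cfg$scatter_sd, "scatter_sd", min = 0)
  stopifnot_scalar_number(cfg$image_noise_sd, "image_noise_sd", min = 0)
  stopifnot_scalar_number(cfg$scans_per_region, "scans_per_region", min = 1)
  cfg
}

#' Wavelength grid of a synthetic configuration
#'
#' @param cfg A `pf_synthetic_config`.
#' @return Numeric vector of band-centre wavelengths in nm, strictly
#'   increasing and evenly spaced.
#' @export
wavelength_grid <- function(cfg) {
  seq(cfg$wavelength_start_nm, cfg$wavelength_end_nm, length.out = cfg$n_bands)
}

# Gaussian absorption dip centres (nm), widths (nm), and healthy-class depths.
# The 1450 nm water-association band carries the full class effect; the
# 1200 nm band carries half of it.
.dip_centres <- c(1200, 1450)
.dip_widths <- c(45, 60)
.dip_depths_healthy <- c(0.10, 0.16)
.dip_effect_share <- c(0.5, 1.0)

# Noise-free spectrum for one sample: baseline minus class-dependent dips
# (with per-sample depth variability), times a per-sample scatter factor.
spectrum_core <- function(cfg, label) {
  wl <- wavelength_grid(cfg)
  t <- (wl - cfg$wavelength_start_nm) /
    (cfg$wavelength_end_nm - cfg$wavelength_start_nm)
  baseline <- 0.78 - 0.10 * t - 0.08 * (t - 0.5)^2
  depths <- .dip_depths_healthy
  if (as.character(label) == "diseased") {
    depths <- depths + cfg$spectral_effect_size * .dip_effect_share
  }
  if (cfg$dip_depth_sd > 0) {
    depths <- pmax(depths + rnorm(length(depths), 0, cfg$dip_depth_sd), 0)
  }
  dips <- rowSums(vapply(seq_along(.dip_centres), function(k) {
    depths[k] * exp(-(wl - .dip_centres[k])^2 / (2 * .dip_widths[k]^2))
  }, numeric(length(wl))))
  scatter <- if (cfg$scatter_sd > 0) exp(rnorm(1, 0, cfg$scatter_sd)) else 1
  (baseline - dips) * scatter
}

#' Generate one synthetic reflectance spectrum
#'
#' Draws a single calibrated (averaged-scan view) reflectance spectrum for
#' the given class from the generator model: smooth baseline minus Gaussian
#' absorption dips whose depths depend on the class, a per-sample
#' multiplicative scatter factor, plus additive band noise; values are
#' clipped to be non-negative. Uses the current RNG stream (wrap in
#' [withr::with_seed()] or set the seed yourself for reproducibility).
#'
#' @param cfg A [synthetic_config()].
#' @param label `"healthy"` or `"diseased"`.
#' @return Numeric vector of length `cfg$n_bands`.
#' @export
generate_spectrum <- function(cfg, label) {
  validate_synthetic_config(cfg)
  label <- as_pf_label(label)
  core <- spectrum_core(cfg, label)
  noise <- if (cfg$spectral_noise_sd > 0) {
    rnorm(cfg$n_bands, 0, cfg$spectral_noise_sd)
  } else {
    0
  }
  pmax(core + noise, 0)
}

# Instrument response curves used to synthesise raw luminance scans. Smooth,
# strictly W > B at every band.
instrument_white <- function(wl) 2600 + 900 * exp(-((wl - 1250) / 300)^2)
instrument_dark <- function(wl) 96 + 0.004 * (wl - 900)

#' Generate a raw scan set (luminance scans plus references) for one region
#'
#' Synthesises `scans_per_region` raw luminance scans `I` together with the
#' white (`W`) and dark (`B`) reference curves such that calibrating each
#' scan as `(I - B) / (W - B)` and averaging recovers the sample's
#' noise-free spectrum up to the per-scan additive noise (exactly, when
#' `spectral_noise_sd = 0`).
#'
#' @inheritParams generate_spectrum
#' @param region_id Identifier attached to the scan set.
#' @return A list of class `pf_raw_scan_set` with elements `scans` (list of
#'   numeric vectors), `white_reference`, `dark_reference`, `region_id`.
#' @export
generate_raw_scan_set <- function(cfg, label, region_id = "region-1") {
  validate_synthetic_config(cfg)
  label <- as_pf_label(label)
  wl <- wavelength_grid(cfg)
  W <- instrument_white(wl)
  B <- instrument_dark(wl)
  core <- spectrum_core(cfg, label)
  scans <- lapply(seq_len(cfg$scans_per_region), function(i) {
    r <- core
    if (cfg$spectral_noise_sd > 0) {
      r <- r + rnorm(cfg$n_bands, 0, cfg$spectral_noise_sd)
    }
    B + r * (W - B)
  })
  structure(
    list(scans = scans, white_reference = W, dark_reference = B,
         region_id = region_id),
    class = "pf_raw_scan_set"
  )
}

# Base fruit colours (RGB in [0,1]). The diseased shift direction moves the
# healthy yellow-green toward a darker, duller yellow (less green and blue).
.healthy_rgb <- c(0.62, 0.76, 0.30)
.disease_shift_dir <- c(0.20, -0.80, -0.56)

#' Generate one synthetic fruit image
#'
#' Renders a single fruit as a shaded filled ellipse on a near-white
#' background. The base colour is sampled around a class-dependent hue
#' (healthy: yellow-green; diseased: shifted by `image_effect_size` toward a
#' darker yellow); diseased fruit additionally receive randomly placed
#' darker blotches concentrated near the ellipse rim (when
#' `cfg$blotches`). Per-pixel Gaussian noise is added and the result is
#' clipped to `[0, 1]`. Uses the current RNG stream.
#'
#' @inheritParams generate_spectrum
#' @return Numeric array `image_size_px x image_size_px x 3` in `[0, 1]`.
#' @export
generate_image <- function(cfg, label) {
  validate_synthetic_config(cfg)
  label <- as_pf_label(label)
  s <- cfg$image_size_px
  base <- .healthy_rgb
  if (label == "diseased") {
    base <- base + cfg$image_effect_size * .disease_shift_dir
  }
  base <- pmin(pmax(base + rnorm(3, 0, cfg$colour_jitter_sd), 0), 1)

  cx <- (0.5 + runif(1, -0.03, 0.03)) * s
  cy <- (0.5 + runif(1, -0.03, 0.03)) * s
  a <- (0.36 + runif(1, -0.03, 0.03)) * s
  b <- (0.41 + runif(1, -0.03, 0.03)) * s

  xs <- matrix(seq_len(s), s, s)
  ys <- matrix(seq_len(s), s, s, byrow = TRUE)
  r2 <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2
  inside <- r2 <= 1
  shade <- 1 - 0.18 * pmin(r2, 1)

  img <- array(0.97, c(s, s, 3))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[inside] <- base[ch] * shade[inside]
    img[, , ch] <- plane
  }

  if (label == "diseased" && cfg$blotches) {
    n_blotch <- 2L + stats::rpois(1, 4)
    for (k in seq_len(n_blotch)) {
      rho <- 0.55 + 0.45 * stats::rbeta(1, 3, 1.2) # rim-concentrated
      theta <- runif(1, 0, 2 * pi)
      bx <- cx + rho * a * cos(theta)
      by <- cy + rho * b * sin(theta)
      rb <- runif(1, 0.04, 0.09) * s
      hit <- inside & ((xs - bx)^2 + (ys - by)^2 <= rb^2)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[hit] <- plane[hit] * 0.55
        img[, , ch] <- plane
      }
    }
  }

  if (cfg$image_noise_sd > 0) {
    img <- img + array(rnorm(length(img), 0, cfg$image_noise_sd), dim(img))
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a paired spectra + image dataset
#'
#' Produces an exactly class-balanced dataset of `2 * n_per_class` samples.
#' Each sample's spectrum is acquired the way the emulated instrument works:
#' `scans_per_region` raw luminance scans are synthesised, calibrated
#' against the white/dark references with [compute_reflectance()], and
#' averaged with [average_scans()]; the paired image comes from
#' [generate_image()]. The whole dataset is a deterministic function of the
#' configuration (including its `seed`).
#'
#' @param cfg A [synthetic_config()].
#' @param write_dir Optional directory; when given, a `manifest.csv` plus
#'   per-sample spectrum CSVs and PNG images are written there (see
#'   [write_paired_dataset()]).
#' @return A tibble of class `pf_dataset` with columns `sample_id`, `label`
#'   (factor healthy/diseased), `spectrum` (list of numeric vectors) and
#'   `image` (list of RGB arrays), with the wavelength grid and the
#'   generating config attached as attributes.
#' @export
generate_paired_dataset <- function(cfg, write_dir = NULL) {
  validate_synthetic_config(cfg)
  n <- 2L * cfg$n_per_class
  labels <- rep(pf_labels(), each = cfg$n_per_class)
  ds <- with_seed(cfg$seed, {
    rows <- lapply(seq_len(n), function(i) {
      raw <- generate_raw_scan_set(cfg, labels[i],
                                   region_id = sprintf("S%04d", i))
      spec <- average_scans(lapply(raw$scans, function(I) {
        compute_reflectance(I, raw$white_reference, raw$dark_reference)
      }))
      img <- generate_image(cfg, labels[i])
      list(spectrum = pmax(spec, 0), image = img)
    })
    tibble(
      sample_id = sprintf("S%04d", seq_len(n)),
      label = as_pf_label(labels),
      spectrum = lapply(rows, `[[`, "spectrum"),
      image = lapply(rows, `[[`, "image")
    )
  })
  ds <- new_pf_dataset(ds, wavelengths = wavelength_grid(cfg), config = cfg)
  if (!is.null(write_dir)) write_paired_dataset(ds, write_dir)
  ds
}

new_pf_dataset <- function(tbl, wavelengths, config = NULL) {
  attr(tbl, "wavelengths") <- wavelengths
  attr(tbl, "config") <- config
  class(tbl) <- unique(c("pf_dataset", class(tbl)))
  tbl
}

#' Wavelength grid attached to a paired dataset
#' @param ds A `pf_dataset`.
#' @return Numeric vector of wavelengths in nm.
#' @export
dataset_wavelengths <- function(ds) {
  wl <- attr(ds, "wavelengths", exact = TRUE)
  if (is.null(wl)) abort("Dataset carries no wavelength grid.")
  wl
}

#' Write a paired dataset to disk
#'
#' Writes `manifest.csv` (columns `sample_id`, `label`, `spectrum_path`,
#' `image_path`), one two-row CSV per spectrum (first row the wavelength
#' grid in nm, second row the averaged reflectance) under `spectra/`, and
#' one 8-bit RGB PNG per image under `images/`.
#'
#' @param ds A `pf_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_paired_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "spectra"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  wl <- dataset_wavelengths(ds)
  spec_paths <- file.path("spectra", paste0(ds$sample_id, ".csv"))
  img_paths <- file.path("images", paste0(ds$sample_id, ".png"))
  for (i in seq_len(nrow(ds))) {
    m <- rbind(wl, ds$spectrum[[i]])
    utils::write.table(m, file.path(dir, spec_paths[i]), sep = ",",
                       row.names = FALSE, col.names = FALSE)
    png::writePNG(ds$image[[i]], file.path(dir, img_paths[i]))
  }
  manifest <- tibble(
    sample_id = ds$sample_id,
    label = as.character(ds$label),
    spectrum_path = spec_paths,
    image_path = img_paths
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Read a paired dataset written by [write_paired_dataset()]
#'
#' @param dir Directory containing `manifest.csv`.
#' @return A `pf_dataset` tibble.
#' @export
read_paired_dataset <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  spectra <- lapply(manifest$spectrum_path, function(p) {
    m <- as.matrix(utils::read.table(file.path(dir, p), sep = ","))
    unname(m[2, ])
  })
  wl <- {
    m <- as.matrix(utils::read.table(file.path(dir, manifest$spectrum_path[1]),
                                     sep = ","))
    unname(m[1, ])
  }
  images <- lapply(manifest$image_path, function(p) {
    png::readPNG(file.path(dir, p))
  })
  tbl <- tibble(
    sample_id = manifest$sample_id,
    label = as_pf_label(manifest$label),
    spectrum = spectra,
    image = images
  )
  new_pf_dataset(tbl, wavelengths = wl)
}
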