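#' Calibrate raw luminance to reflectance
#'
#' Converts a raw luminance scan `I` to reflectance using the white (`W`)
#' and dark (`B`) reference scans: `R = (I - B) / (W - B)`, elementwise.
#' Reflectance is stored as a fraction (nominally 0 to 1), not a
#' percentage; percentages are a display concern only. No clipping is
#' applied.
#'
#' @param I Numeric vector of measured luminance per band.
#' @param W Numeric vector, white-reference luminance per band.
#' @param B Numeric vector, dark-reference luminance per band.
#' @return Numeric vector of reflectance fractions, same length as `I`.
#' @export
#' @examples
#' compute_reflectance(I = c(5, 6), W = c(10, 12), B = c(0, 0))
compute_reflectance <- function(I, W, B) {
  if (length(I) != length(W) || length(I) != length(B)) {
    abort("`I`, `W` and `B` must have the same length.")
  }
  denom <- W - B
  bad <- which(denom == 0)
  if (length(bad)) {
    abort(sprintf(
      "Calibration degenerate: W == B at band index %d (of %d).",
      bad[1], length(bad)
    ))
  }
  (I - B) / denom
}

#' Average repeated scans of one region
#'
#' Elementwise arithmetic mean of the repeated reflectance (or luminance)
#' scans taken over a single measured region; the averaged spectrum is the
#' modelling unit downstream.
#'
#' @param scans A list of equal-length numeric vectors, or a matrix with one
#'   scan per row.
#' @return Numeric vector, the per-band mean.
#' @export
average_scans <- function(scans) {
  if (is.matrix(scans)) scans <- asplit(scans, 1)
  if (!is.list(scans) || length(scans) == 0L) {
    abort("`scans` must be a non-empty list of numeric vectors.")
  }
  lens <- lengths(scans)
  if (length(unique(lens)) != 1L) {
    abort("All scans must have the same length.")
  }
  colMeans(do.call(rbind, lapply(scans, as.numeric)))
}

#' Calibrate and average a raw scan set
#'
#' Convenience round trip for a [generate_raw_scan_set()] object: calibrate
#' each scan against the set's references and average.
#'
#' @param raw A `pf_raw_scan_set`.
#' @return Numeric reflectance vector.
#' @export
calibrate_scan_set <- function(raw) {
  average_scans(lapply(raw$scans, function(I) {
    compute_reflectance(I, raw$white_reference, raw$dark_reference)
  }))
}

#' Stratified train/validation split
#'
#' Splits a paired dataset by class label: within each class the samples are
#' shuffled with the given seed and the first `round(train_fraction * n)`
#' go to the training side. The partition is exact (no overlap, union is
#' the full dataset) and both sides inherit the dataset's wavelength grid.
#' With 480 balanced samples and `train_fraction = 0.7` this yields
#' 336 training (168 + 168) and 144 validation (72 + 72) samples.
#'
#' @param ds A `pf_dataset` (any tibble with `sample_id` and `label`
#'   columns works).
#' @param train_fraction Fraction of each class assigned to training,
#'   strictly between 0 and 1 (default 0.7).
#' @param seed Integer seed for the shuffle.
#' @return A list with elements `train` and `validation`.
#' @export
split_dataset <- function(ds, train_fraction = 0.7, seed = 1L) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be strictly between 0 and 1.")
  }
  labs <- as_pf_label(ds$label)
  counts <- table(labs)
  if (any(counts < 1)) {
    abort("Both classes must be present to split.")
  }
  # Per-class training counts: round(train_fraction * n_c), with fractional
  # remainders resolved by largest remainder so the overall training size is
  # round(train_fraction * n) even when class counts are tiny.
  targets <- train_fraction * as.numeric(counts)
  n_tr <- floor(targets)
  short <- round(train_fraction * length(labs)) - sum(n_tr)
  if (short > 0) {
    give <- order(targets - n_tr, decreasing = TRUE)[seq_len(short)]
    n_tr[give] <- n_tr[give] + 1L
  }
  train_idx <- with_seed(seed, {
    unlist(lapply(seq_along(levels(labs)), function(i) {
      idx <- sample(which(labs == levels(labs)[i]))
      idx[seq_len(n_tr[i])]
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  wl <- attr(ds, "wavelengths", exact = TRUE)
  cfg <- attr(ds, "config", exact = TRUE)
  restore <- function(x) {
    if (!is.null(wl)) x <- new_pf_dataset(x, wavelengths = wl, config = cfg)
    x
  }
  list(
    train = restore(ds[train_idx, , drop = FALSE]),
    validation = restore(ds[-train_idx, , drop = FALSE])
  )
}

# Stack the spectra of a dataset into an n x n_bands matrix with sample_id
# rownames.
spectra_matrix <- function(ds) {
  x <- do.call(rbind, ds$spectrum)
  rownames(x) <- ds$sample_id
  colnames(x) <- paste0("b", seq_len(ncol(x)))
  x
}
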