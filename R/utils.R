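# Internal helpers: seeded evaluation, seed fan-out, rounding, small checks.

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Counter-based sub-seed derivation: stages of a pipeline get independent,
# reproducible streams from one master seed. Kept below 2^31 - 1.
derive_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) + 1000003 * as.double(index)) %% 2147483629L) + 1L
}

# Display rounding used in all reports: half-up to `digits` decimals, so that
# e.g. 0.9165 prints as 0.917 (plain round() would give 0.916 via banker's
# rounding on some values).
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min) abort(sprintf("`%s` must be >= %s.", name, format(min)))
  invisible(x)
}

# Canonical class labels used throughout; `diseased` is the positive class.
pf_labels <- function() c("healthy", "diseased")

as_pf_label <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), pf_labels())
  if (length(bad)) {
    abort(sprintf("Unknown class label(s): %s", paste(bad, collapse = ", ")))
  }
  factor(x, levels = pf_labels())
}

# 0/1 encoding with diseased = 1 (the positive, disordered class).
encode_labels <- function(labels) {
  as.integer(as_pf_label(labels) == "diseased")
}
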