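# Feature-level fusion: concatenate the image feature vector and the
# spectral feature vector (image first, spectral appended), then train a
# prediction head on the fused vector with both branches frozen.

#' Fuse image and spectral feature vectors by concatenation
#'
#' Appends the spectral features `fb` after the image features `fa` with no
#' scaling or re-weighting: the first `length(fa)` entries of the result
#' equal `fa` exactly and the remainder equal `fb`. Matrices (one sample
#' per row) are fused column-wise; when both carry rownames the spectral
#' rows are aligned to the image rows by sample id.
#'
#' @param fa Image feature vector (or `n x p` matrix).
#' @param fb Spectral feature vector (or `n x q` matrix).
#' @return The fused vector/matrix with attributes `image_len` and
#'   `spectral_len`.
#' @export
fuse_features <- function(fa, fb) {
  la <- if (is.matrix(fa)) ncol(fa) else length(fa)
  lb <- if (is.matrix(fb)) ncol(fb) else length(fb)
  if (la + lb == 0L) abort("Cannot fuse two empty feature vectors.")
  if (is.matrix(fa) || is.matrix(fb)) {
    if (!is.matrix(fa)) fa <- matrix(fa, nrow(fb), 0)
    if (!is.matrix(fb)) fb <- matrix(fb, nrow(fa), 0)
    if (nrow(fa) != nrow(fb)) {
      abort("Image and spectral feature matrices must have the same rows.")
    }
    if (!is.null(rownames(fa)) && !is.null(rownames(fb))) {
      if (!setequal(rownames(fa), rownames(fb))) {
        abort("Unpaired samples: image and spectral rownames differ.")
      }
      fb <- fb[rownames(fa), , drop = FALSE]
    }
    out <- cbind(fa, fb)
  } else {
    out <- c(fa, fb)
  }
  attr(out, "image_len") <- la
  attr(out, "spectral_len") <- lb
  out
}

#' Configuration for the fused prediction head
#'
#' The head is a single dense layer from the fused feature vector to two
#' class scores with an argmax decision; both branch models stay frozen
#' (two-stage training). An optional feature standardisation (off by
#' default, matching the plain-concatenation definition) can rescale each
#' fused feature to zero mean / unit variance before the head.
#'
#' @param tap_name Backbone tap to extract image features from (`NULL` =
#'   deepest tap).
#' @param max_epochs,batch_size,learning_rate,seed Head training settings.
#' @param standardise Standardise fused features before the head
#'   (default `FALSE`).
#' @return A list of class `pf_fusion_config`.
#' @export
fusion_config <- function(tap_name = NULL, max_epochs = 60L, batch_size = 32L,
                          learning_rate = 1e-3, seed = 1L,
                          standardise = FALSE) {
  structure(list(tap_name = tap_name, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 standardise = isTRUE(standardise)),
            class = "pf_fusion_config")
}

resolve_tap <- function(image_model, tap_name) {
  taps <- names(image_model$stages)
  if (is.null(tap_name)) return(taps[length(taps)])
  if (!tap_name %in% taps) {
    abort(sprintf("Unknown tap '%s' (available: %s).", tap_name,
                  paste(taps, collapse = ", ")))
  }
  tap_name
}

#' Train the fused prediction head
#'
#' Extracts the frozen spectral features (hidden activations of the
#' spectral network) and the frozen image features (flattened activations
#' at the chosen tap), concatenates them image-first, and trains the dense
#' two-class head on the fused vectors. Branch parameters are never
#' touched.
#'
#' @param spectral_model A trained `pf_spectral_mlp`.
#' @param image_model A trained `pf_backbone`.
#' @param data Paired training `pf_dataset` (the same split both branches
#'   were trained on).
#' @param config A [fusion_config()].
#' @return An object of class `pf_fusion_model` exposing [predict()].
#' @export
train_fusion_head <- function(spectral_model, image_model, data,
                              config = fusion_config()) {
  tap <- resolve_tap(image_model, config$tap_name)
  fa <- extract_image_feature_matrix(image_model, data, tap)
  fb <- extract_spectral_features(spectral_model, data)
  ff <- fuse_features(fa, fb)
  stats_ <- NULL
  if (config$standardise) {
    mu <- colMeans(ff)
    sdv <- apply(ff, 2, stats::sd)
    sdv[sdv == 0] <- 1
    ff <- sweep(sweep(ff, 2, mu), 2, sdv, "/")
    stats_ <- list(mean = mu, sd = sdv)
  }
  y01 <- encode_labels(data$label)
  head_fit <- mlp_core_fit(ff, y01, n_hidden = 0L, output = "softmax",
                           max_epochs = config$max_epochs,
                           batch_size = config$batch_size,
                           learning_rate = config$learning_rate,
                           seed = config$seed)
  structure(
    list(spectral_model = spectral_model, image_model = image_model,
         tap_name = tap, head = head_fit, config = config,
         standardise_stats = stats_,
         image_len = attr(ff, "image_len") %||% ncol(fa),
         spectral_len = ncol(fb)),
    class = "pf_fusion_model"
  )
}

fused_features_of <- function(object, data) {
  fa <- extract_image_feature_matrix(object$image_model, data,
                                     object$tap_name)
  fb <- extract_spectral_features(object$spectral_model, data)
  ff <- fuse_features(fa, fb)
  if (!is.null(object$standardise_stats)) {
    ff <- sweep(sweep(ff, 2, object$standardise_stats$mean), 2,
                object$standardise_stats$sd, "/")
  }
  ff
}

#' @export
predict.pf_fusion_model <- function(object, data,
                                    type = c("class", "prob"), ...) {
  type <- match.arg(type)
  ff <- fused_features_of(object, data)
  z <- ff %*% object$head$par$W2 +
    rep(object$head$par$b2, each = nrow(ff))
  z <- exp(z - apply(z, 1, max))
  p <- z / rowSums(z)
  colnames(p) <- pf_labels()
  if (type == "prob") return(p)
  factor(pf_labels()[max.col(p, ties.method = "first")], levels = pf_labels())
}

#' Fusion grid over spectral widths and backbones
#'
#' Trains one spectral network per hidden width (independently seeded), and
#' for every (width, backbone) pair trains a fused head and evaluates it on
#' the validation set. The best pair is flagged by validation accuracy with
#' ties broken toward the smaller width.
#'
#' @param train,validation Paired `pf_dataset` splits.
#' @param image_models Named list of trained `pf_backbone`s.
#' @param grid Integer vector of spectral hidden widths.
#' @param mlp_config Base [mlp_config()] for the spectral networks.
#' @param config Base [fusion_config()] for the heads.
#' @return A tibble with one row per pair and attributes `best_n_hidden`,
#'   `best_backbone`.
#' @export
run_fusion_grid <- function(train, validation, image_models,
                            grid = seq(10L, 100L, by = 10L),
                            mlp_config = pearfusion::mlp_config(),
                            config = fusion_config()) {
  if (length(grid) == 0L || length(image_models) == 0L) {
    abort("`grid` and `image_models` must be non-empty.")
  }
  rows <- list()
  for (i in seq_along(grid)) {
    cfg <- mlp_config
    cfg$n_hidden <- as.integer(grid[i])
    cfg$seed <- derive_seed(mlp_config$seed, i)
    sm <- train_spectral_mlp(train, cfg, validation = validation)
    for (nm in names(image_models)) {
      hc <- config
      hc$seed <- derive_seed(config$seed, i * 100L + match(nm, names(image_models)))
      fm <- train_fusion_head(sm, image_models[[nm]], train, hc)
      met <- evaluate_predictions(validation$label, predict(fm, validation))
      rows[[length(rows) + 1L]] <- c(
        list(n_hidden = as.integer(grid[i]), backbone = nm),
        metrics_row(met)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  best <- which.max(out$accuracy)
  attr(out, "best_n_hidden") <- out$n_hidden[best]
  attr(out, "best_backbone") <- out$backbone[best]
  out
}

#' Layer-depth ablation of the fused model
#'
#' Holds both branch models fixed and varies only the backbone tap whose
#' flattened features enter the fusion; one fused head is trained and
#' evaluated per tap.
#'
#' @param spectral_model A trained `pf_spectral_mlp`.
#' @param image_model A trained `pf_backbone`.
#' @param train,validation Paired `pf_dataset` splits.
#' @param taps Character vector of tap names (default: all taps of the
#'   backbone, shallow to deep).
#' @param config Base [fusion_config()].
#' @return A tibble with one row per tap.
#' @export
run_layer_ablation <- function(spectral_model, image_model, train, validation,
                               taps = NULL, config = fusion_config()) {
  if (is.null(taps)) taps <- names(image_model$stages)
  rows <- lapply(seq_along(taps), function(i) {
    hc <- config
    hc$tap_name <- taps[i]
    hc$seed <- derive_seed(config$seed, i)
    fm <- train_fusion_head(spectral_model, image_model, train, hc)
    met <- evaluate_predictions(validation$label, predict(fm, validation))
    c(list(tap = taps[i]), metrics_row(met))
  })
  dplyr::bind_rows(rows)
}
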