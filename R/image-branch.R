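# Image branch: train a backbone as a two-class fruit classifier and extract
# flattened feature vectors from any named tap point.

# Resize an (H, W, 3) array in [0,1] to a square side `size` (bilinear).
resize_image <- function(img, size) {
  d <- dim(img)
  if (d[1] == size && d[2] == size) return(img)
  out <- EBImage::imageData(EBImage::resize(
    EBImage::Image(img, colormode = "Color"), w = size, h = size
  ))
  dim(out) <- c(size, size, 3L)
  out
}

# Stack a list of images into the engine's (H, W, N, C) tensor, resizing to
# `size` as needed.
images_to_tensor <- function(images, size) {
  n <- length(images)
  x <- array(0, c(size, size, n, 3L))
  for (i in seq_len(n)) {
    x[, , i, ] <- resize_image(images[[i]], size)
  }
  x
}

bb_params <- function(bb) {
  c(do.call(c, lapply(bb$stages, nn_params)), nn_params(bb$head))
}

bb_set_params <- function(bb, flat) {
  pos <- 1L
  for (nm in names(bb$stages)) {
    r <- nn_set_params(bb$stages[[nm]], flat, pos)
    bb$stages[[nm]] <- r$node
    pos <- r$pos
  }
  r <- nn_set_params(bb$head, flat, pos)
  bb$head <- r$node
  bb
}

bb_backward <- function(bb, caches, dlogits) {
  rh <- nn_backward(bb$head, caches$head, dlogits)
  rg <- nn_backward(nn_gap(), caches$gap, rh$dx)
  dy <- rg$dx
  stage_grads <- vector("list", length(bb$stages))
  names(stage_grads) <- names(bb$stages)
  for (nm in rev(names(bb$stages))) {
    r <- nn_backward(bb$stages[[nm]], caches$stages[[nm]], dy)
    dy <- r$dx
    stage_grads[[nm]] <- r$grads
  }
  c(do.call(c, stage_grads), rh$grads)
}

#' Training configuration for the image branch
#'
#' @param max_epochs Training epochs (default 15).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Seed for shuffling (initialisation is seeded by the
#'   backbone spec).
#' @return A named list of class `pf_image_train_config`.
#' @export
image_train_config <- function(max_epochs = 15L, batch_size = 32L,
                               learning_rate = 1e-3, seed = 1L) {
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "pf_image_train_config")
}

#' Train a backbone as an image classifier
#'
#' Trains the full backbone (all stages plus the global-pool / dense head)
#' from scratch with Adam on softmax cross-entropy. Training is seeded and
#' deterministic; the returned model is in frozen evaluation mode for
#' feature extraction.
#'
#' @param bb A `pf_backbone` from [build_backbone()].
#' @param data A `pf_dataset` (needs `image` and `label` columns) with at
#'   least two classes present.
#' @param config An [image_train_config()].
#' @return The trained `pf_backbone` (with `trained = TRUE` and a
#'   `loss_history`).
#' @export
train_image_classifier <- function(bb, data, config = image_train_config()) {
  if (length(unique(as.character(data$label))) < 2L) {
    abort("Training data must contain both classes.")
  }
  size <- bb$spec$input_size_px
  x_all <- images_to_tensor(data$image, size)
  y <- encode_labels(data$label) + 1L
  n <- length(y)
  params <- bb_params(bb)
  state <- adam_init(params)
  losses <- numeric(config$max_epochs)
  with_seed(config$seed, {
    for (ep in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      bl <- numeric(0)
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        xb <- x_all[, , idx, , drop = FALSE]
        fw <- backbone_forward(bb, xb, keep = TRUE)
        ls <- softmax_xent(fw$logits, y[idx])
        grads <- bb_backward(bb, fw$caches, ls$dlogits)
        st <- adam_step(params, grads, state, lr = config$learning_rate)
        params <- st$params
        state <- st$state
        bb <- bb_set_params(bb, params)
        bl <- c(bl, ls$loss)
      }
      losses[ep] <- mean(bl)
    }
  })
  bb$trained <- TRUE
  bb$loss_history <- losses
  bb$train_config <- config
  bb
}

# Evaluation-mode forward in memory-bounded chunks.
bb_predict_raw <- function(bb, images, chunk = 64L) {
  size <- bb$spec$input_size_px
  n <- length(images)
  out <- matrix(0, n, 2L)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    x <- images_to_tensor(images[idx], size)
    logits <- backbone_forward(bb, x)$logits
    z <- exp(logits - apply(logits, 1, max))
    out[idx, ] <- z / rowSums(z)
  }
  out
}

#' Predict classes or probabilities from a trained backbone
#'
#' @param object A trained `pf_backbone`.
#' @param data A `pf_dataset` (or tibble with an `image` list-column).
#' @param type `"class"` for labels, `"prob"` for class probabilities.
#' @param ... Unused.
#' @return A factor of labels, or an `n x 2` probability matrix with
#'   columns `healthy`, `diseased`.
#' @export
predict.pf_backbone <- function(object, data, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- bb_predict_raw(object, data$image)
  colnames(p) <- pf_labels()
  if (type == "prob") return(p)
  factor(pf_labels()[max.col(p, ties.method = "first")], levels = pf_labels())
}

#' Extract feature maps at a named tap point
#'
#' Runs the (frozen) backbone forward to the named tap and returns the
#' activation grid for each sample. Deterministic: the same image always
#' yields the same map.
#'
#' @param bb A `pf_backbone`.
#' @param data A `pf_dataset` with an `image` list-column.
#' @param tap_name One of `bb$spec$tap_points`.
#' @param chunk Images processed per forward pass (memory bound).
#' @return A list of `pf_feature_map` objects (arrays `height x width x
#'   channels` with a `tap_name` attribute), named by `sample_id` when
#'   available.
#' @export
extract_features_at_tap <- function(bb, data, tap_name, chunk = 64L) {
  if (!tap_name %in% names(bb$stages)) {
    abort(sprintf("Unknown tap '%s' for family %s (taps: %s).",
                  tap_name, bb$spec$family,
                  paste(names(bb$stages), collapse = ", ")))
  }
  size <- bb$spec$input_size_px
  images <- data$image
  n <- length(images)
  maps <- vector("list", n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    x <- images_to_tensor(images[idx], size)
    tap <- backbone_forward(bb, x, upto = tap_name)$tap
    for (j in seq_along(idx)) {
      m <- tap[, , j, , drop = FALSE]
      dim(m) <- dim(tap)[c(1, 2, 4)]
      attr(m, "tap_name") <- tap_name
      class(m) <- c("pf_feature_map", class(m))
      maps[[idx[j]]] <- m
    }
  }
  if (!is.null(data$sample_id)) names(maps) <- data$sample_id
  maps
}

#' Flatten a feature map to a 1-D feature vector
#'
#' Reshapes a `height x width x channels` activation grid into a vector of
#' length `height * width * channels`. The ordering convention is fixed and
#' row-major — height varies slowest, then width, then channel fastest — so
#' extracted features are reproducible across runs; no values are dropped
#' or duplicated.
#'
#' @param map A `pf_feature_map` (or any 3-D array).
#' @return Numeric vector of length `prod(dim(map))`.
#' @export
flatten <- function(map) {
  d <- dim(map)
  if (is.null(d) || length(d) != 3L) abort("`map` must be a 3-D array.")
  as.vector(aperm(unclass(map), c(3, 2, 1)))
}

#' Flattened tap features for a whole dataset
#'
#' Convenience wrapper combining [extract_features_at_tap()] and
#' [flatten()] into an `n x p` feature matrix (rownames are sample ids).
#'
#' @inheritParams extract_features_at_tap
#' @return Numeric matrix, one row per sample.
#' @export
extract_image_feature_matrix <- function(bb, data, tap_name, chunk = 64L) {
  maps <- extract_features_at_tap(bb, data, tap_name, chunk = chunk)
  x <- do.call(rbind, lapply(maps, flatten))
  rownames(x) <- names(maps)
  x
}
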