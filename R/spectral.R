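# Spectral branch: a one-hidden-layer network trained on raw reflectance
# spectra. Its post-activation hidden layer is the spectral feature vector
# used for fusion.

# Generic dense engine shared by the spectral network (one ReLU hidden layer,
# sigmoid output) and the fusion prediction head (no hidden layer, softmax
# over two class scores). Weights are initialised from a uniform
# distribution (Glorot limits), optimised with Adam on cross-entropy, fully
# seeded. Optional early stopping on a validation split restores the best
# parameters.
mlp_core_fit <- function(x, y01, n_hidden, output = c("sigmoid", "softmax"),
                         max_epochs = 200L, batch_size = 32L,
                         learning_rate = 1e-3, seed = 1L,
                         x_val = NULL, y_val = NULL, patience = 20L) {
  output <- match.arg(output)
  n <- nrow(x)
  p <- ncol(x)
  q <- if (output == "sigmoid") 1L else 2L
  fwd <- function(par, xx) {
    if (n_hidden > 0L) {
      h <- pmax(xx %*% par$W1 + rep(par$b1, each = nrow(xx)), 0)
      z <- h %*% par$W2 + rep(par$b2, each = nrow(xx))
    } else {
      h <- NULL
      z <- xx %*% par$W2 + rep(par$b2, each = nrow(xx))
    }
    list(h = h, z = z)
  }
  loss_of <- function(par, xx, yy) {
    z <- fwd(par, xx)$z
    if (output == "sigmoid") {
      pr <- stats::plogis(z[, 1])
      -mean(yy * log(pmax(pr, 1e-12)) + (1 - yy) * log(pmax(1 - pr, 1e-12)))
    } else {
      softmax_xent(z, yy + 1L)$loss
    }
  }
  with_seed(seed, {
    par <- list()
    if (n_hidden > 0L) {
      par$W1 <- matrix(glorot_uniform(p * n_hidden, p, n_hidden), p, n_hidden)
      par$b1 <- numeric(n_hidden)
      par$W2 <- matrix(glorot_uniform(n_hidden * q, n_hidden, q), n_hidden, q)
    } else {
      par$W2 <- matrix(glorot_uniform(p * q, p, q), p, q)
    }
    par$b2 <- numeric(q)
    state <- adam_init(par)
    best <- list(loss = Inf, par = par, since = 0L)
    losses <- numeric(0)
    for (ep in seq_len(max_epochs)) {
      ord <- sample.int(n)
      bl <- numeric(0)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        yb <- y01[idx]
        f <- fwd(par, xb)
        if (output == "sigmoid") {
          pr <- stats::plogis(f$z[, 1])
          loss <- -mean(yb * log(pmax(pr, 1e-12)) +
                          (1 - yb) * log(pmax(1 - pr, 1e-12)))
          dz <- matrix((pr - yb) / length(yb), ncol = 1L)
        } else {
          ls <- softmax_xent(f$z, yb + 1L)
          loss <- ls$loss
          dz <- ls$dlogits
        }
        g <- list()
        if (n_hidden > 0L) {
          g$W2 <- crossprod(f$h, dz)
          dh <- (dz %*% t(par$W2)) * (f$h > 0)
          g$W1 <- crossprod(xb, dh)
          g$b1 <- colSums(dh)
          g <- g[c("W1", "b1", "W2")]
        } else {
          g$W2 <- crossprod(xb, dz)
        }
        g$b2 <- colSums(dz)
        st <- adam_step(par, g[names(par)], state, lr = learning_rate)
        par <- st$params
        state <- st$state
        bl <- c(bl, loss)
      }
      losses <- c(losses, mean(bl))
      if (!is.null(x_val)) {
        vl <- loss_of(par, x_val, y_val)
        if (vl < best$loss - 1e-8) {
          best <- list(loss = vl, par = par, since = 0L)
        } else {
          best$since <- best$since + 1L
          if (best$since >= patience) break
        }
      }
    }
    if (!is.null(x_val) && is.finite(best$loss)) par <- best$par
    list(par = par, loss_history = losses, output = output,
         n_hidden = as.integer(n_hidden))
  })
}

#' Configuration for the spectral one-hidden-layer network
#'
#' The network has exactly one hidden layer of rectified-linear units and a
#' single sigmoid output unit; weights are initialised from a uniform
#' distribution and optimised with Adam on binary cross-entropy.
#'
#' @param n_hidden Hidden-layer width (>= 1; the node sweep runs
#'   10, 20, ..., 100; default 90, the best standalone width reported for
#'   the emulated study).
#' @param max_epochs Maximum training epochs (default 200).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param patience Early-stopping patience on validation loss, in epochs
#'   (default 20; only used when a validation set is supplied).
#' @param seed Integer seed covering initialisation and shuffling.
#' @return A list of class `pf_mlp_config`.
#' @export
mlp_config <- function(n_hidden = 90L, max_epochs = 200L, batch_size = 32L,
                       learning_rate = 1e-3, patience = 20L, seed = 1L) {
  if (n_hidden < 1L) abort("`n_hidden` must be >= 1 (exactly one hidden layer).")
  structure(list(n_hidden = as.integer(n_hidden),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "pf_mlp_config")
}

#' Train the spectral network
#'
#' @param data A `pf_dataset` (needs `spectrum` and `label`); both classes
#'   must be present.
#' @param config An [mlp_config()].
#' @param validation Optional held-out `pf_dataset` for early stopping.
#' @return An object of class `pf_spectral_mlp` exposing [predict()] and
#'   [extract_spectral_features()].
#' @export
train_spectral_mlp <- function(data, config = mlp_config(), validation = NULL) {
  if (length(unique(as.character(data$label))) < 2L) {
    abort("Training data must contain both classes.")
  }
  x <- spectra_matrix(data)
  y <- encode_labels(data$label)
  xv <- yv <- NULL
  if (!is.null(validation)) {
    xv <- spectra_matrix(validation)
    yv <- encode_labels(validation$label)
  }
  fit <- mlp_core_fit(x, y, n_hidden = config$n_hidden, output = "sigmoid",
                      max_epochs = config$max_epochs,
                      batch_size = config$batch_size,
                      learning_rate = config$learning_rate,
                      seed = config$seed, x_val = xv, y_val = yv,
                      patience = config$patience)
  structure(
    list(par = fit$par, config = config, loss_history = fit$loss_history,
         wavelengths = attr(data, "wavelengths", exact = TRUE),
         n_bands = ncol(x)),
    class = "pf_spectral_mlp"
  )
}

check_grid <- function(model, x) {
  if (ncol(x) != model$n_bands) {
    abort(sprintf("Wavelength grid mismatch: model expects %d bands, got %d.",
                  model$n_bands, ncol(x)))
  }
  invisible(x)
}

#' @export
predict.pf_spectral_mlp <- function(object, data,
                                    type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- spectra_matrix(data)
  check_grid(object, x)
  h <- pmax(x %*% object$par$W1 + rep(object$par$b1, each = nrow(x)), 0)
  pr <- stats::plogis(as.vector(h %*% object$par$W2 + object$par$b2))
  if (type == "prob") {
    return(cbind(healthy = 1 - pr, diseased = pr))
  }
  factor(ifelse(pr >= 0.5, "diseased", "healthy"), levels = pf_labels())
}

#' Extract the spectral feature vector (hidden activations)
#'
#' Returns the post-activation hidden layer of the trained spectral network
#' for each sample — the length-`n_hidden`, non-negative feature vector
#' that feeds the fusion head. Deterministic given the model.
#'
#' @param model A `pf_spectral_mlp`.
#' @param data A `pf_dataset` on the same wavelength grid as training.
#' @return Numeric matrix `n x n_hidden`, rownames are sample ids.
#' @export
extract_spectral_features <- function(model, data) {
  x <- spectra_matrix(data)
  check_grid(model, x)
  h <- pmax(x %*% model$par$W1 + rep(model$par$b1, each = nrow(x)), 0)
  rownames(h) <- rownames(x)
  h
}

#' Sweep the hidden-layer width of the spectral network
#'
#' Trains one spectral network per grid value (each with an independently
#' derived seed), evaluates each on the validation set with the
#' macro-averaged metrics, and flags the best width by validation accuracy
#' (ties broken toward the smaller width).
#'
#' @param train,validation `pf_dataset` splits.
#' @param grid Integer vector of hidden widths (default `seq(10, 100, 10)`).
#' @param config Base [mlp_config()]; its `n_hidden` and `seed` are
#'   overridden per grid value.
#' @return A tibble of class `pf_sweep` with one row per width (columns
#'   `n_hidden`, `accuracy`, `precision`, `recall`, `f1`, confusion counts)
#'   and attributes `best_n_hidden` and `models` (the fitted networks).
#' @export
run_node_sweep <- function(train, validation, grid = seq(10L, 100L, by = 10L),
                           config = mlp_config()) {
  if (length(grid) == 0L) abort("`grid` must be non-empty.")
  models <- list()
  rows <- lapply(seq_along(grid), function(i) {
    cfg <- config
    cfg$n_hidden <- as.integer(grid[i])
    cfg$seed <- derive_seed(config$seed, i)
    m <- train_spectral_mlp(train, cfg, validation = validation)
    models[[as.character(grid[i])]] <<- m
    met <- compute_metrics(confusion_from_predictions(
      validation$label, predict(m, validation)))
    c(list(n_hidden = as.integer(grid[i])), metrics_row(met))
  })
  out <- dplyr::bind_rows(rows)
  best <- out$n_hidden[which.max(out$accuracy)]
  attr(out, "best_n_hidden") <- best
  attr(out, "models") <- models
  class(out) <- c("pf_sweep", class(out))
  out
}
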