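# Classical spectral baselines with their fixed, published hyperparameter
# presets: PLS-DA, polynomial-kernel SVM, shallow random forest, AdaBoost
# and XGBoost. PLS-DA, SVM, RF and XGBoost are fitted through the standard
# packages (mixOmics, e1071, ranger, xgboost); AdaBoost (SAMME.R with
# depth-limited CART trees) is implemented here.

#' Hyperparameter presets for the classical spectral baselines
#'
#' The shipped presets are the study's final, grid-search-selected settings:
#' PLS-DA with 8 latent components; SVM with a polynomial kernel, C = 601,
#' gamma = 0.15; a random forest limited to depth 20 with 15 trees and
#' minimum split size 3; AdaBoost and XGBoost each with 50 estimators at
#' learning rate 1.0. The AdaBoost and XGBoost lines are printed
#' identically in the source table (almost certainly a copy error); both
#' presets are kept as printed.
#'
#' @return A named list of `pf_baseline_preset` objects
#'   (`plsda`, `svm`, `random_forest`, `adaboost`, `xgboost`).
#' @export
baseline_presets <- function() {
  mk <- function(family, ...) {
    structure(list(model_family = family, hyperparameters = list(...)),
              class = "pf_baseline_preset")
  }
  list(
    plsda = mk("PLS-DA", n_components = 8L),
    svm = mk("SVM", C = 601, gamma = 0.15, kernel = "poly"),
    random_forest = mk("random-forest", max_depth = 20L, n_trees = 15L,
                       min_split = 3L),
    adaboost = mk("AdaBoost", n_estimators = 50L, learning_rate = 1.0,
                  algorithm = "SAMME.R"),
    xgboost = mk("XGBoost", n_estimators = 50L, learning_rate = 1.0)
  )
}

# Real-AdaBoost (SAMME.R) with depth-limited CART base learners on labels
# coded -1/+1.
fit_adaboost <- function(x, y01, n_estimators, learning_rate, seed,
                         max_depth = 1L) {
  df <- as.data.frame(x)
  yf <- factor(y01, levels = c(0, 1))
  n <- length(y01)
  ys <- ifelse(y01 == 1, 1, -1)
  w <- rep(1 / n, n)
  stumps <- vector("list", n_estimators)
  with_seed(seed, {
    for (m in seq_len(n_estimators)) {
      fit <- rpart::rpart(
        yf ~ ., data = cbind(df, yf = yf), weights = w, method = "class",
        control = rpart::rpart.control(maxdepth = max_depth, cp = 0,
                                       minsplit = 2, xval = 0)
      )
      p1 <- pmin(pmax(predict(fit)[, "1"], 1e-6), 1 - 1e-6)
      h <- 0.5 * log(p1 / (1 - p1))
      w <- w * exp(-learning_rate * ys * h)
      w <- w / sum(w)
      stumps[[m]] <- fit
    }
  })
  list(stumps = stumps, learning_rate = learning_rate)
}

predict_adaboost <- function(model, x) {
  df <- as.data.frame(x)
  score <- rep(0, nrow(df))
  for (fit in model$stumps) {
    p1 <- pmin(pmax(predict(fit, newdata = df)[, "1"], 1e-6), 1 - 1e-6)
    score <- score + model$learning_rate * 0.5 * log(p1 / (1 - p1))
  }
  as.integer(score > 0)
}

#' Train a classical spectral baseline
#'
#' Fits one of the five baseline families on the spectra with its preset
#' hyperparameters. PLS-DA is a latent-projection regression on the class
#' indicator with a maximum-distance class decision.
#'
#' @param data A `pf_dataset` training split.
#' @param preset A `pf_baseline_preset` or one of the names of
#'   [baseline_presets()].
#' @param seed Seed for the stochastic families.
#' @return An object of class `pf_baseline` exposing [predict()].
#' @export
train_baseline <- function(data, preset, seed = 1L) {
  if (is.character(preset)) {
    preset <- baseline_presets()[[match.arg(preset,
                                            names(baseline_presets()))]]
  }
  x <- spectra_matrix(data)
  y01 <- encode_labels(data$label)
  hp <- preset$hyperparameters
  fit <- switch(preset$model_family,
    "PLS-DA" = {
      ncomp <- hp$n_components
      if (ncomp > min(nrow(x) - 1L, ncol(x))) {
        abort("`n_components` exceeds the rank of the training spectra.")
      }
      mixOmics::plsda(x, factor(y01, levels = c(0, 1)), ncomp = ncomp)
    },
    "SVM" = e1071::svm(x, factor(y01, levels = c(0, 1)), cost = hp$C,
                       gamma = hp$gamma, kernel = "polynomial",
                       scale = FALSE),
    "random-forest" = {
      df <- data.frame(x, y = factor(y01, levels = c(0, 1)))
      ranger::ranger(y ~ ., data = df, num.trees = hp$n_trees,
                     max.depth = hp$max_depth, min.node.size = hp$min_split,
                     seed = seed, num.threads = 1L)
    },
    "AdaBoost" = fit_adaboost(x, y01, hp$n_estimators, hp$learning_rate,
                              seed = seed),
    "XGBoost" = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = hp$learning_rate,
                    nthread = 1L),
      data = xgboost::xgb.DMatrix(x, label = y01),
      nrounds = hp$n_estimators, verbose = 0
    ),
    abort(sprintf("Unknown baseline family '%s'.", preset$model_family))
  )
  structure(list(family = preset$model_family, preset = preset, fit = fit,
                 n_bands = ncol(x)),
            class = "pf_baseline")
}

#' @export
predict.pf_baseline <- function(object, data, ...) {
  x <- spectra_matrix(data)
  if (ncol(x) != object$n_bands) {
    abort("Wavelength grid mismatch with the training spectra.")
  }
  y01 <- switch(object$family,
    "PLS-DA" = {
      ncomp <- object$preset$hyperparameters$n_components
      cls <- predict(object$fit, x)$class$max.dist[, ncomp]
      as.integer(as.character(cls))
    },
    "SVM" = as.integer(as.character(predict(object$fit, x))),
    "random-forest" = {
      as.integer(as.character(predict(object$fit,
                                      data = data.frame(x))$predictions))
    },
    "AdaBoost" = predict_adaboost(object$fit, x),
    "XGBoost" = as.integer(predict(object$fit,
                                   xgboost::xgb.DMatrix(x)) >= 0.5)
  )
  factor(ifelse(y01 == 1, "diseased", "healthy"), levels = pf_labels())
}
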