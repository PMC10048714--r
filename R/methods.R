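# Plotting and broom-style methods for the result objects.

#' @export
autoplot.pf_confusion <- function(object, ...) {
  pos <- object$positive_label
  neg <- setdiff(pf_labels(), pos)
  df <- tibble(
    truth = factor(c(pos, pos, neg, neg), levels = pf_labels()),
    predicted = factor(c(pos, neg, pos, neg), levels = pf_labels()),
    count = c(object$tp, object$fn, object$fp, object$tn)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#3182bd") +
    ggplot2::labs(x = "Predicted", y = "True", fill = "n") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pf_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("n_hidden", "accuracy", "precision", "recall", "f1")],
    -"n_hidden", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_hidden, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Hidden-layer nodes", y = "Validation metric") +
    ggplot2::theme_minimal()
}

#' Plot a sample of spectra coloured by class
#'
#' @param ds A `pf_dataset`.
#' @param n_per_class Spectra drawn per class (default 15, deterministic:
#'   the first `n_per_class` of each).
#' @return A ggplot object.
#' @export
plot_spectra <- function(ds, n_per_class = 15L) {
  wl <- dataset_wavelengths(ds)
  keep <- unlist(lapply(pf_labels(), function(lv) {
    utils::head(which(ds$label == lv), n_per_class)
  }))
  df <- dplyr::bind_rows(lapply(keep, function(i) {
    tibble(sample_id = ds$sample_id[i], label = ds$label[i],
           wavelength = wl, reflectance = ds$spectrum[[i]])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength,
                                   y = .data$reflectance,
                                   group = .data$sample_id,
                                   colour = .data$label)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "Wavelength (nm)", y = "Reflectance") +
    ggplot2::theme_minimal()
}

#' @export
tidy.pf_metrics <- function(x, ...) {
  x$per_class
}

#' @export
glance.pf_metrics <- function(x, ...) {
  tibble(accuracy = x$accuracy, precision = x$precision, recall = x$recall,
         f1 = x$f1, total = with(x$confusion, tp + tn + fp + fn))
}

#' @export
tidy.pf_spectral_mlp <- function(x, ...) {
  tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @export
glance.pf_spectral_mlp <- function(x, ...) {
  tibble(n_hidden = x$config$n_hidden, n_bands = x$n_bands,
         epochs_run = length(x$loss_history),
         final_loss = x$loss_history[length(x$loss_history)])
}

#' @export
glance.pf_backbone <- function(x, ...) {
  tibble(family = x$spec$family, width_scale = x$spec$width_scale,
         input_size_px = x$spec$input_size_px,
         n_parameters = sum(vapply(bb_params(x), length, numeric(1))),
         trained = x$trained)
}

#' @export
glance.pf_fusion_model <- function(x, ...) {
  tibble(tap = x$tap_name, image_len = x$image_len,
         spectral_len = x$spectral_len,
         fused_len = x$image_len + x$spectral_len,
         standardised = !is.null(x$standardise_stats))
}

#' @export
print.pf_backbone <- function(x, ...) {
  cat(sprintf("<pf_backbone %s-style, width %.2g, input %dpx, %s>\n",
              x$spec$family, x$spec$width_scale, x$spec$input_size_px,
              if (x$trained) "trained" else "untrained"))
  cat("  taps:", paste(names(x$stages), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.pf_fusion_model <- function(x, ...) {
  cat(sprintf("<pf_fusion_model tap=%s |Fa|=%d |Fb|=%d>\n",
              x$tap_name, x$image_len, x$spectral_len))
  invisible(x)
}
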