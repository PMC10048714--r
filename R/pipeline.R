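# End-to-end experiment harness: simulate -> split -> spectral sweep +
# baselines -> image backbones -> fusion grid -> layer ablation -> worked
# examples -> report. Every stage draws its seed from the master seed by a
# counter-based derivation, so stages are independently reproducible.

#' Full-run configuration
#'
#' Serialisable description of an end-to-end experiment: the synthetic
#' generator settings, the split, both branch configurations, the fusion
#' settings, and the output directory. Round-trips losslessly through YAML
#' via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param n_per_class Samples per class for the simulated collection
#'   (default 100, the desk-scale size; the emulated study used 240).
#' @param synthetic Extra arguments passed to [synthetic_config()].
#' @param train_fraction Train share of the stratified split (default 0.7).
#' @param node_grid Spectral hidden-width grid (default 10, 20, ..., 100).
#' @param families Backbone families to train (default all six).
#' @param grid_backbones Families used in the fusion width-selection grid
#'   (default `c("vgg16", "resnet50")`).
#' @param ablation_backbones Families whose taps are ablated
#'   (default `c("resnet101", "xception")`).
#' @param input_size_px,width_scale Desk-scale backbone geometry.
#' @param image_epochs,spectral_epochs,head_epochs Training lengths.
#' @param output_dir Optional directory for CSVs/report.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `pf_config`.
#' @export
pipeline_config <- function(n_per_class = 100L,
                            synthetic = list(),
                            train_fraction = 0.7,
                            node_grid = seq(10L, 100L, by = 10L),
                            families = c("vgg16", "vgg19", "resnet50",
                                         "resnet101", "xception",
                                         "densenet201"),
                            grid_backbones = c("vgg16", "resnet50"),
                            ablation_backbones = c("resnet101", "xception"),
                            input_size_px = 64L,
                            width_scale = 0.25,
                            image_epochs = 15L,
                            spectral_epochs = 150L,
                            head_epochs = 60L,
                            output_dir = NULL,
                            seed = 1L) {
  structure(
    list(n_per_class = as.integer(n_per_class), synthetic = synthetic,
         train_fraction = train_fraction,
         node_grid = as.integer(node_grid), families = families,
         grid_backbones = grid_backbones,
         ablation_backbones = ablation_backbones,
         input_size_px = as.integer(input_size_px),
         width_scale = width_scale,
         image_epochs = as.integer(image_epochs),
         spectral_epochs = as.integer(spectral_epochs),
         head_epochs = as.integer(head_epochs),
         output_dir = output_dir, seed = as.integer(seed)),
    class = "pf_config"
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A `pf_config`.
#' @param path File path.
#' @return `path` (write) or the restored `pf_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

#' Hash of a configuration
#'
#' Stable hash identifying the configuration that produced a result row.
#' @param config A `pf_config` (or any R object).
#' @return A character scalar.
#' @export
config_hash <- function(config) rlang::hash(unclass(config))

pf_log <- function(verbose, stage, t0) {
  if (verbose) {
    message(sprintf("[pearfusion] %-14s %6.1fs", stage,
                    as.numeric(Sys.time()) - t0))
  }
}

#' Run the full fusion experiment sequence
#'
#' Executes, on synthetic data: dataset simulation, the stratified split,
#' the spectral node sweep plus the five classical baselines, from-scratch
#' training of the configured backbone families, the fusion grid (spectral
#' widths x grid backbones), the six-family fusion comparison at the
#' selected width, the layer-depth ablation, and the worked-example
#' reconstruction; optionally renders the report. Deterministic under a
#' fixed master seed.
#'
#' @param config A [pipeline_config()].
#' @param stages Subset of stage names to run (dependencies are run as
#'   needed); default all.
#' @param verbose Log stage timings (default TRUE).
#' @return A list with elements `tables` (named list of tibbles), `models`,
#'   `data` (the split), and `config`.
#' @export
run_experiments <- function(config = pipeline_config(),
                            stages = c("spectral", "image", "fusion_grid",
                                       "fusion_families", "ablation",
                                       "reconstruct", "report"),
                            verbose = TRUE) {
  t0 <- as.numeric(Sys.time())
  hash <- config_hash(config)
  tables <- list()
  models <- list()

  syn_args <- c(list(n_per_class = config$n_per_class,
                     seed = derive_seed(config$seed, 1L)),
                config$synthetic)
  ds <- do.call(synthetic_config, syn_args)
  ds <- generate_paired_dataset(ds)
  pf_log(verbose, "simulate", t0)

  split <- split_dataset(ds, config$train_fraction,
                         seed = derive_seed(config$seed, 2L))
  pf_log(verbose, "split", t0)

  sweep_tbl <- NULL
  if (any(c("spectral", "fusion_grid", "fusion_families", "ablation")
          %in% stages)) {
    sweep_tbl <- run_node_sweep(
      split$train, split$validation, grid = config$node_grid,
      config = mlp_config(max_epochs = config$spectral_epochs,
                          seed = derive_seed(config$seed, 3L))
    )
    models$spectral_sweep <- attr(sweep_tbl, "models")
    if ("spectral" %in% stages) {
      base_rows <- lapply(names(baseline_presets()), function(nm) {
        m <- train_baseline(split$train, nm,
                            seed = derive_seed(config$seed, 4L))
        met <- evaluate_predictions(split$validation$label,
                                    predict(m, split$validation))
        c(list(model = nm), metrics_row(met))
      })
      tables$spectral_models <- dplyr::bind_rows(
        c(list(c(list(model = sprintf("MLP_%d",
                                      attr(sweep_tbl, "best_n_hidden"))),
               metrics_row(compute_metrics(confusion_2x2(
                 tp = sweep_tbl$tp[which.max(sweep_tbl$accuracy)],
                 tn = sweep_tbl$tn[which.max(sweep_tbl$accuracy)],
                 fp = sweep_tbl$fp[which.max(sweep_tbl$accuracy)],
                 fn = sweep_tbl$fn[which.max(sweep_tbl$accuracy)]))))),
          base_rows)
      )
      tables$node_sweep <- as_tibble(sweep_tbl)
      pf_log(verbose, "spectral", t0)
    }
  }

  backbones <- list()
  need_image <- any(c("image", "fusion_grid", "fusion_families", "ablation")
                    %in% stages)
  if (need_image) {
    wanted <- unique(c(
      if (any(c("image", "fusion_families") %in% stages)) config$families,
      if ("fusion_grid" %in% stages) config$grid_backbones,
      if ("ablation" %in% stages) config$ablation_backbones
    ))
    img_rows <- list()
    for (i in seq_along(wanted)) {
      fam <- wanted[i]
      bb <- build_backbone(desk_backbone_spec(
        fam, seed = derive_seed(config$seed, 10L + i),
        input_size_px = config$input_size_px,
        width_scale = config$width_scale
      ))
      bb <- train_image_classifier(bb, split$train, image_train_config(
        max_epochs = config$image_epochs,
        seed = derive_seed(config$seed, 30L + i)
      ))
      backbones[[fam]] <- bb
      met <- evaluate_predictions(split$validation$label,
                                  predict(bb, split$validation))
      img_rows[[fam]] <- c(list(model = fam), metrics_row(met))
      pf_log(verbose, paste0("image:", fam), t0)
    }
    models$backbones <- backbones
    if ("image" %in% stages) {
      tables$image_models <- dplyr::bind_rows(
        img_rows[intersect(config$families, names(img_rows))])
    }
  }

  best_n <- attr(sweep_tbl, "best_n_hidden") %||% 30L
  if ("fusion_grid" %in% stages) {
    tables$fusion_grid <- run_fusion_grid(
      split$train, split$validation,
      backbones[config$grid_backbones],
      grid = config$node_grid,
      mlp_config = mlp_config(max_epochs = config$spectral_epochs,
                              seed = derive_seed(config$seed, 5L)),
      config = fusion_config(max_epochs = config$head_epochs,
                             seed = derive_seed(config$seed, 6L))
    )
    best_n <- attr(tables$fusion_grid, "best_n_hidden")
    pf_log(verbose, "fusion_grid", t0)
  }

  fusion_mlp <- NULL
  if (any(c("fusion_families", "ablation") %in% stages)) {
    fusion_mlp <- train_spectral_mlp(
      split$train,
      mlp_config(n_hidden = best_n, max_epochs = config$spectral_epochs,
                 seed = derive_seed(config$seed, 7L)),
      validation = split$validation
    )
    models$fusion_mlp <- fusion_mlp
  }

  if ("fusion_families" %in% stages) {
    rows <- lapply(seq_along(config$families), function(i) {
      fam <- config$families[i]
      fm <- train_fusion_head(fusion_mlp, backbones[[fam]], split$train,
                              fusion_config(
                                max_epochs = config$head_epochs,
                                seed = derive_seed(config$seed, 40L + i)))
      met <- evaluate_predictions(split$validation$label,
                                  predict(fm, split$validation))
      c(list(model = sprintf("MLP_%d_%s", best_n, fam)), metrics_row(met))
    })
    tables$fusion_families <- dplyr::bind_rows(rows)
    pf_log(verbose, "fusion_families", t0)
  }

  if ("ablation" %in% stages) {
    abl <- lapply(seq_along(config$ablation_backbones), function(i) {
      fam <- config$ablation_backbones[i]
      tbl <- run_layer_ablation(
        fusion_mlp, backbones[[fam]], split$train, split$validation,
        config = fusion_config(max_epochs = config$head_epochs,
                               seed = derive_seed(config$seed, 50L + i)))
      tbl$model <- sprintf("MLP_%d_%s_%s", best_n, fam, tbl$tap)
      tbl
    })
    tables$layer_ablation <- dplyr::bind_rows(abl)
    pf_log(verbose, "ablation", t0)
  }

  if ("reconstruct" %in% stages) {
    tables$worked_examples <- reconstruct_worked_examples()
  }

  tables <- lapply(tables, function(tbl) {
    tbl$config_hash <- hash
    tbl
  })

  if ("report" %in% stages && !is.null(config$output_dir)) {
    render_report(tables, config$output_dir)
    pf_log(verbose, "report", t0)
  }

  list(tables = tables, models = models, data = split, config = config)
}
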