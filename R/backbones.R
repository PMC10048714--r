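#' Declarative specification of a convolutional backbone
#'
#' Describes a backbone family, its width/depth scale, input size and named
#' tap points. At `width_scale = 1` and the default block repeats the
#' families follow their published block patterns: the resnet styles
#' reproduce the canonical five-stage spatial sizes (112, 56, 28, 14, 7 at
#' input 224) and the xception style pools its exit flow to a 2048-length
#' vector. Reduced `width_scale`, `input_size_px` and `block_repeats` give
#' desk-scale networks that preserve the per-stage halving pattern and are
#' cheap enough to train from scratch on a laptop CPU.
#'
#' @param family One of `"vgg16"`, `"vgg19"`, `"resnet50"`, `"resnet101"`,
#'   `"xception"`, `"densenet201"` (all "-style" re-implementations of the
#'   published block patterns; no pretrained weights are involved).
#' @param width_scale Channel-count multiplier (1 = published widths).
#' @param input_size_px Square input size fed to the network; images are
#'   resized internally to this size.
#' @param block_repeats Optional integer vector overriding the per-stage
#'   block repeat counts (resnet: 4 stages; vgg: 5 conv blocks; densenet:
#'   4 dense blocks). `NULL` uses the family's published counts.
#' @param middle_flow_repeats Number of xception-style middle-flow blocks
#'   (published pattern: 8).
#' @param seed Seed for parameter initialisation.
#' @return An object of class `pf_backbone_spec`.
#' @export
backbone_spec <- function(family = c("resnet101", "resnet50", "vgg16", "vgg19",
                                     "xception", "densenet201"),
                          width_scale = 1,
                          input_size_px = 224L,
                          block_repeats = NULL,
                          middle_flow_repeats = 8L,
                          seed = 1L) {
  family <- match.arg(family)
  defaults <- switch(family,
    resnet50 = c(3L, 4L, 6L, 3L),
    resnet101 = c(3L, 4L, 23L, 3L),
    vgg16 = c(2L, 2L, 3L, 3L, 3L),
    vgg19 = c(2L, 2L, 4L, 4L, 4L),
    densenet201 = c(6L, 12L, 48L, 32L),
    xception = NULL
  )
  if (is.null(block_repeats)) block_repeats <- defaults
  if (!is.null(defaults) && length(block_repeats) != length(defaults)) {
    abort(sprintf("`block_repeats` for %s must have length %d.",
                  family, length(defaults)))
  }
  if (width_scale <= 0) abort("`width_scale` must be positive.")
  structure(
    list(family = family,
         width_scale = width_scale,
         input_size_px = as.integer(input_size_px),
         block_repeats = block_repeats,
         middle_flow_repeats = as.integer(middle_flow_repeats),
         tap_points = backbone_tap_names(family),
         seed = as.integer(seed)),
    class = "pf_backbone_spec"
  )
}

#' Tap-point names of a backbone family
#' @param family Backbone family name.
#' @return Character vector of ordered tap names, shallow to deep.
#' @export
backbone_tap_names <- function(family) {
  switch(family,
    resnet50 = ,
    resnet101 = paste0("layer", 1:5),
    vgg16 = ,
    vgg19 = paste0("block", 1:5),
    densenet201 = paste0("block", 1:4),
    xception = c("entry_flow", "middle_flow", "exit_flow"),
    abort(sprintf("Unknown backbone family '%s'.", family))
  )
}

#' Desk-scale backbone specification
#'
#' Convenience wrapper returning a reduced-scale spec (64 px input, quarter
#' width, single-repeat stages, two middle-flow blocks) that trains from
#' scratch in seconds while preserving each family's stage structure and
#' halving pattern.
#'
#' @inheritParams backbone_spec
#' @export
desk_backbone_spec <- function(family, seed = 1L,
                               input_size_px = 64L, width_scale = 0.25) {
  reps <- switch(family,
    resnet50 = ,
    resnet101 = c(1L, 1L, 1L, 1L),
    vgg16 = ,
    vgg19 = c(1L, 1L, 1L, 1L, 1L),
    densenet201 = c(2L, 2L, 2L, 2L),
    xception = NULL
  )
  backbone_spec(family, width_scale = width_scale,
                input_size_px = input_size_px, block_repeats = reps,
                middle_flow_repeats = 2L, seed = seed)
}

chw <- function(c, w) max(1L, as.integer(round(c * w)))

resnet_bottleneck <- function(in_ch, mid, out, stride = 1L) {
  shortcut <- if (in_ch != out || stride != 1L) {
    nn_conv(in_ch, out, 1L, stride = stride, pad = 0L)
  }
  nn_res(
    main = nn_seq(
      nn_conv(in_ch, mid, 1L, stride = stride, pad = 0L), nn_relu(),
      nn_conv(mid, mid, 3L, pad = 1L), nn_relu(),
      nn_conv(mid, out, 1L, pad = 0L)
    ),
    shortcut = shortcut, post_relu = TRUE
  )
}

resnet_stage <- function(in_ch, mid, out, reps, stride, lead = NULL) {
  nodes <- if (is.null(lead)) list() else list(lead)
  nodes <- c(nodes, list(resnet_bottleneck(in_ch, mid, out, stride)))
  for (i in seq_len(reps - 1L)) {
    nodes <- c(nodes, list(resnet_bottleneck(out, mid, out, 1L)))
  }
  nn_seq(nodes)
}

build_resnet <- function(spec) {
  w <- spec$width_scale
  r <- spec$block_repeats
  c64 <- chw(64, w); c128 <- chw(128, w); c256 <- chw(256, w)
  c512 <- chw(512, w); c1024 <- chw(1024, w); c2048 <- chw(2048, w)
  stages <- list(
    layer1 = nn_seq(nn_conv(3L, c64, 7L, stride = 2L, pad = 3L), nn_relu()),
    layer2 = resnet_stage(c64, c64, c256, r[1], 1L,
                          lead = nn_maxpool(3L, 2L, pad = 1L)),
    layer3 = resnet_stage(c256, c128, c512, r[2], 2L),
    layer4 = resnet_stage(c512, c256, c1024, r[3], 2L),
    layer5 = resnet_stage(c1024, c512, c2048, r[4], 2L)
  )
  list(stages = stages, out_ch = c2048)
}

build_vgg <- function(spec) {
  w <- spec$width_scale
  reps <- spec$block_repeats
  chans <- vapply(c(64, 128, 256, 512, 512), chw, integer(1), w = w)
  in_ch <- 3L
  stages <- list()
  for (i in seq_along(chans)) {
    nodes <- list()
    for (j in seq_len(reps[i])) {
      nodes <- c(nodes, list(nn_conv(in_ch, chans[i], 3L, pad = 1L), nn_relu()))
      in_ch <- chans[i]
    }
    nodes <- c(nodes, list(nn_maxpool(2L, 2L)))
    stages[[paste0("block", i)]] <- nn_seq(nodes)
  }
  list(stages = stages, out_ch = in_ch)
}

xception_sep <- function(in_ch, out_ch) {
  nn_seq(nn_dwconv(in_ch, 3L, pad = 1L), nn_conv(in_ch, out_ch, 1L, pad = 0L))
}

xception_entry_block <- function(in_ch, out_ch, leading_relu = TRUE) {
  main <- list()
  if (leading_relu) main <- list(nn_relu())
  main <- c(main, list(
    xception_sep(in_ch, out_ch), nn_relu(),
    xception_sep(out_ch, out_ch), nn_maxpool(3L, 2L, pad = 1L)
  ))
  nn_res(nn_seq(main),
         shortcut = nn_conv(in_ch, out_ch, 1L, stride = 2L, pad = 0L),
         post_relu = FALSE)
}

build_xception <- function(spec) {
  w <- spec$width_scale
  c32 <- chw(32, w); c64 <- chw(64, w); c128 <- chw(128, w)
  c256 <- chw(256, w); c728 <- chw(728, w); c1024 <- chw(1024, w)
  c1536 <- chw(1536, w); c2048 <- chw(2048, w)
  middle_block <- function() {
    nn_res(nn_seq(
      nn_relu(), xception_sep(c728, c728),
      nn_relu(), xception_sep(c728, c728),
      nn_relu(), xception_sep(c728, c728)
    ), shortcut = NULL, post_relu = FALSE)
  }
  stages <- list(
    entry_flow = nn_seq(
      nn_conv(3L, c32, 3L, stride = 2L, pad = 1L), nn_relu(),
      nn_conv(c32, c64, 3L, pad = 1L), nn_relu(),
      xception_entry_block(c64, c128, leading_relu = FALSE),
      xception_entry_block(c128, c256),
      xception_entry_block(c256, c728)
    ),
    middle_flow = nn_seq(lapply(seq_len(spec$middle_flow_repeats),
                                function(i) middle_block())),
    exit_flow = nn_seq(
      nn_res(nn_seq(
        nn_relu(), xception_sep(c728, c728),
        nn_relu(), xception_sep(c728, c1024), nn_maxpool(3L, 2L, pad = 1L)
      ), shortcut = nn_conv(c728, c1024, 1L, stride = 2L, pad = 0L),
         post_relu = FALSE),
      xception_sep(c1024, c1536), nn_relu(),
      xception_sep(c1536, c2048), nn_relu(),
      nn_gapmap()
    )
  )
  list(stages = stages, out_ch = c2048)
}

build_densenet <- function(spec) {
  w <- spec$width_scale
  g <- chw(32, w)
  dense_layer <- function(in_ch) {
    nn_seq(nn_conv(in_ch, 4L * g, 1L, pad = 0L), nn_relu(),
           nn_conv(4L * g, g, 3L, pad = 1L), nn_relu())
  }
  dense_block <- function(in_ch, n) {
    layers <- vector("list", n)
    cur <- in_ch
    for (i in seq_len(n)) {
      layers[[i]] <- dense_layer(cur)
      cur <- cur + g
    }
    list(node = nn_dense_block(layers), out_ch = cur)
  }
  reps <- spec$block_repeats
  c0 <- chw(64, w)
  stem <- list(nn_conv(3L, c0, 7L, stride = 2L, pad = 3L), nn_relu(),
               nn_maxpool(3L, 2L, pad = 1L))
  stages <- list()
  cur <- c0
  for (i in seq_along(reps)) {
    lead <- if (i == 1L) {
      stem
    } else {
      half <- max(1L, cur %/% 2L)
      tr <- list(nn_conv(cur, half, 1L, pad = 0L), nn_relu(), nn_avgpool2())
      cur <- half
      tr
    }
    db <- dense_block(cur, reps[i])
    stages[[paste0("block", i)]] <- nn_seq(c(lead, list(db$node)))
    cur <- db$out_ch
  }
  list(stages = stages, out_ch = cur)
}

#' Build a convolutional backbone with named tap points
#'
#' Constructs the network described by a [backbone_spec()]: the family's
#' stage structure with feature taps at each named stage boundary, plus a
#' two-class classification head (global average pooling, a dense layer to
#' two class scores, softmax). Parameter initialisation is seeded from
#' `spec$seed`.
#'
#' @param spec A `pf_backbone_spec`.
#' @return An object of class `pf_backbone`.
#' @export
build_backbone <- function(spec) {
  if (!inherits(spec, "pf_backbone_spec")) abort("`spec` must be a backbone_spec().")
  built <- with_seed(spec$seed, {
    b <- switch(spec$family,
      resnet50 = ,
      resnet101 = build_resnet(spec),
      vgg16 = ,
      vgg19 = build_vgg(spec),
      xception = build_xception(spec),
      densenet201 = build_densenet(spec)
    )
    b$head <- nn_dense(b$out_ch, 2L)
    b
  })
  structure(
    list(spec = spec, stages = built$stages, head = built$head,
         out_ch = built$out_ch, trained = FALSE, loss_history = NULL),
    class = "pf_backbone"
  )
}

# Forward through the stages (optionally collecting tap outputs), then the
# head. `upto` stops after the named tap. Returns logits and/or taps.
backbone_forward <- function(bb, x, keep = FALSE, taps = FALSE, upto = NULL) {
  tap_out <- list()
  caches <- list()
  for (nm in names(bb$stages)) {
    r <- nn_forward(bb$stages[[nm]], x, keep)
    x <- r$y
    if (keep) caches[[nm]] <- r$cache
    if (taps) tap_out[[nm]] <- x
    if (!is.null(upto) && nm == upto) {
      return(list(tap = x, taps = tap_out))
    }
  }
  rg <- nn_forward(nn_gap(), x, keep)
  rh <- nn_forward(bb$head, rg$y, keep)
  list(logits = rh$y, taps = tap_out,
       caches = if (keep) list(stages = caches, gap = rg$cache, head = rh$cache))
}

#' Spatial sizes and channel counts at each tap point
#'
#' Runs one forward pass on a blank input of the spec's size and reports
#' each tap's output shape, e.g. to confirm that a full-width resnet-style
#' backbone reproduces the canonical stage sizes 112, 56, 28, 14, 7 at
#' input 224.
#'
#' @param bb A `pf_backbone`.
#' @return A tibble with columns `tap`, `height`, `width`, `channels`.
#' @export
tap_shapes <- function(bb) {
  s <- bb$spec$input_size_px
  x <- array(0, c(s, s, 1L, 3L))
  r <- backbone_forward(bb, x, taps = TRUE)
  tibble(
    tap = names(r$taps),
    height = vapply(r$taps, function(t) dim(t)[1], integer(1),
                    USE.NAMES = FALSE),
    width = vapply(r$taps, function(t) dim(t)[2], integer(1),
                   USE.NAMES = FALSE),
    channels = vapply(r$taps, function(t) dim(t)[4], integer(1),
                      USE.NAMES = FALSE)
  )
}
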