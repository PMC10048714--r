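test_that("every family builds at desk scale and predicts a probability pair", {
  ds <- easy_image_dataset(n_per_class = 2L, image_size_px = 16L)
  for (fam in c("vgg16", "vgg19", "resnet50", "resnet101", "xception",
                "densenet201")) {
    bb <- build_backbone(desk_backbone_spec(fam, input_size_px = 64L,
                                            width_scale = 0.25, seed = 2L))
    expect_s3_class(bb, "pf_backbone")
    expect_equal(names(bb$stages), backbone_tap_names(fam))
    p <- predict(bb, ds, type = "prob")
    expect_equal(dim(p), c(4L, 2L))
    expect_equal(unname(rowSums(p)), rep(1, 4), tolerance = 1e-12)
  }
})

test_that("tap spatial size never increases with depth in any family", {
  for (fam in c("vgg16", "resnet101", "xception", "densenet201")) {
    bb <- build_backbone(desk_backbone_spec(fam, input_size_px = 64L,
                                            width_scale = 0.25, seed = 3L))
    sh <- tap_shapes(bb)
    expect_true(all(diff(sh$height) <= 0))
    expect_true(all(diff(sh$width) <= 0))
  }
})

test_that("desk-scale resnet preserves the per-stage halving pattern", {
  bb <- build_backbone(desk_backbone_spec("resnet50", input_size_px = 64L))
  expect_equal(tap_shapes(bb)$height, c(32L, 16L, 8L, 4L, 2L))
})

test_that("backbone construction is seed-deterministic", {
  spec <- desk_backbone_spec("resnet50", seed = 7L, input_size_px = 32L)
  b1 <- build_backbone(spec)
  b2 <- build_backbone(spec)
  expect_identical(pearfusion:::bb_params(b1), pearfusion:::bb_params(b2))
})

test_that("unknown families and taps are rejected", {
  expect_error(backbone_spec("alexnet"))
  expect_error(backbone_tap_names("lenet"), "Unknown backbone family")
  bb <- build_backbone(desk_backbone_spec("vgg16", input_size_px = 32L))
  ds <- easy_image_dataset(n_per_class = 1L, image_size_px = 16L)
  expect_error(extract_features_at_tap(bb, ds, "layer9"), "Unknown tap")
})

test_that("a small backbone learns an easy colour separation", {
  ds <- easy_image_dataset(n_per_class = 10L, image_size_px = 32L, seed = 21L)
  bb <- build_backbone(desk_backbone_spec("resnet50", input_size_px = 32L,
                                          width_scale = 0.25, seed = 4L))
  bb <- train_image_classifier(bb, ds, image_train_config(max_epochs = 12L,
                                                          seed = 5L))
  acc <- mean(predict(bb, ds) == ds$label)
  expect_gte(acc, 0.95)
  expect_true(bb$trained)
})

test_that("image training is seed-deterministic", {
  ds <- easy_image_dataset(n_per_class = 4L, image_size_px = 16L, seed = 9L)
  train_once <- function() {
    bb <- build_backbone(desk_backbone_spec("vgg16", input_size_px = 16L,
                                            width_scale = 0.125, seed = 6L))
    train_image_classifier(bb, ds, image_train_config(max_epochs = 3L,
                                                      seed = 7L))
  }
  b1 <- train_once()
  b2 <- train_once()
  expect_identical(b1$loss_history, b2$loss_history)
  expect_identical(pearfusion:::bb_params(b1), pearfusion:::bb_params(b2))
  expect_error(
    train_image_classifier(build_backbone(desk_backbone_spec("vgg16")),
                           ds[ds$label == "healthy", ]),
    "both classes"
  )
})

test_that("tap feature extraction is deterministic and correctly shaped", {
  ds <- easy_image_dataset(n_per_class = 2L, image_size_px = 16L)
  bb <- build_backbone(desk_backbone_spec("resnet50", input_size_px = 32L,
                                          width_scale = 0.25, seed = 8L))
  m1 <- extract_features_at_tap(bb, ds, "layer5")
  m2 <- extract_features_at_tap(bb, ds, "layer5")
  expect_identical(m1, m2)
  expect_length(m1, nrow(ds))
  d <- dim(m1[[1]])
  expect_equal(d[1:2], c(1L, 1L))
  fa <- extract_image_feature_matrix(bb, ds, "layer5")
  expect_equal(dim(fa), c(nrow(ds), prod(d)))
  expect_equal(unname(fa[1, ]), flatten(m1[[1]]))
})
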