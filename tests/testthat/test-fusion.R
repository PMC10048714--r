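test_that("fusion is exact concatenation, image features first", {
  expect_equal(as.vector(fuse_features(c(1, 2), 3)), c(1, 2, 3))
  ff <- fuse_features(c(1, 2), c(3, 4, 5))
  expect_equal(attr(ff, "image_len"), 2L)
  expect_equal(attr(ff, "spectral_len"), 3L)

  # empty spectral side: fusion is the identity on the image features
  fa_only <- fuse_features(c(9, 8), numeric(0))
  expect_equal(as.vector(fa_only), c(9, 8))
  expect_error(fuse_features(numeric(0), numeric(0)), "empty")
})

test_that("fused vectors conserve both inputs bit-for-bit", {
  withr::with_seed(14, {
    for (i in 1:20) {
      fa <- rnorm(sample(1:2048, 1))
      fb <- rnorm(sample(1:100, 1))
      ff <- fuse_features(fa, fb)
      expect_identical(as.vector(ff[seq_along(fa)]), fa)
      expect_identical(as.vector(ff[length(fa) + seq_along(fb)]), fb)
      expect_length(ff, length(fa) + length(fb))
    }
  })
  # the emulated study's headline sizes: 2048 image + 30 spectral = 2078
  expect_length(fuse_features(rnorm(2048), rnorm(30)), 2078L)
})

test_that("matrix fusion aligns paired samples by id and rejects unpaired", {
  fa <- matrix(1:6, 2, dimnames = list(c("s1", "s2"), NULL))
  fb <- matrix(7:10, 2, dimnames = list(c("s2", "s1"), NULL))
  ff <- fuse_features(fa, fb)
  expect_equal(ff["s1", 4:5], c(8, 10), ignore_attr = TRUE)
  fb_bad <- matrix(7:10, 2, dimnames = list(c("s3", "s1"), NULL))
  expect_error(fuse_features(fa, fb_bad), "Unpaired")
})

test_that("a head fed constant features predicts at the class prior", {
  withr::with_seed(15, {
    x <- matrix(1, 60, 8)
    y <- rep(c(0L, 1L), 30)
    fit <- pearfusion:::mlp_core_fit(x, y, n_hidden = 0L, output = "softmax",
                                     max_epochs = 30L, seed = 1L)
    z <- x %*% fit$par$W2 + rep(fit$par$b2, each = nrow(x))
    acc <- mean((max.col(z) - 1L) == y)
    expect_gte(acc, 0.35)
    expect_lte(acc, 0.65)
  })
})

test_that("fusion head training freezes both branches", {
  ds <- easy_image_dataset(n_per_class = 6L, image_size_px = 16L, seed = 31L)
  sm <- train_spectral_mlp(ds, mlp_config(n_hidden = 10L, max_epochs = 20L,
                                          seed = 1L))
  bb <- build_backbone(desk_backbone_spec("vgg16", input_size_px = 16L,
                                          width_scale = 0.125, seed = 2L))
  bb <- train_image_classifier(bb, ds, image_train_config(max_epochs = 2L,
                                                          seed = 3L))
  par_before <- list(spec = sm$par, img = pearfusion:::bb_params(bb))
  fm <- train_fusion_head(sm, bb, ds, fusion_config(max_epochs = 10L,
                                                    seed = 4L))
  expect_identical(fm$spectral_model$par, par_before$spec)
  expect_identical(pearfusion:::bb_params(fm$image_model), par_before$img)
  expect_equal(fm$tap_name, "block5")
  expect_equal(fm$spectral_len, 10L)
  expect_s3_class(predict(fm, ds), "factor")
  g <- glance(fm)
  expect_equal(g$fused_len, g$image_len + g$spectral_len)
})

test_that("the fusion grid covers every pair and is internally consistent", {
  ds <- easy_image_dataset(n_per_class = 8L, image_size_px = 16L, seed = 32L)
  sp <- split_dataset(ds, 0.7, seed = 1)
  mk_bb <- function(fam, seed) {
    train_image_classifier(
      build_backbone(desk_backbone_spec(fam, input_size_px = 16L,
                                        width_scale = 0.125, seed = seed)),
      sp$train, image_train_config(max_epochs = 2L, seed = seed)
    )
  }
  bbs <- list(vgg16 = mk_bb("vgg16", 5L), resnet50 = mk_bb("resnet50", 6L))
  tbl <- run_fusion_grid(sp$train, sp$validation, bbs, grid = c(10L, 20L),
                         mlp_config = mlp_config(max_epochs = 15L, seed = 7L),
                         config = fusion_config(max_epochs = 10L, seed = 8L))
  expect_equal(nrow(tbl), 4L)
  expect_setequal(unique(tbl$backbone), c("vgg16", "resnet50"))
  n_val <- nrow(sp$validation)
  expect_equal(tbl$accuracy, (tbl$tp + tbl$tn) / n_val)
  expect_true(all(tbl$accuracy >= 0 & tbl$accuracy <= 1))
  expect_true(attr(tbl, "best_n_hidden") %in% c(10L, 20L))

  single <- run_fusion_grid(sp$train, sp$validation, bbs["vgg16"],
                            grid = 10L,
                            mlp_config = mlp_config(max_epochs = 5L),
                            config = fusion_config(max_epochs = 5L))
  expect_equal(nrow(single), 1L)
})

test_that("the layer ablation varies only the tap", {
  ds <- easy_image_dataset(n_per_class = 8L, image_size_px = 16L, seed = 33L)
  sp <- split_dataset(ds, 0.7, seed = 2)
  sm <- train_spectral_mlp(sp$train, mlp_config(n_hidden = 10L,
                                                max_epochs = 15L, seed = 1L))
  bb <- train_image_classifier(
    build_backbone(desk_backbone_spec("resnet50", input_size_px = 32L,
                                      width_scale = 0.125, seed = 2L)),
    sp$train, image_train_config(max_epochs = 2L, seed = 3L)
  )
  tbl <- run_layer_ablation(sm, bb, sp$train, sp$validation,
                            config = fusion_config(max_epochs = 8L,
                                                   seed = 4L))
  expect_equal(tbl$tap, paste0("layer", 1:5))
  one <- run_layer_ablation(sm, bb, sp$train, sp$validation, taps = "layer3",
                            config = fusion_config(max_epochs = 5L))
  expect_equal(nrow(one), 1L)
})
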