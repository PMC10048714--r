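# Finite-difference verification of the network engine. The probe network
# exercises every layer type the backbones use: plain/strided convolution,
# depthwise convolution, max pooling, residual blocks (with and without a
# projection shortcut), dense concatenation blocks, average pooling, global
# pooling and the dense head. Biases are randomised before checking so no
# pre-activation sits exactly on the rectifier kink.

ns <- asNamespace("pearfusion")

probe_net <- function() {
  ns$nn_seq(
    ns$nn_conv(2, 3, 3, stride = 1, pad = 1), ns$nn_relu(),
    ns$nn_res(ns$nn_seq(ns$nn_conv(3, 2, 1, pad = 0), ns$nn_relu(),
                        ns$nn_conv(2, 4, 3, pad = 1)),
              shortcut = ns$nn_conv(3, 4, 1, pad = 0), post_relu = TRUE),
    ns$nn_dwconv(4, 3, pad = 1),
    ns$nn_maxpool(3, 2, pad = 1),
    ns$nn_dense_block(list(
      ns$nn_seq(ns$nn_conv(4, 2, 1, pad = 0), ns$nn_relu()),
      ns$nn_seq(ns$nn_conv(6, 2, 3, pad = 1), ns$nn_relu())
    )),
    ns$nn_avgpool2()
  )
}

randomise_biases <- function(net) {
  params <- ns$nn_params(net)
  for (i in seq_along(params)) {
    if (is.null(dim(params[[i]]))) {
      params[[i]] <- params[[i]] + rnorm(length(params[[i]]), 0, 0.1)
    }
  }
  ns$nn_set_params(net, params)$node
}

test_that("analytic gradients match finite differences for every layer type", {
  withr::with_seed(12, {
    net <- randomise_biases(probe_net())
    x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
    y <- c(1L, 2L)
    gp <- ns$nn_gap()
    f0 <- ns$nn_forward(net, x, keep = TRUE)
    head_ <- ns$nn_dense(dim(f0$y)[4], 2)

    loss_of <- function(nn, x) {
      f <- ns$nn_forward(nn, x, keep = TRUE)
      g <- ns$nn_forward(gp, f$y, keep = TRUE)
      h <- ns$nn_forward(head_, g$y, keep = TRUE)
      ns$softmax_xent(h$y, y)$loss
    }

    f <- ns$nn_forward(net, x, keep = TRUE)
    g <- ns$nn_forward(gp, f$y, keep = TRUE)
    h <- ns$nn_forward(head_, g$y, keep = TRUE)
    ls <- ns$softmax_xent(h$y, y)
    bh <- ns$nn_backward(head_, h$cache, ls$dlogits)
    bg <- ns$nn_backward(gp, g$cache, bh$dx)
    bn <- ns$nn_backward(net, f$cache, bg$dx)

    params <- ns$nn_params(net)
    expect_length(bn$grads, length(params))
    eps <- 1e-5
    for (pi in seq_along(params)) {
      probe <- withr::with_seed(pi, sample.int(length(params[[pi]]), 2))
      for (j in probe) {
        p2 <- params
        p2[[pi]][j] <- params[[pi]][j] + eps
        lp <- loss_of(ns$nn_set_params(net, p2)$node, x)
        p2[[pi]][j] <- params[[pi]][j] - eps
        lm <- loss_of(ns$nn_set_params(net, p2)$node, x)
        num <- (lp - lm) / (2 * eps)
        expect_equal(bn$grads[[pi]][j], num, tolerance = 1e-4)
      }
    }

    # input gradient
    j <- 17L
    x2 <- x
    x2[j] <- x[j] + eps
    lp <- loss_of(net, x2)
    x2[j] <- x[j] - eps
    lm <- loss_of(net, x2)
    expect_equal(bn$dx[j], (lp - lm) / (2 * eps), tolerance = 1e-4)
  })
})

test_that("flatten is a conservation-preserving reshape with fixed ordering", {
  m <- array(0:11, c(2, 2, 3))
  v <- flatten(m)
  expect_length(v, 12)
  expect_setequal(v, 0:11)
  # row-major (height, width, channel): channel varies fastest
  H <- 2L; W <- 2L; C <- 3L
  for (h in 1:H) for (w in 1:W) for (c_ in 1:C) {
    expect_equal(v[((h - 1) * W + (w - 1)) * C + c_], m[h, w, c_])
  }
  # degenerate spatial dims: flatten equals the channel vector
  m1 <- array(rnorm(5), c(1, 1, 5))
  expect_equal(flatten(m1), as.vector(m1))
  expect_error(flatten(matrix(1, 2, 2)), "3-D")
})

test_that("softmax cross-entropy gradients and probabilities are consistent", {
  withr::with_seed(2, {
    z <- matrix(rnorm(8), 4, 2)
    y <- c(1L, 2L, 1L, 2L)
    r <- ns$softmax_xent(z, y)
    expect_equal(rowSums(r$probs), rep(1, 4))
    expect_equal(sum(r$dlogits), 0, tolerance = 1e-12)
  })
})
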