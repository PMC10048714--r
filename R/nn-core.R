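# Minimal reverse-mode network engine used by the convolutional backbones.
#
# Tensors are numeric arrays with dim (H, W, N, C) — column-major, so height
# varies fastest. A network is a tree of "nodes"; each node type implements a
# forward pass (returning output + cache) and a backward pass (returning the
# input gradient and parameter gradients, flattened in the same deterministic
# traversal order as nn_params()). Initialisation is He/Glorot-uniform and
# fully seeded by the caller.

he_uniform <- function(n, fan_in) {
  lim <- sqrt(6 / fan_in)
  runif(n, -lim, lim)
}

glorot_uniform <- function(n, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

nn_conv <- function(in_ch, out_ch, k, stride = 1L, pad = as.integer(k %/% 2)) {
  fan_in <- k * k * in_ch
  list(type = "conv",
       W = matrix(he_uniform(fan_in * out_ch, fan_in), fan_in, out_ch),
       b = numeric(out_ch),
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad),
       in_ch = as.integer(in_ch), out_ch = as.integer(out_ch))
}

nn_dwconv <- function(ch, k = 3L, pad = 1L) {
  list(type = "dwconv",
       W = array(he_uniform(k * k * ch, k * k), c(k, k, ch)),
       b = numeric(ch),
       k = as.integer(k), stride = 1L, pad = as.integer(pad),
       ch = as.integer(ch))
}

nn_dense <- function(p, q) {
  list(type = "dense",
       W = matrix(glorot_uniform(p * q, p, q), p, q),
       b = numeric(q), p = as.integer(p), q = as.integer(q))
}

nn_relu <- function() list(type = "relu")
nn_maxpool <- function(k, stride, pad = 0L) {
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad))
}
nn_avgpool2 <- function() list(type = "avgpool2")
nn_gap <- function() list(type = "gap")
nn_gapmap <- function() list(type = "gapmap")
nn_seq <- function(...) {
  nodes <- list(...)
  if (length(nodes) == 1L && is.list(nodes[[1]]) && is.null(nodes[[1]]$type)) {
    nodes <- nodes[[1]]
  }
  list(type = "seq", nodes = nodes)
}
nn_res <- function(main, shortcut = NULL, post_relu = TRUE) {
  list(type = "res", main = main, shortcut = shortcut, post_relu = post_relu)
}
nn_dense_block <- function(layers) list(type = "dense_block", layers = layers)

out_hw <- function(H, k, stride, pad) (H + 2L * pad - k) %/% stride + 1L

# ---- forward ---------------------------------------------------------------

nn_forward <- function(node, x, keep = FALSE) {
  switch(node$type,
    conv = {
      d <- dim(x)
      cols <- im2col_cpp(as.vector(x), d[1], d[2], d[3], d[4],
                         node$k, node$stride, node$pad)
      y <- cols %*% node$W
      y <- y + rep(node$b, each = nrow(y))
      oH <- out_hw(d[1], node$k, node$stride, node$pad)
      oW <- out_hw(d[2], node$k, node$stride, node$pad)
      dim(y) <- c(oH, oW, d[3], node$out_ch)
      list(y = y, cache = if (keep) list(xdim = d, cols = cols))
    },
    dwconv = {
      d <- dim(x)
      y <- dwconv_fwd_cpp(as.vector(x), d[1], d[2], d[3], d[4],
                          as.vector(node$W), node$b,
                          node$k, node$stride, node$pad)
      oH <- out_hw(d[1], node$k, node$stride, node$pad)
      oW <- out_hw(d[2], node$k, node$stride, node$pad)
      dim(y) <- c(oH, oW, d[3], d[4])
      list(y = y, cache = if (keep) list(xdim = d, x = x))
    },
    dense = {
      y <- x %*% node$W
      y <- y + rep(node$b, each = nrow(y))
      list(y = y, cache = if (keep) list(x = x))
    },
    relu = {
      y <- pmax(x, 0)
      list(y = y, cache = if (keep) list(mask = x > 0))
    },
    maxpool = {
      d <- dim(x)
      r <- maxpool_fwd_cpp(as.vector(x), d[1], d[2], d[3], d[4],
                           node$k, node$stride, node$pad)
      y <- r$out
      dim(y) <- c(r$oH, r$oW, d[3], d[4])
      list(y = y, cache = if (keep) list(argmax = r$argmax,
                                         in_len = length(x), xdim = d))
    },
    avgpool2 = {
      d <- dim(x)
      i1 <- seq(1L, 2L * (d[1] %/% 2L), by = 2L)
      j1 <- seq(1L, 2L * (d[2] %/% 2L), by = 2L)
      y <- (x[i1, j1, , , drop = FALSE] + x[i1 + 1L, j1, , , drop = FALSE] +
            x[i1, j1 + 1L, , , drop = FALSE] +
            x[i1 + 1L, j1 + 1L, , , drop = FALSE]) / 4
      list(y = y, cache = if (keep) list(xdim = d))
    },
    gap = {
      d <- dim(x)
      xm <- x
      dim(xm) <- c(d[1] * d[2], d[3] * d[4])
      y <- matrix(colMeans(xm), d[3], d[4])
      list(y = y, cache = if (keep) list(xdim = d))
    },
    gapmap = {
      d <- dim(x)
      xm <- x
      dim(xm) <- c(d[1] * d[2], d[3] * d[4])
      y <- colMeans(xm)
      dim(y) <- c(1L, 1L, d[3], d[4])
      list(y = y, cache = if (keep) list(xdim = d))
    },
    seq = {
      caches <- vector("list", length(node$nodes))
      for (i in seq_along(node$nodes)) {
        r <- nn_forward(node$nodes[[i]], x, keep)
        x <- r$y
        if (keep) caches[[i]] <- r$cache
      }
      list(y = x, cache = if (keep) caches)
    },
    res = {
      rm_ <- nn_forward(node$main, x, keep)
      if (is.null(node$shortcut)) {
        ys <- x
        cs <- NULL
      } else {
        rs <- nn_forward(node$shortcut, x, keep)
        ys <- rs$y
        cs <- rs$cache
      }
      s <- rm_$y + ys
      if (node$post_relu) {
        y <- pmax(s, 0)
        mask <- if (keep) s > 0
      } else {
        y <- s
        mask <- NULL
      }
      list(y = y, cache = if (keep) list(main = rm_$cache, shortcut = cs,
                                         mask = mask))
    },
    dense_block = {
      d <- dim(x)
      feats <- x
      caches <- vector("list", length(node$layers))
      widths <- integer(length(node$layers))
      for (i in seq_along(node$layers)) {
        r <- nn_forward(node$layers[[i]], feats, keep)
        widths[i] <- dim(r$y)[4]
        dn <- dim(feats)
        merged <- array(0, c(dn[1], dn[2], dn[3], dn[4] + widths[i]))
        merged[, , , seq_len(dn[4])] <- feats
        merged[, , , dn[4] + seq_len(widths[i])] <- r$y
        feats <- merged
        if (keep) caches[[i]] <- r$cache
      }
      list(y = feats, cache = if (keep) list(caches = caches, c0 = d[4],
                                             widths = widths))
    },
    abort(sprintf("Unknown node type '%s'.", node$type))
  )
}

# ---- backward --------------------------------------------------------------
# Returns list(dx = ..., grads = flat list of parameter gradients in the same
# order as nn_params(node)).

nn_backward <- function(node, cache, dy) {
  switch(node$type,
    conv = {
      od <- dim(dy)
      dym <- dy
      dim(dym) <- c(od[1] * od[2] * od[3], od[4])
      dW <- crossprod(cache$cols, dym)
      db <- colSums(dym)
      dcols <- dym %*% t(node$W)
      d <- cache$xdim
      dx <- col2im_cpp(dcols, d[1], d[2], d[3], d[4],
                       node$k, node$stride, node$pad)
      dim(dx) <- d
      list(dx = dx, grads = list(dW, db))
    },
    dwconv = {
      d <- cache$xdim
      r <- dwconv_bwd_cpp(as.vector(dy), as.vector(cache$x),
                          d[1], d[2], d[3], d[4], as.vector(node$W),
                          node$k, node$stride, node$pad)
      dx <- r$dx
      dim(dx) <- d
      dw <- r$dw
      dim(dw) <- dim(node$W)
      list(dx = dx, grads = list(dw, r$db))
    },
    dense = {
      dW <- crossprod(cache$x, dy)
      db <- colSums(dy)
      dx <- dy %*% t(node$W)
      list(dx = dx, grads = list(dW, db))
    },
    relu = {
      list(dx = dy * cache$mask, grads = list())
    },
    maxpool = {
      dx <- maxpool_bwd_cpp(as.vector(dy), cache$argmax, cache$in_len)
      dim(dx) <- cache$xdim
      list(dx = dx, grads = list())
    },
    avgpool2 = {
      d <- cache$xdim
      i1 <- seq(1L, 2L * (d[1] %/% 2L), by = 2L)
      j1 <- seq(1L, 2L * (d[2] %/% 2L), by = 2L)
      dx <- array(0, d)
      q <- dy / 4
      dx[i1, j1, , ] <- q
      dx[i1 + 1L, j1, , ] <- q
      dx[i1, j1 + 1L, , ] <- q
      dx[i1 + 1L, j1 + 1L, , ] <- q
      list(dx = dx, grads = list())
    },
    gap = {
      d <- cache$xdim
      dx <- array(rep(as.vector(dy) / (d[1] * d[2]), each = d[1] * d[2]), d)
      list(dx = dx, grads = list())
    },
    gapmap = {
      d <- cache$xdim
      dx <- array(rep(as.vector(dy) / (d[1] * d[2]), each = d[1] * d[2]), d)
      list(dx = dx, grads = list())
    },
    seq = {
      grads <- vector("list", length(node$nodes))
      for (i in rev(seq_along(node$nodes))) {
        r <- nn_backward(node$nodes[[i]], cache[[i]], dy)
        dy <- r$dx
        grads[[i]] <- r$grads
      }
      list(dx = dy, grads = do.call(c, grads))
    },
    res = {
      ds <- if (node$post_relu) dy * cache$mask else dy
      rm_ <- nn_backward(node$main, cache$main, ds)
      if (is.null(node$shortcut)) {
        dx <- rm_$dx + ds
        gs <- list()
      } else {
        rs <- nn_backward(node$shortcut, cache$shortcut, ds)
        dx <- rm_$dx + rs$dx
        gs <- rs$grads
      }
      list(dx = dx, grads = c(rm_$grads, gs))
    },
    dense_block = {
      dfeats <- dy
      grads <- vector("list", length(node$layers))
      c0 <- cache$c0
      widths <- cache$widths
      for (i in rev(seq_along(node$layers))) {
        cin <- c0 + sum(widths[seq_len(i - 1L)])
        dchild <- dfeats[, , , cin + seq_len(widths[i]), drop = FALSE]
        dfeats <- dfeats[, , , seq_len(cin), drop = FALSE]
        r <- nn_backward(node$layers[[i]], cache$caches[[i]], dchild)
        dfeats <- dfeats + r$dx
        grads[[i]] <- r$grads
      }
      list(dx = dfeats, grads = do.call(c, grads))
    },
    abort(sprintf("Unknown node type '%s'.", node$type))
  )
}

# ---- parameter flattening --------------------------------------------------

nn_params <- function(node) {
  switch(node$type,
    conv = ,
    dwconv = ,
    dense = list(node$W, node$b),
    seq = do.call(c, c(lapply(node$nodes, nn_params), list(list()))),
    res = c(nn_params(node$main),
            if (!is.null(node$shortcut)) nn_params(node$shortcut) else list()),
    dense_block = do.call(c, c(lapply(node$layers, nn_params), list(list()))),
    list()
  )
}

nn_set_params <- function(node, flat, pos = 1L) {
  res <- switch(node$type,
    conv = ,
    dwconv = ,
    dense = {
      node$W[] <- flat[[pos]]
      node$b[] <- flat[[pos + 1L]]
      list(node = node, pos = pos + 2L)
    },
    seq = {
      for (i in seq_along(node$nodes)) {
        r <- nn_set_params(node$nodes[[i]], flat, pos)
        node$nodes[[i]] <- r$node
        pos <- r$pos
      }
      list(node = node, pos = pos)
    },
    res = {
      r <- nn_set_params(node$main, flat, pos)
      node$main <- r$node
      pos <- r$pos
      if (!is.null(node$shortcut)) {
        r <- nn_set_params(node$shortcut, flat, pos)
        node$shortcut <- r$node
        pos <- r$pos
      }
      list(node = node, pos = pos)
    },
    dense_block = {
      for (i in seq_along(node$layers)) {
        r <- nn_set_params(node$layers[[i]], flat, pos)
        node$layers[[i]] <- r$node
        pos <- r$pos
      }
      list(node = node, pos = pos)
    },
    list(node = node, pos = pos)
  )
  res
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    params[[i]] <- params[[i]] -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Softmax cross-entropy over K classes. y is an integer vector in 1..K.
softmax_xent <- function(logits, y) {
  m <- apply(logits, 1, max)
  z <- exp(logits - m)
  p <- z / rowSums(z)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = p)
}
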