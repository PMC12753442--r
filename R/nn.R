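# Minimal reverse-mode neural-network engine.
#
# Layers are plain lists: list(kind, p = <named list of parameter arrays>,
# cfg = <constants>, state = <non-optimized buffers>, sub = <named list of
# layer sequences, for composite blocks>). Forward passes return the output,
# a cache for the backward pass, and the (possibly state-updated) layer.
# Image batches are arrays dim (H, W, C, N); dense activations are N x F
# matrices. Convolution and max-pooling run in compiled code (src/).

nn_dense <- function(n_in, n_out) {
  list(kind = "dense",
       p = list(W = matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)),
                           n_in, n_out),
                b = numeric(n_out)),
       cfg = list(), state = list(), sub = NULL)
}

nn_relu <- function() {
  list(kind = "relu", p = list(), cfg = list(), state = list(), sub = NULL)
}

nn_conv <- function(kh, kw, ci, co, stride = 1L, pad = 0L) {
  fan_in <- kh * kw * ci
  list(kind = "conv",
       p = list(W = array(rnorm(kh * kw * ci * co, sd = sqrt(2 / fan_in)),
                          dim = c(kh, kw, ci, co)),
                b = numeric(co)),
       cfg = list(stride = as.integer(stride), pad = as.integer(pad)),
       state = list(), sub = NULL)
}

nn_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  list(kind = "bn",
       p = list(gamma = rep(1, c), beta = numeric(c)),
       cfg = list(momentum = momentum, eps = eps),
       state = list(rm = numeric(c), rv = rep(1, c)), sub = NULL)
}

nn_maxpool <- function(k, stride = k) {
  list(kind = "maxpool", p = list(),
       cfg = list(k = as.integer(k), stride = as.integer(stride)),
       state = list(), sub = NULL)
}

nn_gap <- function() {
  list(kind = "gap", p = list(), cfg = list(), state = list(), sub = NULL)
}

# Basic residual block: two 3x3 convs with batch norm; 1x1 projection on the
# shortcut when the shape changes.
nn_resblock <- function(ci, co, stride = 1L) {
  main <- list(nn_conv(3, 3, ci, co, stride = stride, pad = 1L),
               nn_bn(co), nn_relu(),
               nn_conv(3, 3, co, co, stride = 1L, pad = 1L), nn_bn(co))
  proj <- if (stride != 1L || ci != co) {
    list(nn_conv(1, 1, ci, co, stride = stride, pad = 0L), nn_bn(co))
  }
  list(kind = "resblock", p = list(), cfg = list(), state = list(),
       sub = list(main = main, proj = proj))
}

bn_fwd <- function(layer, x, training) {
  d <- dim(x); C <- d[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    v <- colMeans(xc * xc)
    mom <- layer$cfg$momentum
    layer$state$rm <- (1 - mom) * layer$state$rm + mom * mu
    layer$state$rv <- (1 - mom) * layer$state$rv + mom * v
  } else {
    mu <- layer$state$rm
    v <- layer$state$rv
    xc <- sweep(xm, 2, mu)
  }
  inv <- 1 / sqrt(v + layer$cfg$eps)
  xhat <- sweep(xc, 2, inv, `*`)
  ym <- sweep(sweep(xhat, 2, layer$p$gamma, `*`), 2, layer$p$beta, `+`)
  y <- aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(out = y, cache = list(xhat = xhat, inv = inv, d = d,
                             training = training),
       layer = layer)
}

bn_bwd <- function(layer, cache, dy) {
  d <- cache$d; C <- d[3]
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = C)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, layer$p$gamma, `*`)
  if (cache$training) {
    m <- nrow(dym)
    t1 <- sweep(dxhat, 2, colSums(dxhat) / m)
    t2 <- sweep(xhat, 2, colSums(dxhat * xhat) / m, `*`)
    dxm <- sweep(t1 - t2, 2, cache$inv, `*`)
  } else {
    dxm <- sweep(dxhat, 2, cache$inv, `*`)
  }
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

layer_forward <- function(layer, x, training) {
  switch(layer$kind,
    dense = {
      y <- x %*% layer$p$W
      y <- sweep(y, 2, layer$p$b, `+`)
      list(out = y, cache = list(x = x), layer = layer)
    },
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = list(mask = mask), layer = layer)
    },
    conv = {
      y <- conv2d_fwd(x, layer$p$W, layer$p$b,
                      layer$cfg$stride, layer$cfg$pad)
      list(out = y, cache = list(x = x), layer = layer)
    },
    bn = bn_fwd(layer, x, training),
    maxpool = {
      r <- maxpool_fwd(x, layer$cfg$k, layer$cfg$stride)
      list(out = r$y, cache = list(idx = r$idx, xdim = dim(x)),
           layer = layer)
    },
    gap = {
      d <- dim(x)
      y <- t(matrix(colMeans(matrix(x, nrow = d[1] * d[2])), d[3], d[4]))
      list(out = y, cache = list(d = d), layer = layer)
    },
    resblock = {
      fm <- nn_seq_forward(layer$sub$main, x, training)
      if (is.null(layer$sub$proj)) {
        sc <- x; pc <- NULL
      } else {
        fp <- nn_seq_forward(layer$sub$proj, x, training)
        sc <- fp$out; pc <- fp$caches
        layer$sub$proj <- fp$layers
      }
      layer$sub$main <- fm$layers
      s <- fm$out + sc
      mask <- s > 0
      list(out = s * mask,
           cache = list(main = fm$caches, proj = pc, mask = mask),
           layer = layer)
    },
    stop("unknown layer kind: ", layer$kind)
  )
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$kind,
    dense = {
      list(dx = dy %*% t(layer$p$W),
           grads = list(W = crossprod(cache$x, dy), b = colSums(dy)))
    },
    relu = list(dx = dy * cache$mask, grads = list()),
    conv = {
      r <- conv2d_bwd(cache$x, layer$p$W, dy,
                      layer$cfg$stride, layer$cfg$pad)
      list(dx = r$dx, grads = list(W = r$dw, b = r$db))
    },
    bn = bn_bwd(layer, cache, dy),
    maxpool = {
      list(dx = maxpool_bwd(cache$xdim, cache$idx, dy), grads = list())
    },
    gap = {
      d <- cache$d
      dx <- array(rep(as.vector(t(dy)) / (d[1] * d[2]), each = d[1] * d[2]),
                  dim = d)
      list(dx = dx, grads = list())
    },
    resblock = {
      ds <- dy * cache$mask
      bm <- nn_seq_backward(layer$sub$main, cache$main, ds)
      if (is.null(layer$sub$proj)) {
        dx <- bm$dx + ds
        gproj <- NULL
      } else {
        bp <- nn_seq_backward(layer$sub$proj, cache$proj, ds)
        dx <- bm$dx + bp$dx
        gproj <- bp$grads
      }
      list(dx = dx, grads = list(main = bm$grads, proj = gproj))
    },
    stop("unknown layer kind: ", layer$kind)
  )
}

nn_seq_forward <- function(layers, x, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, training)
    x <- r$out
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(out = x, caches = caches, layers = layers)
}

nn_seq_backward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = dy, grads = grads)
}

# --- Adam ------------------------------------------------------------------

adam_init_layers <- function(layers) {
  lapply(layers, function(ly) {
    st <- list(p = lapply(ly$p, function(w) list(m = w * 0, v = w * 0)))
    if (!is.null(ly$sub)) {
      st$sub <- lapply(ly$sub, function(s) if (!is.null(s)) adam_init_layers(s))
    }
    st
  })
}

adam_step_layers <- function(layers, grads, state, lr, t,
                             beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    for (nm in names(layers[[i]]$p)) {
      gw <- if (is.list(g) && !is.null(g[[nm]])) g[[nm]] else next
      s <- state[[i]]$p[[nm]]
      s$m <- beta1 * s$m + (1 - beta1) * gw
      s$v <- beta2 * s$v + (1 - beta2) * gw * gw
      mh <- s$m / (1 - beta1^t)
      vh <- s$v / (1 - beta2^t)
      layers[[i]]$p[[nm]] <- layers[[i]]$p[[nm]] - lr * mh / (sqrt(vh) + eps)
      state[[i]]$p[[nm]] <- s
    }
    if (!is.null(layers[[i]]$sub)) {
      for (sn in names(layers[[i]]$sub)) {
        if (is.null(layers[[i]]$sub[[sn]])) next
        r <- adam_step_layers(layers[[i]]$sub[[sn]], g[[sn]],
                              state[[i]]$sub[[sn]], lr, t, beta1, beta2, eps)
        layers[[i]]$sub[[sn]] <- r$layers
        state[[i]]$sub[[sn]] <- r$state
      }
    }
  }
  list(layers = layers, state = state)
}

# --- Cross-entropy ---------------------------------------------------------

# logits: n x 2, labels in {0,1}. Returns mean loss and d(loss)/d(logits).
ce_loss <- function(logits, labels) {
  if (!all(labels %in% c(0, 1))) {
    stop_lnm("labels must be 0 or 1", "lnm_label_error")
  }
  n <- nrow(logits)
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  ix <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(p[ix], 1e-300)))
  dl <- p
  dl[ix] <- dl[ix] - 1
  list(loss = loss, dlogits = dl / n, prob = p)
}
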