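# The training loop relies on hand-derived backward passes; every layer kind
# is checked here against central-difference numerical gradients.

nn_fwd <- lnmfusion:::nn_seq_forward
nn_bwd <- lnmfusion:::nn_seq_backward

test_that("layer backward passes match numerical gradients", {
  layers <- withr::with_seed(1, list(
    lnmfusion:::nn_conv(3, 3, 2, 3, stride = 2L, pad = 1L),
    lnmfusion:::nn_bn(3), lnmfusion:::nn_relu(),
    lnmfusion:::nn_resblock(3, 4, stride = 2L),
    lnmfusion:::nn_maxpool(2L, 2L),
    lnmfusion:::nn_gap(), lnmfusion:::nn_dense(4, 5)))
  x <- withr::with_seed(2, array(rnorm(16 * 16 * 2 * 3), c(16, 16, 2, 3)))
  R <- withr::with_seed(3, matrix(rnorm(3 * 5), 3, 5))
  loss <- function(ls, xx = x) sum(nn_fwd(ls, xx, TRUE)$out * R)
  fw <- nn_fwd(layers, x, TRUE)
  bw <- nn_bwd(layers, fw$caches, R)
  num_vs_analytic <- function(get, set, analytic, label, k = 6, eps = 1e-5) {
    v <- get()
    k <- min(k, length(v))
    for (i in seq_len(k)) {
      vp <- v; vp[i] <- v[i] + eps
      vm <- v; vm[i] <- v[i] - eps
      ng <- (loss(set(vp)) - loss(set(vm))) / (2 * eps)
      expect_equal(analytic[i], ng, tolerance = 1e-5,
                   info = paste(label, i))
    }
  }
  L <- layers
  num_vs_analytic(function() L[[1]]$p$W,
                  function(v) { ls <- L; ls[[1]]$p$W[] <- v; ls },
                  bw$grads[[1]]$W, "conv W")
  num_vs_analytic(function() L[[1]]$p$b,
                  function(v) { ls <- L; ls[[1]]$p$b <- v; ls },
                  bw$grads[[1]]$b, "conv b", k = 3)
  num_vs_analytic(function() L[[2]]$p$gamma,
                  function(v) { ls <- L; ls[[2]]$p$gamma <- v; ls },
                  bw$grads[[2]]$gamma, "bn gamma", k = 3)
  num_vs_analytic(function() L[[2]]$p$beta,
                  function(v) { ls <- L; ls[[2]]$p$beta <- v; ls },
                  bw$grads[[2]]$beta, "bn beta", k = 3)
  num_vs_analytic(function() L[[4]]$sub$main[[1]]$p$W,
                  function(v) { ls <- L; ls[[4]]$sub$main[[1]]$p$W[] <- v; ls },
                  bw$grads[[4]]$main[[1]]$W, "resblock conv1 W")
  num_vs_analytic(function() L[[4]]$sub$proj[[1]]$p$W,
                  function(v) { ls <- L; ls[[4]]$sub$proj[[1]]$p$W[] <- v; ls },
                  bw$grads[[4]]$proj[[1]]$W, "resblock proj W")
  num_vs_analytic(function() L[[7]]$p$W,
                  function(v) { ls <- L; ls[[7]]$p$W[] <- v; ls },
                  bw$grads[[7]]$W, "dense W")
  # gradient w.r.t. the input (covers maxpool and the residual shortcut)
  for (i in 1:6) {
    eps <- 1e-5
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    ng <- (loss(L, xp) - loss(L, xm)) / (2 * eps)
    expect_equal(bw$dx[i], ng, tolerance = 1e-4, info = paste("dx", i))
  }
})

test_that("cross-entropy loss and gradient match numerical differentiation", {
  lg <- withr::with_seed(4, matrix(rnorm(8), 4, 2))
  lb <- c(0, 1, 1, 0)
  ce <- lnmfusion:::ce_loss(lg, lb)
  for (i in seq_along(lg)) {
    eps <- 1e-6
    lp <- lg; lp[i] <- lg[i] + eps
    lm <- lg; lm[i] <- lg[i] - eps
    ng <- (lnmfusion:::ce_loss(lp, lb)$loss -
             lnmfusion:::ce_loss(lm, lb)$loss) / (2 * eps)
    expect_equal(ce$dlogits[i], ng, tolerance = 1e-6)
  }
  expect_error(lnmfusion:::ce_loss(lg, c(0, 1, 2, 0)),
               class = "lnm_label_error")
})

test_that("InfoNCE gradients match numerical differentiation in all modes", {
  za <- withr::with_seed(5, matrix(rnorm(5 * 7), 5))
  zb <- withr::with_seed(6, matrix(rnorm(5 * 7), 5))
  for (inc in c(FALSE, TRUE)) {
    for (sym in c(FALSE, TRUE)) {
      cfg <- contrastive_config(temperature = 0.7,
                                include_positive_in_denominator = inc,
                                symmetrize = sym)
      r <- info_nce(za, zb, cfg, grad = TRUE)
      for (i in 1:8) {
        eps <- 1e-6
        zp <- za; zp[i] <- za[i] + eps
        zm <- za; zm[i] <- za[i] - eps
        ng <- (info_nce(zp, zb, cfg)$mean - info_nce(zm, zb, cfg)$mean) /
          (2 * eps)
        expect_equal(r$dza[i], ng, tolerance = 1e-5)
        zp <- zb; zp[i] <- zb[i] + eps
        zm <- zb; zm[i] <- zb[i] - eps
        ng <- (info_nce(za, zp, cfg)$mean - info_nce(za, zm, cfg)$mean) /
          (2 * eps)
        expect_equal(r$dzb[i], ng, tolerance = 1e-5)
      }
    }
  }
})

test_that("batch-norm evaluation mode uses running statistics", {
  ly <- lnmfusion:::nn_bn(2)
  x <- withr::with_seed(7, array(rnorm(4 * 4 * 2 * 6, mean = 3, sd = 2),
                                 c(4, 4, 2, 6)))
  # a few training passes accumulate running statistics
  for (k in 1:50) ly <- lnmfusion:::layer_forward(ly, x, TRUE)$layer
  ev <- lnmfusion:::layer_forward(ly, x, FALSE)
  # eval output is deterministic and roughly standardized
  ev2 <- lnmfusion:::layer_forward(ly, x, FALSE)
  expect_identical(ev$out, ev2$out)
  expect_lt(abs(mean(ev$out)), 0.3)
})

test_that("a single small optimization step decreases the objective", {
  withr::with_seed(8, {
    layers <- list(lnmfusion:::nn_dense(6, 4), lnmfusion:::nn_relu(),
                   lnmfusion:::nn_dense(4, 2))
    x <- matrix(rnorm(2 * 6), 2, 6)
    y <- c(0, 1)
    fw <- nn_fwd(layers, x, TRUE)
    l0 <- lnmfusion:::ce_loss(fw$out, y)
    bw <- nn_bwd(layers, fw$caches, l0$dlogits)
    st <- lnmfusion:::adam_init_layers(layers)
    r <- lnmfusion:::adam_step_layers(layers, bw$grads, st, lr = 1e-3, t = 1)
    l1 <- lnmfusion:::ce_loss(nn_fwd(r$layers, x, TRUE)$out, y)
    expect_lt(l1$loss, l0$loss)
  })
})
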