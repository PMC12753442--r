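test_that("fusion concatenates in CT || US || clinical order", {
  withr::with_seed(1, {
    h <- list(h_ct = matrix(rnorm(4 * 512), 4),
              h_us = matrix(rnorm(4 * 512), 4),
              h_clin = matrix(rnorm(4 * 512), 4))
    f <- fuse(h)
    expect_equal(dim(f), c(4, 1536))
    expect_equal(f[, 1:512], h$h_ct)
    expect_equal(f[, 513:1024], h$h_us)
    expect_equal(f[, 1025:1536], h$h_clin)
    h0 <- h; h0$h_us[] <- 0
    expect_true(all(fuse(h0)[, 513:1024] == 0))
    bad <- h; bad$h_us <- bad$h_us[1:2, ]
    expect_error(fuse(bad), class = "lnm_shape_error")
  })
})

test_that("classifier scores equal the affine oracle", {
  cl <- build_classifier(6, seed = 1)
  W <- matrix(seq(-0.5, 0.6, length.out = 12), 6, 2)
  b <- c(0.1, -0.2)
  cl$layers[[1]]$p$W <- W
  cl$layers[[1]]$p$b <- b
  x <- withr::with_seed(2, matrix(rnorm(12), 2, 6))
  sc <- classify(x, cl)
  expect_equal(dim(sc), c(2, 2))
  expect_equal(sc, sweep(x %*% W, 2, b, `+`), tolerance = 1e-12)
  expect_equal(classify(x[c(1, 1), ], cl)[1, ],
               classify(x[c(1, 1), ], cl)[2, ])
  expect_error(classify(x[, 1:3], cl), class = "lnm_shape_error")
  # tie broken toward the negative class
  expect_equal(lnmfusion:::hard_predictions(matrix(c(1, 1), 1)), 0L)
})

test_that("total loss decomposes exactly into CE plus contrastive", {
  withr::with_seed(3, {
    n <- 6
    scores <- matrix(rnorm(n * 2), n)
    labels <- rep(c(0, 1), 3)
    proj <- list(z_ct = matrix(rnorm(n * 8), n),
                 z_us = matrix(rnorm(n * 8), n),
                 z_clin = matrix(rnorm(n * 8), n))
    frag <- combined_contrastive(proj)
    lb <- total_loss(scores, labels, frag)
    expect_equal(lb$total, lb$ce + lb$contrastive, tolerance = 1e-12)
    expect_equal(lb$contrastive, mean(lb$pair_losses), tolerance = 1e-12)
    expect_equal(lb$total,
                 lnmfusion:::ce_loss(scores, labels)$loss +
                   mean(vapply(list(c("z_ct", "z_clin"), c("z_us", "z_clin"),
                                    c("z_ct", "z_us")),
                               function(p) info_nce(proj[[p[1]]],
                                                    proj[[p[2]]])$mean,
                               numeric(1))),
                 tolerance = 1e-7)
    # uniform scores -> CE = log 2; confident correct scores -> CE ~ 0
    lb2 <- total_loss(matrix(0, 4, 2), c(0, 1, 0, 1))
    expect_equal(lb2$ce, log(2), tolerance = 1e-12)
    conf <- 60 * cbind(1 - c(0, 1, 0, 1), c(0, 1, 0, 1))
    lb3 <- total_loss(conf, c(0, 1, 0, 1), frag)
    expect_lt(lb3$ce, 1e-12)
    expect_equal(lb3$total, lb3$contrastive, tolerance = 1e-10)
    expect_error(total_loss(scores, c(0, 1, 2, 0, 1, 0)),
                 class = "lnm_label_error")
  })
})

test_that("the 127-patient split follows the documented rounding rule", {
  co <- tiny_cohort()
  big <- generate_cohort(synthetic_params(seed = 1, image_size = 8))
  sp <- split_cohort(big, seed = 5)
  expect_equal(length(sp$train_ids), 102)
  expect_equal(length(sp$val_ids), 12)
  expect_equal(length(sp$test_ids), 13)
  # same seed -> identical assignment
  sp2 <- split_cohort(big, seed = 5)
  expect_identical(sp[1:3], sp2[1:3])
  # stratification puts at least one positive in every split
  lab <- function(ids) big$label[match(ids, big$patient_id)]
  expect_gte(sum(lab(sp$val_ids)), 1)
  expect_gte(sum(lab(sp$test_ids)), 1)
  prev <- mean(big$label)
  expect_lt(abs(mean(lab(sp$train_ids)) - prev), 0.05)
})

test_that("splits partition arbitrary cohorts", {
  withr::with_seed(9, {
    for (k in 1:5) {
      n <- sample(30:200, 1)
      np <- max(4, round(n * runif(1, 0.1, 0.4)))
      co <- generate_cohort(synthetic_params(seed = k, n_patients = n,
                                             n_positive = np,
                                             image_size = 8))
      sp <- split_cohort(co, seed = k, stratified = sample(c(TRUE, FALSE), 1))
      all_ids <- c(sp$train_ids, sp$val_ids, sp$test_ids)
      expect_equal(sort(all_ids), sort(co$patient_id))
      expect_equal(anyDuplicated(all_ids), 0)
    }
  })
})

test_that("inverse-frequency weights balance classes in expectation", {
  labels <- rep(c(1, 0), c(16, 86))
  w <- sampler_weights(labels)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w[labels == 1], rep((1 / 16) / 2, 16), tolerance = 1e-12)
  expect_equal(w[labels == 0], rep((1 / 86) / 2, 86), tolerance = 1e-12)
  expect_equal(sampler_weights(rep(c(0, 1), 10)), rep(0.05, 20),
               tolerance = 1e-12)
  expect_error(sampler_weights(rep(1, 5)), class = "lnm_domain_error")
  # Monte-Carlo of the weighted sampler
  withr::with_seed(4, {
    fr <- mean(replicate(2000, {
      mean(labels[sample.int(102, 8, replace = TRUE, prob = w)])
    }))
    expect_equal(fr, 0.5, tolerance = 0.03)
  })
})

test_that("checkpoint selection takes the earliest best-validation epoch", {
  expect_equal(lnmfusion:::select_best_epoch(c(0.5, 0.9, 0.9, 0.7)), 2L)
  expect_equal(lnmfusion:::select_best_epoch(c(0.9, 0.1)), 1L)
  expect_equal(lnmfusion:::select_best_epoch(c(0.1, 0.2, 0.8)), 3L)
})

test_that("cosine annealing decays the learning rate to zero", {
  lrs <- cosine_lr(1e-3, 1:30, 30)
  expect_equal(lrs[1], 1e-3)
  expect_lt(lrs[30], 1e-6)
  expect_true(all(diff(lrs) < 0))
  expect_equal(cosine_lr(1e-3, 1, 1), 1e-3)
})

test_that("a one-epoch smoke run returns a self-contained checkpoint", {
  co <- tiny_cohort()
  sp <- split_cohort(co, seed = 1)
  fit <- train_lnm(co, sp, train_config(epochs = 1, seed = 1),
                   tiny_enc_cfg(), contrastive_config())
  expect_s3_class(fit, "lnm_fit")
  expect_equal(nrow(fit$history), 1)
  expect_equal(fit$best_epoch, 1L)
  expect_true(all(c("ce", "contrastive", "total", "val_acc") %in%
                    names(fit$history)))
  expect_true(is.finite(fit$history$total))
  # exact decomposition also holds in the logged history
  expect_equal(fit$history$total, fit$history$ce + fit$history$contrastive,
               tolerance = 1e-9)
  expect_equal(fit$history$contrastive,
               rowMeans(fit$history[, c("loss_ct_clin", "loss_us_clin",
                                        "loss_ct_us")]),
               tolerance = 1e-9)
  # the checkpoint carries everything prediction needs
  pr <- predict(fit, co)
  expect_equal(nrow(pr), length(sp$test_ids))
  expect_true(all(pr$score >= 0 & pr$score <= 1))
  expect_true(all(pr$pred %in% c(0, 1)))
  # normalization bounds were fitted on the training split only
  tr_rows <- co[match(sp$train_ids, co$patient_id), ]
  nm <- fit_normalizer(tr_rows, fit$features)
  expect_equal(fit$normalizer$lo, nm$lo)
  expect_equal(fit$normalizer$hi, nm$hi)
  # tidiers
  expect_equal(nrow(tidy(fit)), 1)
  g <- glance(fit)
  expect_equal(g$modalities, "ct+us+clinical")
  expect_output(print(fit), "lnm_fit")
})

test_that("training is reproducible under a fixed seed", {
  co <- tiny_cohort()
  sp <- split_cohort(co, seed = 2)
  f1 <- train_lnm(co, sp, train_config(epochs = 2, seed = 7), tiny_enc_cfg())
  f2 <- train_lnm(co, sp, train_config(epochs = 2, seed = 7), tiny_enc_cfg())
  expect_equal(f1$history, f2$history, tolerance = 1e-12)
  expect_identical(predict(f1, co)$score, predict(f2, co)$score)
})

test_that("single-modality and no-contrastive ablation modes train", {
  co <- tiny_cohort()
  sp <- split_cohort(co, seed = 3)
  f_clin <- train_lnm(co, sp, train_config(epochs = 1, seed = 1),
                      tiny_enc_cfg(), modalities = "clinical",
                      use_contrastive = FALSE)
  expect_equal(f_clin$history$contrastive, 0)
  expect_equal(ncol(f_clin$nets$classifier$layers[[1]]$p$W), 2)
  expect_equal(nrow(f_clin$nets$classifier$layers[[1]]$p$W), 512)
  f_nc <- train_lnm(co, sp, train_config(epochs = 1, seed = 1),
                    tiny_enc_cfg(), use_contrastive = FALSE)
  expect_equal(f_nc$history$contrastive, 0)
  expect_equal(nrow(f_nc$nets$classifier$layers[[1]]$p$W), 1536)
  # training split must contain both classes
  bad_split <- sp
  keep <- co$patient_id[co$label == 0]
  bad_split$train_ids <- intersect(sp$train_ids, keep)
  expect_error(train_lnm(co, bad_split, train_config(epochs = 1, seed = 1),
                         tiny_enc_cfg()),
               class = "lnm_domain_error")
})
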