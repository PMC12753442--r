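# Late fusion, joint objective and the training loop: concatenation of the
# three 512-d representations, a linear binary classifier, total loss =
# cross-entropy + combined contrastive, inverse-frequency weighted
# mini-batch sampling, stratified 80/10/10 splitting, Adam with cosine
# annealing, and validation-accuracy checkpoint selection.

MODALITIES <- c("ct", "us", "clinical")

#' Training configuration
#'
#' @param lr initial Adam learning rate (default 1e-3), decayed to zero by a
#'   cosine annealing schedule without restarts.
#' @param epochs training epochs (default 30).
#' @param batch_size mini-batch size (default 8).
#' @param seed training seed (weights, sampling, augmentation).
#' @param class_weighting use inverse-class-frequency sampling so each batch
#'   is class-balanced in expectation (default TRUE).
#' @return An `lnm_train_config` list.
#' @export
train_config <- function(lr = 1e-3, epochs = 30L, batch_size = 8L,
                         seed = 1L, class_weighting = TRUE) {
  if (lr <= 0 || epochs < 1 || batch_size < 2) {
    stop_lnm("lr > 0, epochs >= 1 and batch_size >= 2 required",
             "lnm_param_error")
  }
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 class_weighting = isTRUE(class_weighting)),
            class = "lnm_train_config")
}

#' Concatenation fusion
#'
#' Column-binds the modality representations in the fixed order
#' CT || US || clinical (only the modalities present in `features`).
#'
#' @param features named list with `n x D` matrices among `h_ct`, `h_us`,
#'   `h_clin`.
#' @return An `n x (m*D)` matrix.
#' @export
fuse <- function(features) {
  order_ <- c("h_ct", "h_us", "h_clin")
  use <- order_[order_ %in% names(features)]
  if (length(use) == 0) stop_lnm("no features to fuse", "lnm_shape_error")
  mats <- features[use]
  ns <- vapply(mats, nrow, integer(1))
  if (length(unique(ns)) != 1) {
    stop_lnm("row counts differ across modalities", "lnm_shape_error")
  }
  do.call(cbind, unname(mats))
}

#' Build the linear binary classifier
#'
#' A single affine layer mapping the fused representation to two class
#' scores.
#'
#' @param d_in fused width (3 x 512 = 1536 for the full model).
#' @param seed optional initialization seed.
#' @return An `lnm_classifier`.
#' @export
build_classifier <- function(d_in, seed = NULL) {
  build <- function() list(nn_dense(d_in, 2L))
  layers <- if (is.null(seed)) build() else with_local_seed(seed, build())
  structure(list(layers = layers, d_in = d_in), class = "lnm_classifier")
}

#' Score a batch of fused representations
#'
#' @param fused `n x d_in` matrix.
#' @param classifier an [build_classifier()] object.
#' @return `n x 2` score matrix (column 1 = negative class, column 2 =
#'   positive). Hard predictions take the argmax with ties broken toward
#'   the negative class.
#' @export
classify <- function(fused, classifier) {
  stopifnot(inherits(classifier, "lnm_classifier"))
  fused <- as.matrix(fused)
  if (ncol(fused) != classifier$d_in) {
    stop_lnm(paste0("fused width ", ncol(fused), " != classifier input ",
                    classifier$d_in), "lnm_shape_error")
  }
  nn_seq_forward(classifier$layers, fused, training = FALSE)$out
}

hard_predictions <- function(scores) {
  as.integer(scores[, 2] > scores[, 1])  # tie -> negative class
}

#' Joint loss decomposition
#'
#' `total = ce + contrastive`, exactly; `contrastive` is the mean of the
#' pair losses (0 when no contrastive fragment is supplied).
#'
#' @param scores `n x 2` class scores (logits).
#' @param labels integer labels in \{0, 1\}.
#' @param contrastive a [combined_contrastive()] result (or `NULL`).
#' @return An `lnm_loss_breakdown` list with `ce`, `pair_losses`,
#'   `contrastive` and `total`.
#' @export
total_loss <- function(scores, labels, contrastive = NULL) {
  ce <- ce_loss(as.matrix(scores), labels)$loss
  pl <- if (is.null(contrastive)) c(ct_clin = NA_real_, us_clin = NA_real_,
                                    ct_us = NA_real_) else {
    contrastive$pair_losses
  }
  cl <- if (is.null(contrastive)) 0 else contrastive$contrastive
  structure(list(ce = ce, pair_losses = pl, contrastive = cl,
                 total = ce + cl),
            class = "lnm_loss_breakdown")
}

#' Stratified 80/10/10 cohort split
#'
#' Split sizes follow round-half-up of 0.8n (train) and 0.1n (test), with
#' validation taking the remainder. Stratification allocates each class to
#' the splits by largest-remainder apportionment and, when feasible, moves
#' one training positive into any validation/test split left without one.
#'
#' @param cohort an `lnm_cohort` (needs `patient_id` and `label`).
#' @param seed split seed.
#' @param stratified preserve class prevalence per split (default TRUE).
#' @return An `lnm_split` with `train_ids`, `val_ids`, `test_ids`.
#' @export
split_cohort <- function(cohort, seed = 1L, stratified = TRUE) {
  n <- nrow(cohort)
  if (n < 3) stop_lnm("cohort too small to split", "lnm_domain_error")
  n_train <- round_half_up(0.8 * n)
  n_test <- round_half_up(0.1 * n)
  n_val <- n - n_train - n_test
  if (n_val < 1 || n_test < 1) {
    stop_lnm("cohort too small for an 80/10/10 split", "lnm_domain_error")
  }
  ids <- cohort$patient_id
  labels <- cohort$label
  with_local_seed(derive_seed(seed, "split"), {
    if (!stratified) {
      perm <- sample(ids)
      split <- list(train_ids = perm[seq_len(n_train)],
                    val_ids = perm[n_train + seq_len(n_val)],
                    test_ids = perm[n_train + n_val + seq_len(n_test)])
    } else {
      classes <- sort(unique(labels))
      # largest-remainder apportionment of each split total across classes
      apportion <- function(total, class_n) {
        quota <- class_n * total / sum(class_n)
        base <- floor(quota)
        rem <- total - sum(base)
        if (rem > 0) {
          extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
          base[extra] <- base[extra] + 1
        }
        base
      }
      class_n <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
      val_c <- apportion(n_val, class_n)
      test_c <- apportion(n_test, class_n)
      # feasibility: never assign more than the class holds
      over <- val_c + test_c > class_n
      if (any(over)) {
        stop_lnm("cohort too small to stratify every split", "lnm_domain_error")
      }
      # guarantee at least one positive in val and test when feasible
      pos_i <- which(classes == 1)
      if (length(pos_i) == 1 && class_n[pos_i] >= 3) {
        if (val_c[pos_i] == 0) val_c[pos_i] <- 1
        if (test_c[pos_i] == 0) test_c[pos_i] <- 1
        if (val_c[pos_i] + test_c[pos_i] > class_n[pos_i] - 1) {
          stop_lnm("too few positives to place one in every split",
                   "lnm_domain_error")
        }
      }
      pick <- function(pool, k) if (k > 0) sample(pool, k) else character(0)
      val_ids <- character(0); test_ids <- character(0)
      for (k in seq_along(classes)) {
        pool <- sample(ids[labels == classes[k]])
        val_ids <- c(val_ids, pool[seq_len(val_c[k])])
        test_ids <- c(test_ids, pool[val_c[k] + seq_len(test_c[k])])
      }
      split <- list(train_ids = setdiff(ids, c(val_ids, test_ids)),
                    val_ids = val_ids, test_ids = test_ids)
    }
    structure(c(split, list(seed = as.integer(seed),
                            stratified = isTRUE(stratified))),
              class = "lnm_split")
  })
}

#' Inverse-frequency sampling weights
#'
#' Each record's probability is proportional to the inverse of its class
#' count, so a batch drawn with replacement is class-balanced in
#' expectation. Probabilities sum to 1.
#'
#' @param labels integer labels in \{0, 1\} of the training split.
#' @return A numeric vector of sampling probabilities.
#' @export
sampler_weights <- function(labels) {
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts == 0)) {
    stop_lnm("both classes must be present in the training split",
             "lnm_domain_error")
  }
  w <- (1 / counts[as.character(labels)]) / length(counts)
  as.numeric(w)
}

#' Cosine annealing learning rate
#'
#' @param lr0 initial rate.
#' @param epoch 1-based epoch index.
#' @param epochs total epochs.
#' @return The learning rate for `epoch`; decays from `lr0` to 0 at the
#'   final epoch, no restarts.
#' @export
cosine_lr <- function(lr0, epoch, epochs) {
  lr0 * 0.5 * (1 + cos(pi * (epoch - 1) / max(epochs - 1, 1)))
}

# earliest epoch achieving the maximum validation accuracy
select_best_epoch <- function(val_acc) which.max(val_acc)

# contrastive term over however many modalities are in play (3 -> the
# three-pair average; 2 -> the single ordered pair; 1 -> nothing)
contrastive_term <- function(proj, config, grad) {
  if (length(proj) >= 3) return(combined_contrastive(proj, config, grad = grad))
  if (length(proj) == 2) {
    nms <- intersect(c("z_ct", "z_us", "z_clin"), names(proj))
    r <- info_nce(proj[[nms[1]]], proj[[nms[2]]], config, grad = grad)
    pl <- c(ct_clin = NA_real_, us_clin = NA_real_, ct_us = NA_real_)
    key <- paste(sub("z_", "", nms[1]), sub("z_", "", nms[2]), sep = "_")
    key <- sub("clinical", "clin", key)
    if (key %in% names(pl)) pl[key] <- r$mean
    out <- list(pair_losses = pl, contrastive = r$mean)
    if (grad) {
      out$dz <- stats::setNames(list(r$dza, r$dzb), nms)
    }
    return(out)
  }
  NULL
}

mod_feature_name <- function(m) {
  c(ct = "h_ct", us = "h_us", clinical = "h_clin")[m]
}
mod_proj_name <- function(m) {
  c(ct = "z_ct", us = "z_us", clinical = "z_clin")[m]
}

# forward the used encoders over a set of cohort rows
forward_modalities <- function(rows, nets, enc_cfg, normalizer, modalities,
                               training) {
  side <- enc_cfg$image_input_side
  out <- list(H = list(), caches = list(), batches = list())
  for (m in modalities) {
    if (m == "clinical") {
      x <- apply_normalizer(rows, normalizer)
      enc <- nets$enc_clin
      r <- nn_seq_forward(enc$layers, x, training = FALSE)
      out$H[["h_clin"]] <- r$out
      out$caches[["clinical"]] <- r$caches
    } else {
      imgs <- rows[[paste0(m, "_image")]]
      x <- prepare_image_batch(imgs, side, enc_cfg$crop_area_range,
                               training = training, enc_cfg$in_channels)
      enc_name <- if (enc_cfg$share_image_backbone) "enc_ct" else
        paste0("enc_", m)
      r <- nn_seq_forward(nets[[enc_name]]$layers, x, training = training)
      out$H[[mod_feature_name(m)]] <- r$out
      out$caches[[m]] <- r$caches
      out$batches[[m]] <- x
      if (training) nets[[enc_name]]$layers <- r$layers  # BN running stats
    }
  }
  out$nets <- nets
  out
}

#' Train the multi-modal contrastive fusion model
#'
#' Joint optimization of cross-entropy on the fused representation plus the
#' combined contrastive loss, with Adam (cosine-annealed learning rate),
#' inverse-frequency weighted batch sampling, and selection of the epoch
#' with the highest validation accuracy (ties -> earliest).
#'
#' @param cohort an `lnm_cohort` tibble (derived indices are computed if
#'   absent).
#' @param split an [split_cohort()] assignment.
#' @param config a [train_config()].
#' @param enc_cfg an [encoder_config()].
#' @param con_cfg an [contrastive_config()].
#' @param modalities subset of `c("ct", "us", "clinical")` to train on.
#' @param use_contrastive include the contrastive term (needs >= 2
#'   modalities)?
#' @param features clinical feature names fed to the clinical encoder.
#' @param verbose print per-epoch progress?
#' @return An `lnm_fit` checkpoint: best-epoch weights, the resolved
#'   configs, normalization bounds, the split, and the per-epoch metric
#'   history (see [tidy.lnm_fit()]).
#' @export
train_lnm <- function(cohort, split, config = train_config(),
                      enc_cfg = encoder_config(), con_cfg = contrastive_config(),
                      modalities = c("ct", "us", "clinical"),
                      use_contrastive = TRUE,
                      features = clinical_feature_names(), verbose = FALSE) {
  stopifnot(inherits(split, "lnm_split"))
  modalities <- match.arg(modalities, MODALITIES, several.ok = TRUE)
  if (!all(c("nlr", "plr", "sii", "pni") %in% names(cohort)) &&
      "clinical" %in% modalities) {
    cohort <- derived_indices(cohort)
  }
  rows_of <- function(ids) cohort[match(ids, cohort$patient_id), ]
  train_rows <- rows_of(split$train_ids)
  if (length(unique(train_rows$label)) < 2) {
    stop_lnm("training split must contain both classes", "lnm_domain_error")
  }
  use_contrastive <- use_contrastive && length(modalities) >= 2
  with_local_seed(derive_seed(config$seed, "train"), {
    normalizer <- if ("clinical" %in% modalities) {
      fit_normalizer(train_rows, features)
    }
    # --- build networks ---
    nets <- list()
    D <- enc_cfg$feature_dim
    if ("ct" %in% modalities || ("us" %in% modalities &&
                                 enc_cfg$share_image_backbone)) {
      nets$enc_ct <- build_image_encoder(enc_cfg, seed = NULL)
    }
    if ("us" %in% modalities && !enc_cfg$share_image_backbone) {
      nets$enc_us <- build_image_encoder(enc_cfg, seed = NULL)
    }
    if ("clinical" %in% modalities) {
      nets$enc_clin <- build_clinical_encoder(length(features), enc_cfg,
                                              seed = NULL)
    }
    if (use_contrastive) {
      for (m in modalities) {
        nets[[paste0("head_", m)]] <- build_projection_head(D, con_cfg)
      }
    }
    nets$classifier <- build_classifier(length(modalities) * D)
    adam <- lapply(nets, function(nt) adam_init_layers(nt$layers))
    step_t <- 0L
    w <- if (config$class_weighting) sampler_weights(train_rows$label) else
      rep(1 / nrow(train_rows), nrow(train_rows))
    n_batches <- ceiling(nrow(train_rows) / config$batch_size)
    history <- vector("list", config$epochs)
    best <- list(acc = -Inf, epoch = NA_integer_, nets = NULL)
    for (epoch in seq_len(config$epochs)) {
      lr <- cosine_lr(config$lr, epoch, config$epochs)
      ep <- c(ce = 0, contrastive = 0, total = 0,
              ct_clin = 0, us_clin = 0, ct_us = 0)
      for (b in seq_len(n_batches)) {
        idx <- sample.int(nrow(train_rows), config$batch_size,
                          replace = TRUE, prob = w)
        rows <- train_rows[idx, ]
        fw <- forward_modalities(rows, nets, enc_cfg, normalizer, modalities,
                                 training = TRUE)
        nets <- fw$nets
        # projections + contrastive
        frag <- NULL
        proj_caches <- list()
        if (use_contrastive) {
          proj <- list()
          for (m in modalities) {
            hr <- nn_seq_forward(nets[[paste0("head_", m)]]$layers,
                                 fw$H[[mod_feature_name(m)]], training = TRUE)
            proj[[mod_proj_name(m)]] <- hr$out
            proj_caches[[m]] <- hr$caches
          }
          frag <- contrastive_term(proj, con_cfg, grad = TRUE)
        }
        fused <- fuse(fw$H)
        cf <- nn_seq_forward(nets$classifier$layers, fused, training = TRUE)
        ce <- ce_loss(cf$out, rows$label)
        breakdown <- total_loss(cf$out, rows$label, frag)
        stopifnot(abs(breakdown$total -
                        (breakdown$ce + breakdown$contrastive)) < 1e-9)
        if (!is.finite(breakdown$total)) {
          stop_lnm(paste0("training diverged (non-finite loss) at epoch ",
                          epoch, ", batch ", b), "lnm_divergence")
        }
        # --- backward ---
        cb <- nn_seq_backward(nets$classifier$layers, cf$caches, ce$dlogits)
        dH <- list()
        off <- 0
        for (m in intersect(c("ct", "us", "clinical"), modalities)) {
          dH[[m]] <- cb$dx[, off + seq_len(D), drop = FALSE]
          off <- off + D
        }
        grads <- list(classifier = cb$grads)
        if (use_contrastive) {
          for (m in modalities) {
            hb <- nn_seq_backward(nets[[paste0("head_", m)]]$layers,
                                  proj_caches[[m]],
                                  frag$dz[[mod_proj_name(m)]])
            grads[[paste0("head_", m)]] <- hb$grads
            dH[[m]] <- dH[[m]] + hb$dx
          }
        }
        for (m in modalities) {
          if (m == "clinical") {
            eb <- nn_seq_backward(nets$enc_clin$layers, fw$caches$clinical,
                                  dH$clinical)
            grads$enc_clin <- eb$grads
          } else {
            enc_name <- if (enc_cfg$share_image_backbone) "enc_ct" else
              paste0("enc_", m)
            eb <- nn_seq_backward(nets[[enc_name]]$layers, fw$caches[[m]],
                                  dH[[m]])
            if (is.null(grads[[enc_name]])) {
              grads[[enc_name]] <- eb$grads
            } else {
              grads[[enc_name]] <- add_grads(grads[[enc_name]], eb$grads)
            }
          }
        }
        step_t <- step_t + 1L
        for (nm in names(grads)) {
          r <- adam_step_layers(nets[[nm]]$layers, grads[[nm]], adam[[nm]],
                                lr, step_t)
          nets[[nm]]$layers <- r$layers
          adam[[nm]] <- r$state
        }
        ep["ce"] <- ep["ce"] + breakdown$ce
        ep["contrastive"] <- ep["contrastive"] + breakdown$contrastive
        ep["total"] <- ep["total"] + breakdown$total
        if (!is.null(frag)) {
          ep[c("ct_clin", "us_clin", "ct_us")] <-
            ep[c("ct_clin", "us_clin", "ct_us")] +
            ifelse(is.na(frag$pair_losses), 0, frag$pair_losses)
        }
      }
      ep <- ep / n_batches
      # --- validation accuracy under evaluation mode ---
      val_rows <- rows_of(split$val_ids)
      vp <- predict_scores(nets, val_rows, enc_cfg, normalizer, modalities,
                           use_contrastive)
      val_acc <- mean(hard_predictions(vp$logits) == val_rows$label)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, lr = lr, ce = ep[["ce"]],
        contrastive = ep[["contrastive"]], total = ep[["total"]],
        loss_ct_clin = ep[["ct_clin"]], loss_us_clin = ep[["us_clin"]],
        loss_ct_us = ep[["ct_us"]], val_acc = val_acc)
      if (val_acc > best$acc) {
        best <- list(acc = val_acc, epoch = epoch, nets = nets)
      }
      if (verbose) {
        message(sprintf("epoch %d lr %.2e total %.4f val_acc %.3f",
                        epoch, lr, ep[["total"]], val_acc))
      }
    }
    history <- dplyr::bind_rows(history)
    structure(list(nets = best$nets, best_epoch = best$epoch,
                   history = history, normalizer = normalizer,
                   split = split, modalities = modalities,
                   use_contrastive = use_contrastive, features = features,
                   config = config, enc_cfg = enc_cfg, con_cfg = con_cfg),
              class = "lnm_fit")
  })
}

# elementwise sum of two grad structures of identical shape
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- add_grads(a[[i]], b[[i]])
    return(a)
  }
  a + b
}

# evaluation-mode forward returning logits (and probabilities)
predict_scores <- function(nets, rows, enc_cfg, normalizer, modalities,
                           use_contrastive) {
  fw <- forward_modalities(rows, nets, enc_cfg, normalizer, modalities,
                           training = FALSE)
  fused <- fuse(fw$H)
  logits <- nn_seq_forward(nets$classifier$layers, fused,
                           training = FALSE)$out
  z <- logits - apply(logits, 1, max)
  p <- exp(z) / rowSums(exp(z))
  list(logits = logits, prob_pos = p[, 2])
}

#' Predict lymph-node metastasis scores for cohort rows
#'
#' @param object an [train_lnm()] fit.
#' @param cohort an `lnm_cohort`.
#' @param ids patient ids to score (default: the fit's test split).
#' @param ... unused.
#' @return A tibble with `patient_id`, `label`, `score` (positive-class
#'   probability) and `pred` (argmax, ties toward negative).
#' @export
predict.lnm_fit <- function(object, cohort, ids = object$split$test_ids, ...) {
  if ("clinical" %in% object$modalities &&
      !all(c("nlr", "plr", "sii", "pni") %in% names(cohort))) {
    cohort <- derived_indices(cohort)
  }
  rows <- cohort[match(ids, cohort$patient_id), ]
  if (anyNA(rows$patient_id)) {
    stop_lnm("some requested ids are absent from the cohort", "lnm_io_error")
  }
  sc <- predict_scores(object$nets, rows, object$enc_cfg, object$normalizer,
                       object$modalities, object$use_contrastive)
  tibble::tibble(patient_id = rows$patient_id, label = rows$label,
                 score = sc$prob_pos, pred = hard_predictions(sc$logits))
}
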