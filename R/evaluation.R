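# Evaluation: confusion-matrix metrics (ACC/SE/SP as percentages), ROC/AUC
# with the half-credit tie convention (so the trapezoidal area equals the
# pairwise concordance U-statistic exactly), and the modality-ablation
# report.

#' Confusion counts from labels and predictions
#'
#' @param labels,preds integer vectors in \{0, 1\}.
#' @return An `lnm_confusion` list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(labels, preds) {
  stopifnot(length(labels) == length(preds),
            all(labels %in% c(0, 1)), all(preds %in% c(0, 1)))
  structure(list(tp = sum(labels == 1 & preds == 1),
                 tn = sum(labels == 0 & preds == 0),
                 fp = sum(labels == 0 & preds == 1),
                 fn = sum(labels == 1 & preds == 0)),
            class = "lnm_confusion")
}

#' Accuracy, sensitivity and specificity
#'
#' ACC = (TP+TN)/n, SE = TP/(TP+FN), SP = TN/(TN+FP), reported as
#' percentages.
#'
#' @param counts an [confusion_counts()] object, or a named list/vector with
#'   `tp`, `tn`, `fp`, `fn`.
#' @return A tibble with columns `metric` and `value` (percent).
#' @export
#' @examples
#' confusion_metrics(list(tp = 8, fn = 2, tn = 9, fp = 1))
confusion_metrics <- function(counts) {
  cc <- as.list(counts)[c("tp", "tn", "fp", "fn")]
  if (any(vapply(cc, is.null, logical(1)))) {
    stop_lnm("counts must provide tp, tn, fp, fn", "lnm_param_error")
  }
  n <- cc$tp + cc$tn + cc$fp + cc$fn
  if (n == 0) stop_lnm("ACC undefined: no observations", "lnm_undefined_metric")
  if (cc$tp + cc$fn == 0) {
    stop_lnm("SE undefined: no positive cases (tp + fn = 0)",
             "lnm_undefined_metric")
  }
  if (cc$tn + cc$fp == 0) {
    stop_lnm("SP undefined: no negative cases (tn + fp = 0)",
             "lnm_undefined_metric")
  }
  tibble::tibble(
    metric = c("ACC", "SE", "SP"),
    value = 100 * c((cc$tp + cc$tn) / n,
                    cc$tp / (cc$tp + cc$fn),
                    cc$tn / (cc$tn + cc$fp)))
}

#' ROC curve and AUC
#'
#' Sweeps all distinct score thresholds and integrates by the trapezoid
#' rule. Tied scores advance TPR and FPR jointly, which makes the area equal
#' the pairwise concordance probability with ties counted half.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels integer labels in \{0, 1\}; both classes must be present.
#' @return An `lnm_roc` list: `points` tibble (`threshold`, `fpr`, `tpr`)
#'   and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0) {
    stop_lnm("ROC requires both classes", "lnm_domain_error")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0), numeric(1))
  points <- tibble::tibble(threshold = c(Inf, thr),
                           fpr = c(0, fp / N), tpr = c(0, tp / P))
  auc <- sum(diff(points$fpr) *
               (utils::head(points$tpr, -1) + points$tpr[-1]) / 2)
  structure(list(points = points, auc = auc), class = "lnm_roc")
}

#' Evaluate a fit on held-out patients
#'
#' @param fit an [train_lnm()] checkpoint.
#' @param cohort an `lnm_cohort`.
#' @param ids patient ids (default: the fit's test split).
#' @return A one-row tibble: `n`, confusion counts, `acc`, `se`, `sp`
#'   (percent) and `auc` (0-1 scale).
#' @export
evaluate_fit <- function(fit, cohort, ids = fit$split$test_ids) {
  pr <- predict(fit, cohort, ids)
  cc <- confusion_counts(pr$label, pr$pred)
  cm <- confusion_metrics(cc)
  roc <- roc_auc(pr$score, pr$label)
  tibble::tibble(n = nrow(pr), tp = cc$tp, tn = cc$tn, fp = cc$fp,
                 fn = cc$fn,
                 acc = cm$value[cm$metric == "ACC"],
                 se = cm$value[cm$metric == "SE"],
                 sp = cm$value[cm$metric == "SP"],
                 auc = roc$auc)
}

#' Modality-ablation report
#'
#' Trains and evaluates each configuration (a set of modalities with or
#' without the contrastive term) across seeds and reports ACC/SE/SP/AUC as
#' percentages, one row per (configuration, seed) plus a seed-mean row per
#' configuration.
#'
#' @param cohort an `lnm_cohort`.
#' @param configs list of `list(modalities = ..., contrastive = ...)`.
#' @param seeds integer vector; each seed drives the split and the training.
#' @param train_cfg,enc_cfg,con_cfg shared configurations.
#' @return An `lnm_ablation` tibble with columns `ct`, `us`, `clinical`,
#'   `contrastive`, `seed`, `acc`, `se`, `sp`, `auc` (all metric columns in
#'   percent).
#' @export
ablation_table <- function(cohort, configs, seeds = 1:3,
                           train_cfg = train_config(),
                           enc_cfg = encoder_config(),
                           con_cfg = contrastive_config()) {
  if (length(configs) < 1) stop_lnm("need at least one config",
                                    "lnm_param_error")
  rows <- list()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    per_seed <- list()
    for (s in seeds) {
      split <- split_cohort(cohort, seed = s)
      tc <- train_cfg; tc$seed <- as.integer(s)
      row <- tryCatch({
        fit <- train_lnm(cohort, split, tc, enc_cfg, con_cfg,
                         modalities = cfg$modalities,
                         use_contrastive = isTRUE(cfg$contrastive))
        ev <- evaluate_fit(fit, cohort)
        tibble::tibble(acc = ev$acc, se = ev$se, sp = ev$sp,
                       auc = 100 * ev$auc, note = NA_character_)
      }, error = function(e) {
        tibble::tibble(acc = NA_real_, se = NA_real_, sp = NA_real_,
                       auc = NA_real_, note = conditionMessage(e))
      })
      per_seed[[as.character(s)]] <- dplyr::bind_cols(
        tibble::tibble(ct = "ct" %in% cfg$modalities,
                       us = "us" %in% cfg$modalities,
                       clinical = "clinical" %in% cfg$modalities,
                       contrastive = isTRUE(cfg$contrastive),
                       seed = as.character(s)), row)
    }
    per_seed <- dplyr::bind_rows(per_seed)
    mean_row <- dplyr::summarise(per_seed,
      ct = unique(.data$ct), us = unique(.data$us),
      clinical = unique(.data$clinical),
      contrastive = unique(.data$contrastive), seed = "mean",
      acc = mean(.data$acc), se = mean(.data$se), sp = mean(.data$sp),
      auc = mean(.data$auc), note = NA_character_)
    rows[[ci]] <- dplyr::bind_rows(per_seed, mean_row)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("lnm_ablation", class(out))
  out
}
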