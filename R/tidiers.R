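# broom-style accessors and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-epoch training history of a fit
#'
#' @param x an `lnm_fit`.
#' @param ... unused.
#' @return A tibble with one row per epoch: learning rate, mean
#'   cross-entropy, the three contrastive pair losses and their mean, the
#'   total objective, and validation accuracy.
#' @export
tidy.lnm_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x an `lnm_fit`.
#' @param ... unused.
#' @return A tibble with the selected epoch, its validation accuracy, the
#'   modalities used and whether the contrastive term was active.
#' @export
glance.lnm_fit <- function(x, ...) {
  tibble::tibble(best_epoch = x$best_epoch,
                 best_val_acc = x$history$val_acc[x$best_epoch],
                 epochs = nrow(x$history),
                 modalities = paste(x$modalities, collapse = "+"),
                 contrastive = x$use_contrastive,
                 n_train = length(x$split$train_ids),
                 n_val = length(x$split$val_ids),
                 n_test = length(x$split$test_ids))
}

#' @export
print.lnm_fit <- function(x, ...) {
  g <- glance(x)
  cat("<lnm_fit> ", g$modalities,
      if (g$contrastive) "+ contrastive" else "(no contrastive)", "\n")
  cat("  best epoch", g$best_epoch, "of", g$epochs,
      sprintf("(val ACC %.3f)", g$best_val_acc), "\n")
  cat("  split:", g$n_train, "train /", g$n_val, "val /", g$n_test, "test\n")
  invisible(x)
}

#' Plot the training history
#'
#' Loss components and validation accuracy per epoch.
#'
#' @param object an `lnm_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.lnm_fit <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(
    h[, c("epoch", "ce", "contrastive", "total", "val_acc")],
    cols = -"epoch", names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2,
                        colour = "grey40") +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training objective and validation accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a ROC curve
#'
#' @param object an `lnm_roc` from [roc_auc()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.lnm_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @export
print.lnm_roc <- function(x, ...) {
  cat(sprintf("<lnm_roc> AUC = %.4f over %d threshold points\n",
              x$auc, nrow(x$points)))
  invisible(x)
}

#' Plot an ablation report
#'
#' Seed-mean AUC per modality configuration.
#'
#' @param object an `lnm_ablation` from [ablation_table()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.lnm_ablation <- function(object, ...) {
  m <- dplyr::filter(object, .data$seed == "mean")
  m$config <- paste0(ifelse(m$ct, "CT+", ""), ifelse(m$us, "US+", ""),
                     ifelse(m$clinical, "Clin", ""),
                     ifelse(m$contrastive, " (contrastive)", ""))
  long <- tidyr::pivot_longer(m[, c("config", "acc", "se", "sp", "auc")],
                              cols = -"config", names_to = "metric",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$config, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "percent", title = "Modality ablation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
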