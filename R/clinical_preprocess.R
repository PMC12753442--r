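# Clinical-indicator preprocessing: derived inflammation/nutrition indices,
# tumor-marker threshold flags, and the min-max [0,1] normalization applied
# before the clinical encoder.

#' Compute inflammation and nutrition indices
#'
#' Adds the four derived indices to a clinical table:
#' * NLR = neutrophils / lymphocytes
#' * PLR = platelets / lymphocytes
#' * SII = platelets x neutrophils / lymphocytes
#' * PNI = albumin + `pni_multiplier` x lymphocytes
#'
#' Counts are in 10^9/L, albumin in g/L. The conventional PNI multiplier is
#' 5; pass `pni_multiplier = 1` for a plain albumin + lymphocyte sum.
#'
#' @param data a data frame with columns `neutrophils`, `lymphocytes`,
#'   `platelets`, `albumin`.
#' @param pni_multiplier lymphocyte coefficient in the PNI (default 5).
#' @return The input as a tibble with columns `nlr`, `plr`, `sii`, `pni`
#'   appended.
#' @export
#' @examples
#' derived_indices(data.frame(neutrophils = 4, lymphocytes = 2,
#'                            platelets = 250, albumin = 40))
derived_indices <- function(data, pni_multiplier = 5) {
  req <- c("neutrophils", "lymphocytes", "platelets", "albumin")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0) {
    stop_lnm(paste0("missing clinical column(s): ", paste(miss, collapse = ", ")),
             "lnm_missing_field")
  }
  if (any(data$lymphocytes <= 0)) {
    stop_lnm("lymphocyte count must be strictly positive", "lnm_domain_error")
  }
  dplyr::mutate(tibble::as_tibble(data),
    nlr = .data$neutrophils / .data$lymphocytes,
    plr = .data$platelets / .data$lymphocytes,
    sii = .data$platelets * .data$neutrophils / .data$lymphocytes,
    pni = .data$albumin + pni_multiplier * .data$lymphocytes
  )
}

#' Tumor-marker elevation thresholds
#'
#' Clinical cut-offs above which a marker is reported as elevated:
#' SCC-Ag 1.8 ng/mL, CA125 35 U/mL, CA19-9 39 U/mL.
#'
#' @param scc_ag,ca125,ca19_9 positive thresholds.
#' @return A named list of thresholds.
#' @export
marker_thresholds <- function(scc_ag = 1.8, ca125 = 35, ca19_9 = 39) {
  th <- list(scc_ag = scc_ag, ca125 = ca125, ca19_9 = ca19_9)
  if (any(unlist(th) <= 0)) {
    stop_lnm("thresholds must be positive", "lnm_param_error")
  }
  th
}

#' Flag elevated tumor markers
#'
#' A marker is elevated when its value is greater than or equal to the
#' threshold (the clinical convention labels the cut-off itself "elevated").
#'
#' @param data data frame with columns `scc_ag`, `ca125`, `ca19_9`.
#' @param thresholds a [marker_thresholds()] list.
#' @return The input as a tibble with logical columns `scc_elevated`,
#'   `ca125_elevated`, `ca19_9_elevated` appended.
#' @export
binarize_markers <- function(data, thresholds = marker_thresholds()) {
  miss <- setdiff(names(thresholds), names(data))
  if (length(miss) > 0) {
    stop_lnm(paste0("missing marker column(s): ", paste(miss, collapse = ", ")),
             "lnm_missing_field")
  }
  dplyr::mutate(tibble::as_tibble(data),
    scc_elevated = .data$scc_ag >= thresholds$scc_ag,
    ca125_elevated = .data$ca125 >= thresholds$ca125,
    ca19_9_elevated = .data$ca19_9 >= thresholds$ca19_9
  )
}

#' Default clinical feature set for the encoder
#'
#' Eight raw indicators plus the four derived indices (12 features). FIGO
#' stage is excluded by default because its association with the label is
#' near-deterministic; include it with `include_stage = TRUE`.
#'
#' @param include_stage append `figo_stage`?
#' @return Character vector of feature names in their fixed order.
#' @export
clinical_feature_names <- function(include_stage = FALSE) {
  f <- c("age", "scc_ag", "ca125", "ca19_9", "neutrophils", "lymphocytes",
         "platelets", "albumin", "nlr", "plr", "sii", "pni")
  if (include_stage) f <- c(f, "figo_stage")
  f
}

#' Fit a min-max normalizer on training rows
#'
#' Bounds must be fitted on the training split only; held-out values falling
#' outside the training range are clipped into \[0,1\] at application time.
#'
#' @param data training-split data frame containing every feature.
#' @param features feature names, default [clinical_feature_names()].
#' @return An `lnm_normalizer` with per-feature `(lo, hi)` bounds.
#' @export
fit_normalizer <- function(data, features = clinical_feature_names()) {
  if (nrow(data) == 0) {
    stop_lnm("cannot fit a normalizer on an empty training set",
             "lnm_domain_error")
  }
  miss <- setdiff(features, names(data))
  if (length(miss) > 0) {
    stop_lnm(paste0("missing feature column(s): ", paste(miss, collapse = ", ")),
             "lnm_missing_field")
  }
  x <- as.matrix(data[, features, drop = FALSE])
  if (any(!is.finite(x))) {
    stop_lnm("non-finite feature values in training data", "lnm_domain_error")
  }
  structure(list(features = features,
                 lo = apply(x, 2, min), hi = apply(x, 2, max)),
            class = "lnm_normalizer")
}

#' Apply a fitted normalizer
#'
#' @param data data frame containing the normalizer's features.
#' @param normalizer an [fit_normalizer()] object.
#' @return A numeric matrix (rows = patients) with every entry in \[0,1\];
#'   constant training features map to 0.
#' @export
apply_normalizer <- function(data, normalizer) {
  stopifnot(inherits(normalizer, "lnm_normalizer"))
  miss <- setdiff(normalizer$features, names(data))
  if (length(miss) > 0) {
    stop_lnm(paste0("missing feature column(s): ", paste(miss, collapse = ", ")),
             "lnm_missing_field")
  }
  x <- as.matrix(data[, normalizer$features, drop = FALSE])
  rng <- normalizer$hi - normalizer$lo
  out <- sweep(x, 2, normalizer$lo)
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), `/`)
  out[, rng == 0] <- 0
  out <- pmin(pmax(out, 0), 1)
  colnames(out) <- normalizer$features
  out
}
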