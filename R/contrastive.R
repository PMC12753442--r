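# Contrastive alignment of the three modality representations: projection
# heads into a 128-d space, cosine similarity, per-pair InfoNCE, and the
# three-pair average. Analytic gradients are provided for training and are
# verified against numerical differentiation in the test suite.

#' Contrastive-loss configuration
#'
#' @param temperature softmax temperature tau > 0 (default 1).
#' @param projection_dim width of the contrastive space (default 128).
#' @param projection_hidden hidden width of the projection heads.
#' @param include_positive_in_denominator the default (`FALSE`) follows the
#'   form in which the normalizing sum runs over other patients only
#'   (j != i); `TRUE` gives the common InfoNCE variant that includes the
#'   positive pair in the denominator.
#' @param symmetrize average the a->b and b->a losses per pair (default off;
#'   each pair is scored one-directionally).
#' @return An `lnm_contrastive_config` list.
#' @export
contrastive_config <- function(temperature = 1, projection_dim = 128L,
                               projection_hidden = 256L,
                               include_positive_in_denominator = FALSE,
                               symmetrize = FALSE) {
  if (temperature <= 0) stop_lnm("temperature must be > 0", "lnm_param_error")
  structure(list(temperature = temperature,
                 projection_dim = as.integer(projection_dim),
                 projection_hidden = as.integer(projection_hidden),
                 include_positive_in_denominator =
                   isTRUE(include_positive_in_denominator),
                 symmetrize = isTRUE(symmetrize)),
            class = "lnm_contrastive_config")
}

#' Build a projection head
#'
#' Two-layer perceptron `d_in -> projection_hidden -> projection_dim` with a
#' rectifier between the layers.
#'
#' @param d_in input feature width (the encoders' `feature_dim`).
#' @param config an [contrastive_config()].
#' @param seed optional initialization seed (`NULL` = current RNG stream).
#' @return An `lnm_projection_head`.
#' @export
build_projection_head <- function(d_in, config = contrastive_config(),
                                  seed = NULL) {
  build <- function() {
    list(nn_dense(d_in, config$projection_hidden), nn_relu(),
         nn_dense(config$projection_hidden, config$projection_dim))
  }
  layers <- if (is.null(seed)) build() else with_local_seed(seed, build())
  structure(list(layers = layers, d_in = d_in, cfg = config),
            class = "lnm_projection_head")
}

#' Project modality features into the contrastive space
#'
#' @param features a matrix `n x d_in`, or a named list of such matrices.
#' @param heads a single `lnm_projection_head` or a named list matching
#'   `features`.
#' @return The projected `n x projection_dim` matrix (or named list).
#' @export
project <- function(features, heads) {
  if (is.matrix(features)) {
    stopifnot(inherits(heads, "lnm_projection_head"))
    if (ncol(features) != heads$d_in) {
      stop_lnm(paste0("feature width ", ncol(features), " != head input ",
                      heads$d_in), "lnm_shape_error")
    }
    return(nn_seq_forward(heads$layers, features, training = FALSE)$out)
  }
  stopifnot(is.list(features), is.list(heads),
            all(names(features) %in% names(heads)))
  lapply(stats::setNames(names(features), names(features)),
         function(nm) project(features[[nm]], heads[[nm]]))
}

row_normalize <- function(z, what = "embedding") {
  nr <- sqrt(rowSums(z * z))
  if (any(nr < 1e-12)) {
    stop_lnm(paste0("zero-norm ", what, " row: cosine similarity undefined"),
             "lnm_domain_error")
  }
  list(u = z / nr, norm = nr)
}

#' Cosine similarity between two vectors
#'
#' @param za,zb numeric vectors of equal length with positive norm.
#' @return A scalar in \[-1, 1\].
#' @export
#' @examples
#' cosine_similarity(c(1, 2, 3), c(4, 5, 6))
cosine_similarity <- function(za, zb) {
  stopifnot(length(za) == length(zb))
  na <- sqrt(sum(za^2)); nb <- sqrt(sum(zb^2))
  if (na < 1e-12 || nb < 1e-12) {
    stop_lnm("zero-norm vector: cosine similarity undefined",
             "lnm_domain_error")
  }
  sum(za * zb) / (na * nb)
}

# One-directional InfoNCE core: given row-normalized U (anchors) and V
# (candidates), returns per-anchor losses and optionally d(mean loss)/dS.
info_nce_core <- function(U, V, tau, include_positive, grad = FALSE) {
  n <- nrow(U)
  S <- U %*% t(V)
  L <- S / tau
  mask <- matrix(TRUE, n, n)
  if (!include_positive) diag(mask) <- FALSE
  Lm <- L
  Lm[!mask] <- -Inf
  mx <- apply(Lm, 1, max)
  ex <- exp(Lm - mx)
  den <- rowSums(ex)
  per_anchor <- -(diag(L) - (mx + log(den)))
  out <- list(per_anchor = per_anchor, mean = mean(per_anchor))
  if (grad) {
    P <- ex / den
    dS <- P / (n * tau)
    diag(dS) <- diag(dS) - 1 / (n * tau)
    out$dS <- dS
  }
  out
}

# Backprop through row normalization: given dU = dL/dU and the original rows
# z with norms, return dL/dz.
normalize_bwd <- function(dU, u, norm) {
  (dU - u * rowSums(u * dU)) / norm
}

#' InfoNCE loss between two aligned embedding batches
#'
#' Row `i` of `za` and row `i` of `zb` form the positive pair for patient
#' `i`; every cross-patient pair (`za` row i vs `zb` row j, j != i) is a
#' negative. Similarities are cosine, scaled by the temperature. By default
#' the denominator sums over the negatives only; see
#' [contrastive_config()] for the conventional variant and for the
#' symmetrized form.
#'
#' @param za,zb `n x d` matrices, `n >= 2`, no zero rows.
#' @param config an [contrastive_config()].
#' @param grad also return gradients of the mean loss w.r.t. `za` and `zb`?
#' @return A list with `per_anchor` (length n) and `mean`; with
#'   `grad = TRUE`, also `dza` and `dzb`.
#' @export
info_nce <- function(za, zb, config = contrastive_config(), grad = FALSE) {
  za <- as.matrix(za); zb <- as.matrix(zb)
  if (nrow(za) != nrow(zb) || ncol(za) != ncol(zb)) {
    stop_lnm("za and zb must have identical dimensions", "lnm_shape_error")
  }
  if (nrow(za) < 2) {
    stop_lnm("InfoNCE needs a batch of at least 2", "lnm_domain_error")
  }
  a <- row_normalize(za); b <- row_normalize(zb)
  tau <- config$temperature
  inc <- config$include_positive_in_denominator
  f <- info_nce_core(a$u, b$u, tau, inc, grad = grad)
  if (config$symmetrize) {
    r <- info_nce_core(b$u, a$u, tau, inc, grad = grad)
    per_anchor <- (f$per_anchor + r$per_anchor) / 2
    out <- list(per_anchor = per_anchor, mean = mean(per_anchor))
    if (grad) {
      dU <- (f$dS %*% b$u + t(r$dS) %*% b$u) / 2
      dV <- (t(f$dS) %*% a$u + r$dS %*% a$u) / 2
      out$dza <- normalize_bwd(dU, a$u, a$norm)
      out$dzb <- normalize_bwd(dV, b$u, b$norm)
    }
    return(out)
  }
  out <- list(per_anchor = f$per_anchor, mean = f$mean)
  if (grad) {
    out$dza <- normalize_bwd(f$dS %*% b$u, a$u, a$norm)
    out$dzb <- normalize_bwd(t(f$dS) %*% a$u, b$u, b$norm)
  }
  out
}

#' Three-pair combined contrastive loss
#'
#' The mean of the three ordered pair losses CT->clinical, US->clinical and
#' CT->US.
#'
#' @param proj named list with matrices `z_ct`, `z_us`, `z_clin` (aligned
#'   rows).
#' @param config an [contrastive_config()].
#' @param grad also return gradients w.r.t. each projection matrix?
#' @return A list with `pair_losses` (named length-3 vector), `contrastive`
#'   (their mean), and with `grad = TRUE` a named list `dz`.
#' @export
combined_contrastive <- function(proj, config = contrastive_config(),
                                 grad = FALSE) {
  req <- c("z_ct", "z_us", "z_clin")
  stopifnot(all(req %in% names(proj)))
  ns <- vapply(proj[req], nrow, integer(1))
  if (length(unique(ns)) != 1) {
    stop_lnm("projection row counts differ across modalities",
             "lnm_shape_error")
  }
  pairs <- list(ct_clin = c("z_ct", "z_clin"),
                us_clin = c("z_us", "z_clin"),
                ct_us = c("z_ct", "z_us"))
  pair_losses <- numeric(3)
  names(pair_losses) <- names(pairs)
  dz <- lapply(proj[req], function(z) z * 0)
  for (k in seq_along(pairs)) {
    a <- pairs[[k]][1]; b <- pairs[[k]][2]
    r <- info_nce(proj[[a]], proj[[b]], config, grad = grad)
    pair_losses[k] <- r$mean
    if (grad) {
      dz[[a]] <- dz[[a]] + r$dza / 3
      dz[[b]] <- dz[[b]] + r$dzb / 3
    }
  }
  out <- list(pair_losses = pair_losses, contrastive = mean(pair_losses))
  if (grad) out$dz <- dz
  out
}
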