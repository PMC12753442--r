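# Modality encoders: a residual convolutional backbone for images (feature
# taken where a classification head would sit, i.e. after global average
# pooling) and a two-layer perceptron for the normalized clinical vector.
# Both emit D = 512 features per patient.

#' Encoder configuration
#'
#' @param feature_dim width D of every modality representation (default 512).
#' @param clinical_hidden hidden width of the clinical MLP (default 256).
#' @param image_input_side spatial side the encoders consume after
#'   crop-and-resize. 224 is the fidelity setting; smaller sides (e.g. 64)
#'   pair with the `"small"` backbone for CPU-scale runs.
#' @param crop_area_range `(low, high)` area fractions for random cropping
#'   during training; evaluation always center-crops at fraction 1.
#' @param backbone `"resnet18"` (stem + 4 stages x 2 residual blocks,
#'   widths 64/128/256/512) or `"small"` (stem + 2 residual blocks, widths
#'   8/16/32, followed by a linear map to `feature_dim`).
#' @param init `"random"` (default) or `"file"` to load weights from
#'   `weights_file` (an RDS of a previously trained encoder).
#' @param weights_file path used when `init = "file"`.
#' @param share_image_backbone use one weight set for both CT and US
#'   encoders instead of two independent ones (default independent).
#' @param in_channels channel count the backbone expects; grayscale inputs
#'   are replicated to this many channels.
#' @param seed integer seed for weight initialization.
#' @return An `lnm_encoder_config` list.
#' @export
encoder_config <- function(feature_dim = 512L, clinical_hidden = 256L,
                           image_input_side = 224L,
                           crop_area_range = c(0.7, 1.0),
                           backbone = c("resnet18", "small"),
                           init = c("random", "file"), weights_file = NULL,
                           share_image_backbone = FALSE, in_channels = 3L,
                           seed = 1L) {
  backbone <- match.arg(backbone)
  init <- match.arg(init)
  if (length(crop_area_range) != 2 || crop_area_range[1] <= 0 ||
      crop_area_range[1] > crop_area_range[2] || crop_area_range[2] > 1) {
    stop_lnm("crop_area_range must satisfy 0 < low <= high <= 1",
             "lnm_param_error")
  }
  if (init == "file" && is.null(weights_file)) {
    stop_lnm("init = 'file' requires weights_file", "lnm_param_error")
  }
  structure(list(feature_dim = as.integer(feature_dim),
                 clinical_hidden = as.integer(clinical_hidden),
                 image_input_side = as.integer(image_input_side),
                 crop_area_range = crop_area_range, backbone = backbone,
                 init = init, weights_file = weights_file,
                 share_image_backbone = isTRUE(share_image_backbone),
                 in_channels = as.integer(in_channels),
                 seed = as.integer(seed)),
            class = "lnm_encoder_config")
}

# Bilinear resize of a single-channel matrix to side x side. Sample points
# are placed with the half-pixel (align-corners-false) convention.
resize_bilinear <- function(img, side) {
  h <- nrow(img); w <- ncol(img)
  if (h == side && w == side) return(img)
  sy <- (seq_len(side) - 0.5) * h / side + 0.5
  sx <- (seq_len(side) - 0.5) * w / side + 0.5
  y0 <- pmin(pmax(floor(sy), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(sx), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(sy - y0, 0), 1); fx <- pmin(pmax(sx - x0, 0), 1)
  a <- img[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx)
  b <- img[y1, x0, drop = FALSE] * outer(fy, 1 - fx)
  cc <- img[y0, x1, drop = FALSE] * outer(1 - fy, fx)
  d <- img[y1, x1, drop = FALSE] * outer(fy, fx)
  a + b + cc + d
}

#' Random crop and resize augmentation
#'
#' Training mode samples an area fraction uniformly from `crop_area_range`,
#' takes an aspect-preserving crop of that area at a uniformly random
#' location, and bilinearly resizes it to `side`. Evaluation mode uses the
#' full image (center crop at fraction 1). Crop sides round up to whole
#' pixels, so realized area fractions sit within the configured range up to
#' that quantization. Randomness comes from the R RNG stream, so a fixed
#' seed reproduces crops exactly.
#'
#' @param image 2-D intensity matrix, at least 8x8.
#' @param side output side length in pixels.
#' @param crop_area_range `(low, high)` area fractions.
#' @param training sample a random crop (`TRUE`) or use the full image.
#' @return A `side` x `side` matrix.
#' @export
random_crop_resize <- function(image, side, crop_area_range = c(0.7, 1.0),
                               training = TRUE) {
  h <- nrow(image); w <- ncol(image)
  if (is.null(h) || h < 8 || w < 8) {
    stop_lnm("image must be at least 8x8", "lnm_domain_error")
  }
  if (training && (crop_area_range[1] < 1 || crop_area_range[2] < 1)) {
    g <- sample_crop_geometry(h, w, crop_area_range)
    image <- image[g$oy:(g$oy + g$ch - 1), g$ox:(g$ox + g$cw - 1),
                   drop = FALSE]
  }
  resize_bilinear(image, side)
}

# Sample the crop rectangle: area fraction uniform on the configured range,
# aspect preserved, crop sides rounded up to whole pixels, location uniform.
sample_crop_geometry <- function(h, w, crop_area_range) {
  f <- runif(1, crop_area_range[1], crop_area_range[2])
  ch <- min(h, ceiling(sqrt(f) * h))
  cw <- min(w, ceiling(sqrt(f) * w))
  list(oy = if (ch < h) sample.int(h - ch + 1, 1) else 1L,
       ox = if (cw < w) sample.int(w - cw + 1, 1) else 1L,
       ch = ch, cw = cw)
}

# Stack a list of 2-D images into an (side, side, in_channels, n) batch,
# applying the crop-resize policy per image and replicating grayscale to the
# backbone's channel count.
prepare_image_batch <- function(images, side, crop_area_range, training,
                                in_channels = 3L) {
  n <- length(images)
  out <- array(0, dim = c(side, side, in_channels, n))
  for (i in seq_len(n)) {
    im <- random_crop_resize(images[[i]], side, crop_area_range, training)
    for (c in seq_len(in_channels)) out[, , c, i] <- im
  }
  out
}

build_backbone_layers <- function(cfg) {
  if (cfg$backbone == "resnet18") {
    layers <- list(nn_conv(7, 7, cfg$in_channels, 64, stride = 2L, pad = 3L),
                   nn_bn(64), nn_relu(), nn_maxpool(3L, 2L))
    widths <- c(64, 128, 256, 512)
    ci <- 64
    for (k in seq_along(widths)) {
      s <- if (k == 1) 1L else 2L
      layers <- c(layers, list(nn_resblock(ci, widths[k], stride = s),
                               nn_resblock(widths[k], widths[k], stride = 1L)))
      ci <- widths[k]
    }
    layers <- c(layers, list(nn_gap()))
    out_width <- 512L
  } else {
    layers <- list(nn_conv(3, 3, cfg$in_channels, 8, stride = 2L, pad = 1L),
                   nn_bn(8), nn_relu(),
                   nn_resblock(8, 16, stride = 2L),
                   nn_resblock(16, 32, stride = 2L),
                   nn_gap())
    out_width <- 32L
  }
  if (out_width != cfg$feature_dim) {
    layers <- c(layers, list(nn_dense(out_width, cfg$feature_dim)))
  }
  layers
}

#' Build an image encoder
#'
#' @param config an [encoder_config()].
#' @param seed optional seed for weight initialization; defaults to the
#'   config seed. Pass `NULL` to draw from the current RNG stream.
#' @return An `lnm_image_encoder`.
#' @export
build_image_encoder <- function(config, seed = config$seed) {
  build <- function() build_backbone_layers(config)
  layers <- if (is.null(seed)) build() else with_local_seed(seed, build())
  enc <- structure(list(layers = layers, cfg = config),
                   class = "lnm_image_encoder")
  if (config$init == "file") {
    w <- readRDS(config$weights_file)
    if (!inherits(w, "lnm_image_encoder")) {
      stop_lnm("weights_file must contain an lnm_image_encoder",
               "lnm_param_error")
    }
    enc$layers <- w$layers
  }
  enc
}

#' Build a clinical encoder
#'
#' Two affine layers, `n_features -> clinical_hidden -> feature_dim`, with a
#' rectifier between them and none after the second (the features feed both
#' the projection head and the fusion classifier).
#'
#' @param n_features width of the normalized clinical vector.
#' @param config an [encoder_config()].
#' @param seed as in [build_image_encoder()].
#' @return An `lnm_clinical_encoder`.
#' @export
build_clinical_encoder <- function(n_features, config, seed = config$seed) {
  build <- function() {
    list(nn_dense(n_features, config$clinical_hidden), nn_relu(),
         nn_dense(config$clinical_hidden, config$feature_dim))
  }
  layers <- if (is.null(seed)) build() else with_local_seed(seed, build())
  structure(list(layers = layers, n_features = n_features, cfg = config),
            class = "lnm_clinical_encoder")
}

#' Encode a batch of images
#'
#' @param images a list of `side` x `side` matrices (already cropped and
#'   resized), or an array dim `(side, side, channels, n)`.
#' @param encoder an [build_image_encoder()] object.
#' @param training training mode (batch-norm uses batch statistics)?
#' @return An `n x feature_dim` matrix of image representations.
#' @export
image_encode <- function(images, encoder, training = FALSE) {
  stopifnot(inherits(encoder, "lnm_image_encoder"))
  side <- encoder$cfg$image_input_side
  if (is.list(images)) {
    ok <- vapply(images, function(m) all(dim(m) == c(side, side)), logical(1))
    if (!all(ok)) {
      stop_lnm(paste0("images must be ", side, "x", side,
                      " (apply random_crop_resize first)"),
               "lnm_shape_error")
    }
    x <- array(0, dim = c(side, side, encoder$cfg$in_channels, length(images)))
    for (i in seq_along(images)) {
      for (c in seq_len(encoder$cfg$in_channels)) x[, , c, i] <- images[[i]]
    }
  } else {
    x <- images
    if (length(dim(x)) != 4 || dim(x)[1] != side || dim(x)[2] != side) {
      stop_lnm(paste0("image batch must be (", side, ", ", side,
                      ", channels, n)"), "lnm_shape_error")
    }
  }
  nn_seq_forward(encoder$layers, x, training = training)$out
}

#' Encode a batch of clinical vectors
#'
#' @param x an `n x n_features` matrix of normalized (\[0,1\]) clinical
#'   features.
#' @param encoder a [build_clinical_encoder()] object.
#' @return An `n x feature_dim` matrix.
#' @export
clinical_encode <- function(x, encoder) {
  stopifnot(inherits(encoder, "lnm_clinical_encoder"))
  x <- as.matrix(x)
  if (ncol(x) != encoder$n_features) {
    stop_lnm(paste0("expected ", encoder$n_features, " features, got ",
                    ncol(x)), "lnm_shape_error")
  }
  nn_seq_forward(encoder$layers, x, training = FALSE)$out
}
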