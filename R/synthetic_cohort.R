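# Synthetic multi-modal cohort generator.
#
# Emulates the statistical structure the modelling pipeline assumes: a small
# cohort with strong class imbalance (16 of 127 positive by default), one
# CT-like and one US-like grayscale image per patient with a class-dependent
# localized signal, and clinical indicators drawn inside standard laboratory
# reference ranges with a class shift in standardized units.

#' Parameters for a synthetic cohort
#'
#' Defaults mirror the modelled study population: 127 patients of whom 16
#' are lymph-node positive (~12.6% prevalence). `effect_ct`, `effect_us` and
#' `effect_clin` control how much class signal each modality carries, in
#' standardized units for clinical values and as a multiple of a baseline
#' blob amplitude for images; 0 plants no signal at all.
#'
#' @param seed integer seed; identical parameters and seed reproduce the
#'   cohort exactly.
#' @param n_patients cohort size.
#' @param n_positive exact number of positive-label patients.
#' @param image_size side length in pixels of the square generated images.
#' @param effect_ct,effect_us,effect_clin non-negative class-signal
#'   amplitudes per modality.
#' @param noise_sd pixel noise standard deviation (intensity units, images
#'   live in \[0,1\]).
#' @return A validated `lnm_synthetic_params` list.
#' @export
#' @examples
#' p <- synthetic_params(seed = 7, n_patients = 40, n_positive = 5,
#'                       image_size = 16)
synthetic_params <- function(seed = 1L, n_patients = 127L, n_positive = 16L,
                             image_size = 64L, effect_ct = 1, effect_us = 1,
                             effect_clin = 1, noise_sd = 0.05) {
  p <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
            n_positive = as.integer(n_positive),
            image_size = as.integer(image_size),
            effect_ct = effect_ct, effect_us = effect_us,
            effect_clin = effect_clin, noise_sd = noise_sd)
  nums <- unlist(p)
  if (any(!is.finite(nums))) {
    stop_lnm("all synthetic parameters must be finite", "lnm_param_error")
  }
  if (p$n_positive > p$n_patients || p$n_positive < 0) {
    stop_lnm("n_positive must lie in [0, n_patients]", "lnm_param_error")
  }
  if (any(c(p$effect_ct, p$effect_us, p$effect_clin) < 0) || p$noise_sd <= 0) {
    stop_lnm("effects must be >= 0 and noise_sd > 0", "lnm_param_error")
  }
  if (p$image_size < 8) stop_lnm("image_size must be >= 8", "lnm_param_error")
  structure(p, class = "lnm_synthetic_params")
}

# Inverse-CDF truncated normal: deterministic given the RNG stream and exact
# under vectorization.
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Per-indicator recipe: center/sd inside the laboratory reference ranges,
# truncation keeping values physiologically plausible, and the direction of
# the positive-class shift (in units of the generating sd).
clinical_recipe <- function() {
  tibble::tribble(
    ~name,          ~mean, ~sd,  ~lo,   ~hi, ~shift,
    "age",           55,    10,   25,    90,  0,
    "scc_ag",        1.55,  0.5,  0.01,  Inf, +1,
    "ca125",         20,    8,    1,     Inf, 0,
    "ca19_9",        18,    8,    1,     Inf, 0,
    "neutrophils",   4.0,   1.1,  0.2,   Inf, +1,
    "lymphocytes",   2.0,   0.5,  0.2,   Inf, -1,
    "platelets",     237,   55,   20,    Inf, +1,
    "albumin",       45,    3.5,  20,    70,  -1
  )
}

# One grayscale image in [0,1]: smooth background, plus for positive labels a
# Gaussian blob of amplitude 0.1 * effect at a random location, plus pixel
# noise. The US flavour carries heavier speckle-like noise than CT.
synth_image <- function(size, label, effect, noise_sd, modality) {
  ax <- seq(0, 1, length.out = size)
  phase <- runif(2, 0, 2 * pi)
  bg <- 0.45 + 0.1 * outer(cos(2 * pi * ax + phase[1]),
                           sin(2 * pi * ax + phase[2]))
  img <- bg
  if (label == 1 && effect > 0) {
    ctr <- runif(2, 0.25, 0.75)
    w <- 1 / 8
    blob <- 0.1 * effect *
      outer(exp(-(ax - ctr[1])^2 / (2 * w^2)),
            exp(-(ax - ctr[2])^2 / (2 * w^2)))
    img <- img + blob
  }
  mult <- if (modality == "us") 1.5 else 1
  img <- img + matrix(rnorm(size^2, sd = noise_sd * mult), size, size)
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic multi-modal cohort
#'
#' @param params a [synthetic_params()] object.
#' @return An `lnm_cohort` tibble with one row per patient: `patient_id`,
#'   list-columns `ct_image` and `us_image` (square matrices in \[0,1\]),
#'   the raw clinical indicators, `figo_stage` (1-4, ordinal, strongly
#'   associated with the label) and integer `label` (1 = node-positive).
#'   The generating parameters are stored in the `"params"` attribute.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_params(seed = 7, n_patients = 20,
#'                                            n_positive = 3, image_size = 16))
#' table(cohort$label)
generate_cohort <- function(params) {
  stopifnot(inherits(params, "lnm_synthetic_params"))
  with_local_seed(derive_seed(params$seed, "cohort"), {
    n <- params$n_patients
    label <- sample(rep(c(1L, 0L), c(params$n_positive, n - params$n_positive)))
    rec <- clinical_recipe()
    clin <- lapply(seq_len(nrow(rec)), function(i) {
      r <- rec[i, ]
      mu <- r$mean + r$shift * params$effect_clin * r$sd * label
      rtrunc_norm(n, mu, r$sd, r$lo, r$hi)
    })
    names(clin) <- rec$name
    # FIGO stage: near-deterministic association with the label, mirroring
    # the kind of imbalance seen in baseline tables of node-positive disease
    p_neg <- c(0.60, 0.39, 0.008, 0.002)
    p_pos <- c(0.08, 0.12, 0.55, 0.25)
    stage <- vapply(label, function(l) {
      sample(1:4, 1, prob = if (l == 1) p_pos else p_neg)
    }, integer(1))
    ct <- lapply(seq_len(n), function(i) {
      synth_image(params$image_size, label[i], params$effect_ct,
                  params$noise_sd, "ct")
    })
    us <- lapply(seq_len(n), function(i) {
      synth_image(params$image_size, label[i], params$effect_us,
                  params$noise_sd, "us")
    })
    cohort <- tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      ct_image = ct, us_image = us,
      !!!clin,
      figo_stage = stage,
      label = label
    )
    attr(cohort, "params") <- params
    class(cohort) <- c("lnm_cohort", class(cohort))
    cohort
  })
}

clinical_columns <- function() {
  c("age", "scc_ag", "ca125", "ca19_9", "neutrophils", "lymphocytes",
    "platelets", "albumin")
}

#' Write a cohort to disk
#'
#' Writes one 8-bit grayscale PNG per image, a clinical CSV keyed by
#' `patient_id`, and a manifest CSV (`patient_id`, `ct_path`, `us_path`,
#' `label`) linking them. Image intensities round-trip within 1/255.
#'
#' @param cohort an `lnm_cohort` tibble.
#' @param directory output directory, created if absent.
#' @param overwrite overwrite an existing manifest? Defaults to refusing.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, directory, overwrite = FALSE) {
  manifest_path <- file.path(directory, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite) {
    stop_lnm(paste0("manifest already exists at ", manifest_path,
                    "; pass overwrite = TRUE to replace it"),
             "lnm_io_error")
  }
  dir.create(file.path(directory, "images"), recursive = TRUE,
             showWarnings = FALSE)
  n <- nrow(cohort)
  ct_path <- character(n)
  us_path <- character(n)
  for (i in seq_len(n)) {
    ct_path[i] <- file.path("images", paste0(cohort$patient_id[i], "_ct.png"))
    us_path[i] <- file.path("images", paste0(cohort$patient_id[i], "_us.png"))
    png::writePNG(cohort$ct_image[[i]], file.path(directory, ct_path[i]))
    png::writePNG(cohort$us_image[[i]], file.path(directory, us_path[i]))
  }
  manifest <- data.frame(patient_id = cohort$patient_id,
                         ct_path = ct_path, us_path = us_path,
                         label = cohort$label)
  write.csv(manifest, manifest_path, row.names = FALSE)
  clin <- as.data.frame(cohort[, c("patient_id", clinical_columns(),
                                   "figo_stage")])
  write.csv(clin, file.path(directory, "clinical.csv"), row.names = FALSE)
  invisible(manifest_path)
}

#' Read a cohort from a manifest
#'
#' @param manifest path to a manifest CSV written by [write_cohort()] (or
#'   assembled by hand for real data: columns `patient_id`, `ct_path`,
#'   `us_path`, `label`, with a `clinical.csv` beside it).
#' @return An `lnm_cohort` tibble ordered as in the manifest.
#' @export
read_cohort <- function(manifest) {
  if (!file.exists(manifest)) {
    stop_lnm(paste0("manifest not found: ", manifest), "lnm_io_error")
  }
  root <- dirname(manifest)
  mf <- read.csv(manifest, stringsAsFactors = FALSE)
  req <- c("patient_id", "ct_path", "us_path", "label")
  missing_cols <- setdiff(req, names(mf))
  if (length(missing_cols) > 0) {
    stop_lnm(paste0("manifest is missing column(s): ",
                    paste(missing_cols, collapse = ", ")), "lnm_io_error")
  }
  if (anyDuplicated(mf$patient_id)) {
    stop_lnm("duplicate patient_id in manifest", "lnm_io_error")
  }
  read_img <- function(path, id) {
    fp <- file.path(root, path)
    if (!file.exists(fp)) {
      stop_lnm(paste0("image file missing for patient ", id, ": ", fp),
               "lnm_io_error")
    }
    img <- png::readPNG(fp)
    if (length(dim(img)) == 3) img <- img[, , 1]  # collapse RGB(A) to gray
    img
  }
  if (nrow(mf) == 0) {
    cohort <- tibble::tibble(patient_id = character(),
                             ct_image = list(), us_image = list(),
                             label = integer())
    class(cohort) <- c("lnm_cohort", class(cohort))
    return(cohort)
  }
  ct <- mapply(read_img, mf$ct_path, mf$patient_id, SIMPLIFY = FALSE)
  us <- mapply(read_img, mf$us_path, mf$patient_id, SIMPLIFY = FALSE)
  cohort <- tibble::tibble(patient_id = mf$patient_id,
                           ct_image = unname(ct), us_image = unname(us),
                           label = as.integer(mf$label))
  clin_path <- file.path(root, "clinical.csv")
  if (file.exists(clin_path)) {
    clin <- read.csv(clin_path, stringsAsFactors = FALSE)
    cohort <- dplyr::left_join(cohort, clin, by = "patient_id")
  }
  attr(cohort, "params") <- paste0("read from ", manifest)
  class(cohort) <- c("lnm_cohort", class(cohort))
  cohort
}
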