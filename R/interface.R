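# Run configuration and the end-to-end pipeline:
# simulate -> split -> train -> evaluate -> baseline statistics,
# with every artifact written under one run directory and a single global
# seed fanned out deterministically per stage.

run_config_defaults <- function() {
  list(
    seed = 1L,
    output_dir = "lnm_run",
    cohort = list(n_patients = 127L, n_positive = 16L, image_size = 64L,
                  effect_ct = 1, effect_us = 1, effect_clin = 1,
                  noise_sd = 0.05),
    encoder = list(feature_dim = 512L, clinical_hidden = 256L,
                   image_input_side = 64L, crop_area_range = c(0.7, 1.0),
                   backbone = "small", share_image_backbone = FALSE),
    contrastive = list(temperature = 1, projection_dim = 128L,
                       projection_hidden = 256L,
                       include_positive_in_denominator = FALSE,
                       symmetrize = FALSE),
    train = list(lr = 1e-3, epochs = 30L, batch_size = 8L,
                 class_weighting = TRUE),
    evaluation = list(modalities = c("ct", "us", "clinical"),
                      contrastive = TRUE, baseline_table = TRUE)
  )
}

#' Load and validate a run configuration
#'
#' A configuration is a named list (or a YAML file holding one) with blocks
#' `cohort`, `encoder`, `contrastive`, `train` and `evaluation`, plus a
#' global `seed` and `output_dir`. Every block must be present (it may be
#' empty); unset fields are filled with the documented defaults so the
#' resolved configuration written into the run directory reproduces the run
#' exactly.
#'
#' @param config a named list or a path to a YAML file.
#' @return The resolved `lnm_run_config` list.
#' @export
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    stop_lnm("config must be a list or a YAML file path", "lnm_config_error")
  }
  defaults <- run_config_defaults()
  blocks <- c("cohort", "encoder", "contrastive", "train", "evaluation")
  missing_blocks <- setdiff(blocks, names(config))
  if (length(missing_blocks) > 0) {
    stop_lnm(paste0("config is missing block(s): ",
                    paste(missing_blocks, collapse = ", ")),
             "lnm_config_error")
  }
  out <- defaults
  out$seed <- as.integer(config$seed %||% defaults$seed)
  out$output_dir <- config$output_dir %||% defaults$output_dir
  for (b in blocks) {
    out[[b]] <- utils::modifyList(defaults[[b]], as.list(config[[b]]))
  }
  structure(out, class = "lnm_run_config")
}

#' Run the full pipeline into a run directory
#'
#' Generates a synthetic cohort, writes it to disk, splits it 80/10/10,
#' trains the fusion model, evaluates on the held-out test split, produces
#' the baseline-characteristics table, and stores per-epoch JSON-lines logs,
#' the resolved configuration and the checkpoint. Re-running with the same
#' configuration reproduces the cohort, the split and the metric trajectory.
#'
#' @param config an [load_run_config()] input (list or YAML path).
#' @param overwrite overwrite an existing run directory's cohort?
#' @return Invisibly, a list with the run `dir`, the `fit`, the test
#'   `metrics` tibble and the artifact paths.
#' @export
run_pipeline <- function(config, overwrite = FALSE) {
  cfg <- load_run_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(cfg$output_dir, "config.yaml"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_lnm(paste0("pipeline stage '", name, "' failed: ",
                      conditionMessage(e)), "lnm_pipeline_error")
    })
  }
  # --- simulate ---
  cohort <- stage("simulate", {
    p <- do.call(synthetic_params, c(list(seed = cfg$seed), cfg$cohort))
    generate_cohort(p)
  })
  manifest <- stage("write", {
    write_cohort(cohort, file.path(cfg$output_dir, "cohort"),
                 overwrite = overwrite)
  })
  cohort <- derived_indices(cohort)
  # --- split ---
  split <- stage("split", split_cohort(cohort, seed = cfg$seed))
  split_df <- tibble::tibble(
    patient_id = c(split$train_ids, split$val_ids, split$test_ids),
    subset = rep(c("train", "val", "test"),
                 c(length(split$train_ids), length(split$val_ids),
                   length(split$test_ids))))
  write.csv(split_df, file.path(cfg$output_dir, "split.csv"),
            row.names = FALSE)
  # --- train ---
  enc_cfg <- do.call(encoder_config, c(cfg$encoder, list(seed = cfg$seed)))
  con_cfg <- do.call(contrastive_config, cfg$contrastive)
  tr_cfg <- do.call(train_config, c(cfg$train, list(seed = cfg$seed)))
  fit <- stage("train", {
    train_lnm(cohort, split, tr_cfg, enc_cfg, con_cfg,
              modalities = cfg$evaluation$modalities,
              use_contrastive = isTRUE(cfg$evaluation$contrastive))
  })
  log_path <- file.path(cfg$output_dir, "epochs.jsonl")
  writeLines(vapply(seq_len(nrow(fit$history)), function(i) {
    jsonlite::toJSON(as.list(fit$history[i, ]), auto_unbox = TRUE, digits = NA)
  }, character(1)), log_path)
  saveRDS(fit, file.path(cfg$output_dir, "checkpoint.rds"))
  # --- evaluate ---
  metrics <- stage("evaluate", evaluate_fit(fit, cohort))
  write.csv(metrics, file.path(cfg$output_dir, "metrics.csv"),
            row.names = FALSE)
  pr <- predict(fit, cohort)
  roc <- roc_auc(pr$score, pr$label)
  write.csv(roc$points, file.path(cfg$output_dir, "roc_points.csv"),
            row.names = FALSE)
  # --- baseline statistics ---
  if (isTRUE(cfg$evaluation$baseline_table)) {
    stats_tbl <- stage("stats", {
      d <- binarize_markers(cohort)
      d$figo_advanced <- d$figo_stage >= 3
      baseline_table(d, cat_vars = c("scc_elevated", "ca125_elevated",
                                     "ca19_9_elevated", "figo_advanced"))
    })
    write.csv(stats_tbl, file.path(cfg$output_dir, "baseline_table.csv"),
              row.names = FALSE)
  }
  invisible(list(dir = cfg$output_dir, fit = fit, metrics = metrics,
                 paths = list(manifest = manifest, log = log_path,
                              metrics = file.path(cfg$output_dir,
                                                  "metrics.csv"))))
}
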