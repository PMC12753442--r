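# Shared fixtures built in code. Cohorts are memoised per test run so several
# test files can reuse the same generated data without regenerating it.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 40 patients, 16 px images, strong tri-modal signal: enough for smoke runs
tiny_cohort <- function(seed = 3) {
  cached(paste0("tiny", seed), {
    derived_indices(generate_cohort(synthetic_params(
      seed = seed, n_patients = 40, n_positive = 8, image_size = 16,
      effect_ct = 3, effect_us = 3, effect_clin = 3)))
  })
}

tiny_enc_cfg <- function(side = 16) {
  encoder_config(image_input_side = side, backbone = "small",
                 crop_area_range = c(0.7, 1))
}

# unvectorized InfoNCE reference: double loop over anchors and candidates
info_nce_oracle <- function(za, zb, tau = 1, include_positive = FALSE) {
  n <- nrow(za)
  vapply(seq_len(n), function(i) {
    s_pos <- cosine_similarity(za[i, ], zb[i, ])
    js <- if (include_positive) seq_len(n) else setdiff(seq_len(n), i)
    den <- sum(vapply(js, function(j) {
      exp(cosine_similarity(za[i, ], zb[j, ]) / tau)
    }, numeric(1)))
    -log(exp(s_pos / tau) / den)
  }, numeric(1))
}

# pairwise concordance AUC with half-credit ties
auc_pairwise_oracle <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  g <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(g)
}

# mean-intensity linear probe: AUC of a fixed uniform-weight readout
probe_auc <- function(values, labels) roc_auc(values, labels)$auc
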