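test_that("uncorrected Pearson chi-square matches the reference cohort", {
  tabs <- example_lnm_tables()
  want <- c(scc_ag = 5.853, clinical_stage = 92.045,
            differentiation = 0.013, lymphovascular = 3.520,
            perineural = 0.341)
  for (nm in names(want)) {
    r <- pearson_chi_square(tabs[[nm]])
    expect_equal(round(r$statistic, 3), want[[nm]], info = nm)
    expect_equal(r$df, 1)
    expect_true(r$p_value >= 0 && r$p_value <= 1)
  }
  # significance calls match the published table
  expect_lt(pearson_chi_square(tabs$scc_ag)$p_value, 0.05)
  expect_lt(pearson_chi_square(tabs$clinical_stage)$p_value, 0.001)
  expect_gt(pearson_chi_square(tabs$perineural)$p_value, 0.05)
})

test_that("chi-square is zero under independence and permutation-invariant", {
  expect_equal(pearson_chi_square(matrix(10, 2, 2))$statistic, 0)
  withr::with_seed(1, {
    for (k in 1:10) {
      t0 <- matrix(rpois(4, 30) + 1, 2, 2)
      s0 <- pearson_chi_square(t0)$statistic
      expect_equal(pearson_chi_square(t0[2:1, ])$statistic, s0,
                   tolerance = 1e-12)
      expect_equal(pearson_chi_square(t0[, 2:1])$statistic, s0,
                   tolerance = 1e-12)
      expect_equal(pearson_chi_square(t(t0))$statistic, s0,
                   tolerance = 1e-12)
      # oracle: the standard uncorrected implementation
      want <- suppressWarnings(chisq.test(t0, correct = FALSE))
      expect_equal(s0, unname(want$statistic), tolerance = 1e-10)
      expect_equal(pearson_chi_square(t0)$p_value, want$p.value,
                   tolerance = 1e-10)
    }
  })
  expect_error(pearson_chi_square(matrix(c(0, 0, 3, 4), 2)),
               class = "lnm_domain_error")
})

test_that("Fisher exact p equals hypergeometric enumeration", {
  # hand enumeration for [[1,9],[9,1]]: margins r1 = 10, c1 = 10, n = 20
  probs <- dhyper(0:10, 10, 10, 10)
  p_obs <- dhyper(1, 10, 10, 10)
  want <- sum(probs[probs <= p_obs + 1e-12])
  got <- fisher_exact(matrix(c(1, 9, 9, 1), 2))
  expect_equal(got$p_value, want, tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(5, 2, 2))$p_value, 1)
  withr::with_seed(2, {
    for (k in 1:15) {
      tb <- matrix(rpois(4, 8), 2, 2)
      if (sum(tb) == 0 || any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
      expect_equal(fisher_exact(tb)$p_value,
                   fisher.test(tb)$p.value, tolerance = 1e-9)
    }
    # direction agreement with chi-square on large-count tables
    for (k in 1:10) {
      tb <- matrix(rpois(4, 80) + 20, 2, 2)
      pf <- fisher_exact(tb)$p_value
      pc <- pearson_chi_square(tb)$p_value
      expect_equal(pf < 0.01, pc < 0.01)
    }
  })
})

test_that("pooled t handles summaries and raw samples identically", {
  # identical groups -> t = 0
  expect_equal(pooled_t_test(mean1 = 5, sd1 = 1, n1 = 10,
                             mean2 = 5, sd2 = 1, n2 = 12)$statistic, 0)
  # the reference cohort's platelet summaries
  r <- pooled_t_test(mean1 = 244.3, sd1 = 48.3, n1 = 16,
                     mean2 = 245.0, sd2 = 65.5, n2 = 111)
  expect_equal(round(abs(r$statistic), 3), 0.041)
  expect_equal(r$df, 125)
  withr::with_seed(3, {
    for (k in 1:10) {
      x <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
      y <- rnorm(sample(5:30, 1))
      got <- pooled_t_test(x, y)
      want <- t.test(x, y, var.equal = TRUE)
      expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-10)
      expect_equal(got$p_value, want$p.value, tolerance = 1e-10)
      expect_equal(got$df, unname(want$parameter))
    }
  })
  expect_error(pooled_t_test(mean1 = 1, sd1 = 1, n1 = 1,
                             mean2 = 2, sd2 = 1, n2 = 5),
               class = "lnm_domain_error")
})

test_that("Mann-Whitney U matches brute-force pairwise counting", {
  withr::with_seed(4, {
    for (k in 1:20) {
      n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
      x <- sample(1:6, n1, replace = TRUE)  # ties on purpose
      y <- sample(1:6, n2, replace = TRUE)
      r <- mann_whitney_z(x, y)
      u_brute <- sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
      expect_equal(r$u1, u_brute, tolerance = 1e-12)
      expect_equal(r$u1 + r$u2, n1 * n2, tolerance = 1e-12)
      expect_true(r$p_value >= 0 && r$p_value <= 1)
      # swap symmetry of the two-sided p
      expect_equal(mann_whitney_z(y, x)$p_value, r$p_value,
                   tolerance = 1e-12)
    }
  })
  # identical samples -> z ~ 0, p ~ 1
  r0 <- mann_whitney_z(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)
  # complete separation -> extreme U
  rs <- mann_whitney_z(1:5, 6:10)
  expect_equal(rs$u1, 0)
  expect_equal(mann_whitney_z(6:10, 1:5)$u1, 25)
  expect_error(mann_whitney_z(numeric(0), 1:3), class = "lnm_domain_error")
  # continuous samples: p agrees with the standard normal-approximation test
  withr::with_seed(5, {
    x <- rnorm(25); y <- rnorm(30, 0.4)
    want <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_equal(mann_whitney_z(x, y)$p_value, want, tolerance = 1e-9)
  })
})

test_that("K-S normality routing is calibrated", {
  withr::with_seed(6, {
    normal_pass <- vapply(1:20, function(i) {
      ks_normality(rnorm(200, 50, 5))$p_value > 0.05
    }, logical(1))
    expect_gte(mean(normal_pass), 0.95)
    skew_reject <- vapply(1:20, function(i) {
      ks_normality(rexp(200))$p_value < 0.05
    }, logical(1))
    expect_gte(mean(skew_reject), 0.95)
  })
  expect_error(ks_normality(c(1, 2, 3)), class = "lnm_domain_error")
  expect_error(ks_normality(rep(2, 10)), class = "lnm_domain_error")
})

test_that("the baseline table reproduces the published proportions", {
  # node-positive group: 11 of 16 elevated; negative: 41 of 111
  d <- data.frame(
    scc_ag = c(rep(2.5, 11), rep(1.0, 5), rep(2.5, 41), rep(1.0, 70)),
    ca125 = 10, ca19_9 = 10,
    label = rep(c(1, 0), c(16, 111)))
  d <- binarize_markers(d)
  tab <- baseline_table(d, cont_vars = character(0),
                        cat_vars = "scc_elevated")
  expect_equal(attr(tab, "group_n"), c(pos = 16, neg = 111))
  row <- tab[tab$level == "TRUE", ]
  expect_equal(row$summary_pos, "11 (68.8%)")
  expect_equal(row$summary_neg, "41 (36.9%)")
  expect_equal(round(row$statistic, 3), 5.853)
  expect_equal(row$symbol, "x2")
})

test_that("baseline table routes variables by normality", {
  withr::with_seed(7, {
    d <- data.frame(
      gauss = rnorm(160, 50, 5),
      skewed = rexp(160, 0.1),
      flag = rbinom(160, 1, 0.4) == 1,
      label = rep(c(1, 0), c(40, 120)))
    tab <- baseline_table(d, cont_vars = c("gauss", "skewed"),
                          cat_vars = "flag")
    expect_equal(tab$symbol[tab$variable == "gauss"], "t")
    expect_equal(tab$symbol[tab$variable == "skewed"], "z")
    expect_true(all(tab$symbol[tab$variable == "flag"] == "x2"))
    expect_true(grepl("±", tab$summary_pos[tab$variable == "gauss"]))
    expect_true(grepl("\\(", tab$summary_pos[tab$variable == "skewed"]))
    expect_warning(baseline_table(d, cont_vars = c("gauss", "nope"),
                                  cat_vars = "flag"), "nope")
    # Fisher routing option
    tf <- baseline_table(d, cont_vars = character(0), cat_vars = "flag",
                         categorical_test = "fisher")
    expect_true(all(grepl("Fisher", tf$method)))
  })
  expect_error(baseline_table(data.frame(x = 1), group = "label"),
               class = "lnm_missing_field")
  expect_error(baseline_table(data.frame(x = 1:4, label = rep(1, 4)),
                              cont_vars = "x", cat_vars = character(0)),
               class = "lnm_domain_error")
})

test_that("baseline-table p-values are well behaved under the null", {
  withr::with_seed(8, {
    ps <- unlist(lapply(1:15, function(s) {
      co <- derived_indices(generate_cohort(synthetic_params(
        seed = 200 + s, n_patients = 80, n_positive = 20, image_size = 8,
        effect_ct = 0, effect_us = 0, effect_clin = 0)))
      co <- binarize_markers(co)
      tab <- baseline_table(co, cont_vars = c("age", "platelets", "albumin"),
                            cat_vars = "scc_elevated")
      unique(tab$p_value)
    }))
    expect_true(all(ps >= 0 & ps <= 1))
    # roughly uniform: about 5% should fall below 0.05
    expect_lt(mean(ps < 0.05), 0.2)
  })
})
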