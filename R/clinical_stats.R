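# Baseline-characteristics statistics: Pearson chi-square (no continuity
# correction), Fisher's exact test, pooled two-sample t, Mann-Whitney U with
# a normal-approximation z (tie-corrected, continuity-corrected), K-S
# normality routing, and the formatted baseline table.

test_result <- function(method, statistic, symbol, p_value, df = NA_real_,
                        ...) {
  tibble::tibble(method = method, statistic = statistic, symbol = symbol,
                 p_value = p_value, df = df, ...)
}

#' Pearson chi-square test on a contingency table
#'
#' The uncorrected Pearson statistic `sum((O - E)^2 / E)` with expected
#' counts from the row/column marginals. No Yates continuity correction is
#' applied, matching the convention of clinical baseline tables that report
#' the raw statistic; use [fisher_exact()] when expected counts are small.
#'
#' @param table a matrix of non-negative counts (rows = category levels,
#'   columns = groups).
#' @return A one-row tibble: method, statistic, symbol ("x2"), p_value, df.
#' @export
#' @examples
#' pearson_chi_square(matrix(c(5, 11, 70, 41), 2))
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || sum(table) == 0) {
    stop_lnm("table must hold non-negative counts with a positive total",
             "lnm_domain_error")
  }
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    stop_lnm("degenerate table: zero row or column marginal",
             "lnm_domain_error")
  }
  E <- outer(rs, cs) / sum(table)
  stat <- sum((table - E)^2 / E)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  test_result("Pearson chi-square (uncorrected)", stat, "x2",
              pchisq(stat, df, lower.tail = FALSE), df = df)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by hypergeometric enumeration: the sum of the probabilities
#' of all tables (same marginals) no more probable than the observed one.
#'
#' @param table a 2x2 matrix of non-negative counts.
#' @return A one-row tibble (statistic is the observed top-left count).
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0) || sum(table) == 0) {
    stop_lnm("table must hold non-negative counts with a positive total",
             "lnm_domain_error")
  }
  a <- table[1, 1]
  r1 <- sum(table[1, ]); c1 <- sum(table[, 1]); n <- sum(table)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  support <- lo:hi
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  test_result("Fisher exact (two-sided)", a, "a", min(p, 1))
}

#' Pooled-variance two-sample t test
#'
#' Works from raw samples (`x`, `y`) or from group summaries
#' (`mean1, sd1, n1, mean2, sd2, n2`). The statistic uses the pooled
#' variance with `n1 + n2 - 2` degrees of freedom.
#'
#' @param x,y optional raw samples.
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries (used when `x` is NULL).
#' @return A one-row tibble: statistic t, df, two-sided p.
#' @export
#' @examples
#' pooled_t_test(mean1 = 244.3, sd1 = 48.3, n1 = 16,
#'               mean2 = 245.0, sd2 = 65.5, n2 = 111)
pooled_t_test <- function(x = NULL, y = NULL, mean1 = NULL, sd1 = NULL,
                          n1 = NULL, mean2 = NULL, sd2 = NULL, n2 = NULL) {
  if (!is.null(x)) {
    stopifnot(!is.null(y))
    mean1 <- mean(x); sd1 <- sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- sd(y); n2 <- length(y)
  }
  if (n1 < 2 || n2 < 2) {
    stop_lnm("each group needs at least 2 observations", "lnm_domain_error")
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t_stat <- if (se == 0) 0 else (mean1 - mean2) / se
  test_result("pooled two-sample t", t_stat, "t",
              2 * pt(-abs(t_stat), df), df = df)
}

#' Mann-Whitney U test with normal-approximation z
#'
#' U counts pairwise wins of the first sample (ties half-credited). The z
#' statistic uses the tie-corrected variance and a 0.5 continuity correction
#' toward zero; its sign follows `U - n1*n2/2`, so a first sample tending to
#' smaller values gives negative z.
#'
#' @param x,y numeric samples.
#' @return A one-row tibble with z, two-sided p, and columns `u1`, `u2`
#'   (`u1 + u2 = n1*n2`).
#' @export
mann_whitney_z <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop_lnm("both samples must be non-empty", "lnm_domain_error")
  }
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  r1 <- sum(r[seq_len(n1)])
  u1 <- r1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) {
    z <- 0; p <- 1
  } else {
    d <- u1 - mu
    d <- sign(d) * max(abs(d) - 0.5, 0)  # continuity correction toward 0
    z <- d / sqrt(sigma2)
    p <- min(2 * pnorm(-abs(z)), 1)
  }
  test_result("Mann-Whitney U (normal approximation)", z, "z", p,
              u1 = u1, u2 = n1 * n2 - u1)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample K-S statistic against a normal with the sample mean and
#' standard deviation (parameters estimated from the same data, the common
#' software dialect). Used to route continuous variables between mean+/-SD
#' with t test and median (P25, P75) with Mann-Whitney.
#'
#' @param x numeric sample, n >= 5.
#' @return A one-row tibble with statistic D and p.
#' @export
ks_normality <- function(x) {
  if (length(x) < 5) {
    stop_lnm("normality check needs at least 5 observations",
             "lnm_domain_error")
  }
  if (sd(x) == 0) {
    stop_lnm("constant sample: normality check undefined", "lnm_domain_error")
  }
  k <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  test_result("Kolmogorov-Smirnov (normal, estimated parameters)",
              unname(k$statistic), "D", k$p.value)
}

fmt_pct <- function(count, total) {
  sprintf("%.1f%%", round_half_up(1000 * count / total) / 10)
}

fmt_num <- function(x) sprintf("%.1f", round_half_up(10 * x) / 10)

#' Baseline-characteristics table
#'
#' Continuous variables are routed by [ks_normality()] (both groups
#' non-rejecting at `alpha`): normal ones are summarized mean +/- SD and
#' compared by the pooled t test, the rest as median (P25, P75) with the
#' Mann-Whitney z. Categorical variables are summarized as count (percent
#' within group) and compared by the uncorrected Pearson chi-square
#' (`categorical_test = "fisher"` switches to the exact test).
#'
#' @param data data frame with a binary grouping column plus the variables.
#' @param group name of the grouping column (1 = positive group).
#' @param cont_vars continuous variable names.
#' @param cat_vars categorical (logical/factor) variable names.
#' @param alpha normality-routing significance level.
#' @param categorical_test "chisq" (default) or "fisher".
#' @return A tibble with one row per variable (or per categorical level):
#'   `variable`, `level`, `summary_pos`, `summary_neg`, `method`, `symbol`,
#'   `statistic`, `p_value`. Group sizes are in the `"group_n"` attribute.
#' @export
baseline_table <- function(data, group = "label",
                           cont_vars = c("age", "platelets", "albumin",
                                         "nlr", "plr", "sii", "pni"),
                           cat_vars = c("scc_elevated", "ca125_elevated",
                                        "ca19_9_elevated"),
                           alpha = 0.05,
                           categorical_test = c("chisq", "fisher")) {
  categorical_test <- match.arg(categorical_test)
  if (!group %in% names(data)) {
    stop_lnm(paste0("grouping column '", group, "' not found"),
             "lnm_missing_field")
  }
  g <- data[[group]]
  if (!all(g %in% c(0, 1)) || length(unique(g)) != 2) {
    stop_lnm("grouping column must be binary with both groups present",
             "lnm_domain_error")
  }
  pos <- data[g == 1, , drop = FALSE]
  neg <- data[g == 0, , drop = FALSE]
  rows <- list()
  for (v in cont_vars) {
    if (!v %in% names(data)) {
      warning("skipping missing variable: ", v)
      next
    }
    xp <- pos[[v]]; xn <- neg[[v]]
    normal <- ks_normality(xp)$p_value > alpha &&
      ks_normality(xn)$p_value > alpha
    if (normal) {
      tt <- pooled_t_test(xp, xn)
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = v, level = NA_character_,
        summary_pos = paste0(fmt_num(mean(xp)), " ± ", fmt_num(sd(xp))),
        summary_neg = paste0(fmt_num(mean(xn)), " ± ", fmt_num(sd(xn))),
        method = tt$method, symbol = tt$symbol, statistic = tt$statistic,
        p_value = tt$p_value)
    } else {
      mw <- mann_whitney_z(xp, xn)
      q <- function(x) {
        qq <- quantile(x, c(0.5, 0.25, 0.75), names = FALSE)
        paste0(fmt_num(qq[1]), " (", fmt_num(qq[2]), ",", fmt_num(qq[3]), ")")
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = v, level = NA_character_,
        summary_pos = q(xp), summary_neg = q(xn),
        method = mw$method, symbol = mw$symbol, statistic = mw$statistic,
        p_value = mw$p_value)
    }
  }
  for (v in cat_vars) {
    if (!v %in% names(data)) {
      warning("skipping missing variable: ", v)
      next
    }
    f <- factor(data[[v]])
    tab <- table(f, factor(g, levels = c(1, 0)))
    tst <- if (categorical_test == "fisher" && all(dim(tab) == c(2, 2))) {
      fisher_exact(tab)
    } else {
      pearson_chi_square(tab)
    }
    for (lv in levels(f)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = v, level = lv,
        summary_pos = paste0(tab[lv, 1], " (", fmt_pct(tab[lv, 1], nrow(pos)),
                             ")"),
        summary_neg = paste0(tab[lv, 2], " (", fmt_pct(tab[lv, 2], nrow(neg)),
                             ")"),
        method = tst$method, symbol = tst$symbol, statistic = tst$statistic,
        p_value = tst$p_value)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "group_n") <- c(pos = nrow(pos), neg = nrow(neg))
  out
}

#' Reference contingency tables from a published cervical-cancer cohort
#'
#' 2x2 counts (rows = category levels, columns = node-positive /
#' node-negative, group sizes 16 / 111) from a published 127-patient
#' cervical-cancer cohort's baseline table. Used in examples and validation
#' tests of the uncorrected Pearson chi-square.
#'
#' @return A named list of 2x2 count matrices.
#' @export
#' @examples
#' pearson_chi_square(example_lnm_tables()$scc_ag)
example_lnm_tables <- function() {
  mk <- function(a, b, c, d, levels) {
    matrix(c(a, c, b, d), 2, 2,
           dimnames = list(levels, c("LN+", "LN-")))
  }
  list(
    scc_ag = mk(5, 70, 11, 41, c("normal", "elevated")),
    clinical_stage = mk(3, 110, 13, 1, c("FIGO I-II", "FIGO III-IV")),
    differentiation = mk(10, 71, 6, 40, c("well/moderate", "poor")),
    lymphovascular = mk(8, 81, 8, 30, c("positive", "negative")),
    perineural = mk(14, 102, 2, 9, c("positive", "negative"))
  )
}
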