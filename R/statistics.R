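# one-row StatResult tibble shared by every test in the battery
stat_result <- function(statistic, kind, p_value, df = NA_real_,
                        method = NA_character_, estimate = NA_real_,
                        alpha = 0.05) {
  tibble::tibble(
    statistic = as.numeric(statistic),
    statistic_kind = kind,
    p_value = as.numeric(p_value),
    df = as.numeric(df),
    estimate = as.numeric(estimate),
    method = method,
    significant = p_value < alpha
  )
}

#' Insulin-resistance index (HOMA-IR)
#'
#' Homeostasis model assessment of insulin resistance:
#' `HOMA-IR = FINS (uIU/mL) x FBG (mmol/L) / 22.5`.
#'
#' @param fins Fasting insulin in uIU/mL (non-negative).
#' @param fbg Fasting blood glucose in mmol/L (non-negative).
#' @return The unitless index (vectorised).
#' @examples
#' homa_ir(22.5, 1)  # 1
#' homa_ir(9, 5)     # 2
#' @export
homa_ir <- function(fins, fbg) {
  if (any(fins < 0) || any(fbg < 0)) {
    abort("FINS and FBG must be non-negative", class = "morphnet_stat_error")
  }
  fins * fbg / 22.5
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square with
#' df = 1, as used for categorical group comparisons such as sex ratios.
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @param alpha Significance level for the `significant` flag.
#' @return A one-row StatResult tibble.
#' @examples
#' chi_square_2x2(matrix(c(88, 62, 70, 60), 2, byrow = TRUE))
#' @export
chi_square_2x2 <- function(table, alpha = 0.05) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0)) {
    abort("need a 2x2 table of non-negative counts",
          class = "morphnet_stat_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("all table margins must be positive", class = "morphnet_stat_error")
  }
  # small expected counts only degrade the asymptotic p, which is still the
  # conventional report for this statistic; silence stats's reminder
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  stat_result(ct$statistic, "chi2", ct$p.value, df = 1,
              method = "pearson chi-square (uncorrected)", alpha = alpha)
}

#' Pooled two-sample t-test from summary statistics
#'
#' Student (pooled-variance) two-sample t from group means, standard
#' deviations and sizes — usable directly on a published summary table.
#' The statistic is reported as `|t|`-signed by `m2 - m1`.
#'
#' @param m1,sd1,n1 Mean, SD and size of group 1.
#' @param m2,sd2,n2 Mean, SD and size of group 2.
#' @param alpha Significance level.
#' @return A one-row StatResult tibble (`df = n1 + n2 - 2`).
#' @examples
#' two_sample_t_from_summary(50.54, 8.70, 150, 51.02, 9.13, 130)
#' @export
two_sample_t_from_summary <- function(m1, sd1, n1, m2, sd2, n2,
                                      alpha = 0.05) {
  if (sd1 <= 0 || sd2 <= 0 || n1 < 2 || n2 < 2) {
    abort("need positive SDs and group sizes >= 2",
          class = "morphnet_stat_error")
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t_stat <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  stat_result(t_stat, "t", 2 * pt(-abs(t_stat), df), df = df,
              method = "pooled two-sample t (from summaries)",
              estimate = m2 - m1, alpha = alpha)
}

#' Normality-gated two-group comparison
#'
#' Runs a Shapiro-Wilk normality test on each group at level
#' `normality_alpha`; if both pass, a pooled-variance Student t-test is
#' used, otherwise a Mann-Whitney (Wilcoxon rank-sum) test whose statistic
#' is reported as a tie-corrected normal-approximation Z (no continuity
#' correction). The `method` column records which branch ran.
#'
#' @param values Numeric outcome, one per subject.
#' @param group Group labels (exactly two levels).
#' @param alpha Significance level for the comparison.
#' @param normality_alpha Level of the Shapiro-Wilk gate (default 0.05).
#' @return A one-row StatResult tibble; `statistic_kind` is `"t"` or `"Z"`.
#' @export
compare_groups <- function(values, group, alpha = 0.05,
                           normality_alpha = 0.05) {
  group <- as.character(group)
  levels <- unique(group)
  if (length(levels) != 2L) {
    abort("group must have exactly two levels", class = "morphnet_stat_error")
  }
  x <- values[group == levels[1]]
  y <- values[group == levels[2]]
  if (length(x) < 3 || length(y) < 3) {
    abort("need at least 3 subjects per group", class = "morphnet_stat_error")
  }
  if (sd(x) == 0 && sd(y) == 0) {
    abort("both groups are constant: comparison is degenerate",
          class = "morphnet_stat_error")
  }
  normal <- sd(x) > 0 && sd(y) > 0 &&
    shapiro.test(x)$p.value >= normality_alpha &&
    shapiro.test(y)$p.value >= normality_alpha
  if (normal) {
    tt <- t.test(x, y, var.equal = TRUE)
    return(stat_result(tt$statistic, "t", tt$p.value, df = tt$parameter,
                       method = "student t (shapiro-wilk passed)",
                       estimate = mean(x) - mean(y), alpha = alpha))
  }
  # Mann-Whitney U with tie-corrected normal approximation, no continuity
  # correction (matches Z statistics reported in clinical tables)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term))
  z <- (u - mu) / sigma
  stat_result(z, "Z", 2 * pnorm(-abs(z)),
              method = "mann-whitney U, normal approximation (shapiro-wilk failed)",
              estimate = median(x) - median(y), alpha = alpha)
}

#' Covariate-adjusted group test by linear model
#'
#' Least-squares fit of `y` on an intercept, a group indicator and the named
#' covariates; the reported statistic is the t of the group coefficient.
#' With no covariates this is exactly the pooled two-sample t (up to sign
#' convention). The design matrix must be full rank — perfect collinearity
#' (e.g. a covariate duplicating the group indicator) is an explicit error
#' naming the offending columns.
#'
#' @param y Numeric outcome, one per subject (same order as `cohort` rows).
#' @param group Two-level group labels; the indicator is 1 for the first
#'   level encountered.
#' @param covariates Character vector of covariate column names (subset of
#'   `names(cohort)`), possibly empty.
#' @param cohort Data frame holding the covariate columns.
#' @param alpha Significance level.
#' @return A one-row StatResult tibble with the group-coefficient `estimate`.
#' @export
glm_group_test <- function(y, group, covariates = character(), cohort = NULL,
                           alpha = 0.05) {
  group <- as.character(group)
  levels <- unique(group)
  if (length(levels) != 2L) {
    abort("group must have exactly two levels", class = "morphnet_stat_error")
  }
  if (anyDuplicated(covariates)) {
    abort("duplicate covariate names", class = "morphnet_stat_error")
  }
  g <- as.numeric(group == levels[1])
  X <- cbind(`(intercept)` = 1, group = g)
  if (length(covariates)) {
    missing_cov <- setdiff(covariates, names(cohort))
    if (length(missing_cov)) {
      abort(paste("covariates absent from cohort table:",
                  paste(missing_cov, collapse = ", ")),
            class = "morphnet_stat_error")
    }
    cov_df <- cohort[covariates]
    # code non-numeric covariates (e.g. sex) as treatment indicators
    cov_mat <- do.call(cbind, lapply(covariates, function(nm) {
      v <- cov_df[[nm]]
      if (is.numeric(v)) matrix(v, dimnames = list(NULL, nm))
      else matrix(as.numeric(factor(v)) - 1, dimnames = list(NULL, nm))
    }))
    X <- cbind(X, cov_mat)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort(paste("design matrix is rank deficient; collinear column(s):",
                paste(dropped, collapse = ", ")),
          class = "morphnet_rank_error")
  }
  fit <- lm.fit(X, y)
  df <- length(y) - ncol(X)
  rss <- sum(fit$residuals^2)
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(rss / df * xtx_inv[2, 2])
  t_stat <- fit$coefficients["group"] / se
  stat_result(t_stat, "t", 2 * pt(-abs(t_stat), df), df = df,
              method = paste0("glm group test (", levels[1], " - ",
                              levels[2], ")",
                              if (length(covariates))
                                paste0(", covariates: ",
                                       paste(covariates, collapse = "+"))
                              else ""),
              estimate = unname(fit$coefficients["group"]), alpha = alpha)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up BH adjustment; rejections at level `q` are exactly the tests with
#' adjusted p `<= q`, and adjusted values are a monotone non-decreasing
#' transform of the raw p-values.
#'
#' @param p_values Raw p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `adjusted_p` and logical `reject`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)$reject  # all TRUE
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1 | is.na(p_values))) {
    abort("p-values must lie in [0, 1]", class = "morphnet_stat_error")
  }
  adjusted <- p.adjust(p_values, method = "BH")
  list(adjusted_p = adjusted, reject = adjusted <= q)
}

#' Covariate-adjusted (partial) Pearson correlation
#'
#' Pearson correlation between the residuals of `x` and `y` after each is
#' regressed on an intercept plus the named covariates; with an empty
#' covariate set this is the plain Pearson correlation. The p-value uses
#' `t = r sqrt((n - 2 - k) / (1 - r^2))` with `k` covariates.
#'
#' @param x,y Numeric vectors, one value per subject.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @param cohort Data frame holding the covariate columns (same row order).
#' @param alpha Significance level.
#' @return A one-row StatResult tibble with `statistic_kind = "r"`; the
#'   correlation is in `estimate` and `statistic` both.
#' @export
partial_correlation <- function(x, y, covariates = character(),
                                cohort = NULL, alpha = 0.05) {
  n <- length(x)
  k <- length(covariates)
  if (length(y) != n) {
    abort("x and y must have the same length", class = "morphnet_stat_error")
  }
  if (n <= k + 2) {
    abort("need n > k + 2 observations", class = "morphnet_stat_error")
  }
  if (k) {
    missing_cov <- setdiff(covariates, names(cohort))
    if (length(missing_cov)) {
      abort(paste("covariates absent from cohort table:",
                  paste(missing_cov, collapse = ", ")),
            class = "morphnet_stat_error")
    }
    Z <- do.call(cbind, lapply(covariates, function(nm) {
      v <- cohort[[nm]]
      if (is.numeric(v)) v else as.numeric(factor(v)) - 1
    }))
    Z <- cbind(1, Z)
    x <- qr.resid(qr(Z), x)
    y <- qr.resid(qr(Z), y)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("constant residuals: correlation undefined",
          class = "morphnet_stat_error")
  }
  r <- cor(x, y)
  df <- n - 2 - k
  t_stat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  stat_result(r, "r", 2 * pt(-abs(t_stat), df), df = df,
              method = if (k) paste("partial pearson |",
                                    paste(covariates, collapse = "+"))
                       else "pearson",
              estimate = r, alpha = alpha)
}

#' Region-wise group analysis of nodal AUCs with FDR correction
#'
#' For each nodal metric, fits the covariate-adjusted group model
#' ([glm_group_test()]) region by region, then applies Benjamini-Hochberg
#' FDR across the regions *within that metric's family*. Survivors are the
#' regions with adjusted p at or below `q`; the sign of `estimate` gives the
#' direction of the group difference.
#'
#' @param nodal_auc Tibble with columns `subject_id`, `group`, `region` and
#'   one column per nodal metric (as produced by [cohort_network_aucs()]).
#' @param covariates Character vector of covariate names found in `cohort`.
#' @param cohort Per-subject table with `subject_id` and the covariates.
#' @param metrics Which metric columns to analyse.
#' @param q FDR level.
#' @param alpha Raw significance level recorded per test.
#' @return Tibble with one row per metric x region: test output plus
#'   `adjusted_p` and `survivor`.
#' @export
nodal_group_analysis <- function(nodal_auc, covariates = character(),
                                 cohort = NULL,
                                 metrics = c("ne", "dc", "nle", "bc"),
                                 q = 0.05, alpha = 0.05) {
  metrics <- intersect(metrics, names(nodal_auc))
  if (!length(metrics)) {
    abort("no requested metric columns found in nodal_auc",
          class = "morphnet_stat_error")
  }
  if (!all(c("subject_id", "group", "region") %in% names(nodal_auc))) {
    abort("nodal_auc needs subject_id, group and region columns",
          class = "morphnet_stat_error")
  }
  if (length(covariates)) {
    nodal_auc <- dplyr::left_join(
      nodal_auc, dplyr::select(cohort, "subject_id",
                               dplyr::all_of(covariates)),
      by = "subject_id"
    )
  }
  purrr::map_dfr(metrics, function(metric) {
    per_region <- nodal_auc |>
      dplyr::group_by(.data$region) |>
      dplyr::group_modify(function(d, key) {
        glm_group_test(d[[metric]], d$group, covariates = covariates,
                       cohort = d, alpha = alpha)
      }) |>
      dplyr::ungroup()
    fdr <- bh_fdr(per_region$p_value, q = q)
    per_region |>
      dplyr::mutate(metric = metric, adjusted_p = fdr$adjusted_p,
                    survivor = fdr$reject, .before = 1) |>
      dplyr::relocate("region", .before = "metric")
  })
}

#' Group comparison table for the clinical panels
#'
#' Applies [compare_groups()] to every numeric column of a per-subject
#' panel (and [chi_square_2x2()] to `sex` if present), yielding a
#' demographics-style comparison table.
#'
#' @param panel Tibble with `subject_id`, `group` and variable columns.
#' @param alpha Significance level.
#' @return Tibble with one row per variable.
#' @export
compare_panel <- function(panel, alpha = 0.05) {
  vars <- setdiff(names(panel), c("subject_id", "group"))
  purrr::map_dfr(vars, function(v) {
    col <- panel[[v]]
    res <- if (is.numeric(col)) {
      compare_groups(col, panel$group, alpha = alpha)
    } else {
      tab <- table(panel$group, col)
      chi_square_2x2(as.matrix(tab), alpha = alpha)
    }
    dplyr::mutate(res, variable = v, .before = 1)
  })
}
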