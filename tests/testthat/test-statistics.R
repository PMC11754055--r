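test_that("HOMA-IR follows the clinical formula", {
  expect_equal(homa_ir(22.5, 1.0), 1.0)
  expect_equal(homa_ir(0, 5.0), 0.0)
  expect_equal(homa_ir(9.0, 5.0), 2.0)
  expect_equal(homa_ir(c(9, 22.5), c(5, 1)), c(2, 1))
  expect_error(homa_ir(-1, 5), class = "morphnet_stat_error")
})

test_that("2x2 chi-square matches hand computation and handles margins", {
  # observed = expected -> 0
  expect_equal(chi_square_2x2(matrix(50, 2, 2))$statistic, 0)
  # expected 5 everywhere: 4 cells x 25/5 = 20
  r <- chi_square_2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r$statistic, 20.0)
  expect_equal(r$df, 1)
  expect_error(chi_square_2x2(matrix(c(5, 5, 0, 0), 2, byrow = TRUE)),
               class = "morphnet_stat_error")
  expect_error(chi_square_2x2(matrix(1, 3, 3)),
               class = "morphnet_stat_error")
})

test_that("summary-statistic t test matches its closed form", {
  r <- two_sample_t_from_summary(0, 1, 100, 1, 1, 100)
  expect_equal(r$statistic, 1 / sqrt(2 / 100), tolerance = 1e-12)
  expect_equal(r$df, 198)
  expect_equal(two_sample_t_from_summary(5, 2, 30, 5, 2, 30)$statistic, 0)
  expect_error(two_sample_t_from_summary(0, 0, 10, 1, 1, 10),
               class = "morphnet_stat_error")
})

test_that("compare_groups gates on Shapiro-Wilk and picks the right branch", {
  set.seed(31)
  g <- rep(c("a", "b"), each = 100)
  r_norm <- compare_groups(rnorm(200), g)
  expect_equal(r_norm$statistic_kind, "t")
  # exponential data fail normality at n = 100 essentially always
  r_skew <- compare_groups(rexp(200), g)
  expect_equal(r_skew$statistic_kind, "Z")
  # a huge shift is detected under either branch
  x <- c(rnorm(100), rnorm(100) + 50)
  expect_lt(compare_groups(x, g)$p_value, 1e-6)
  expect_error(compare_groups(rep(1, 20), rep(c("a", "b"), 10)),
               class = "morphnet_stat_error")
  expect_error(compare_groups(rnorm(4), rep(c("a", "b"), 2)),
               class = "morphnet_stat_error")
})

test_that("compare_groups null p-values are uniform (both branches)", {
  set.seed(77)
  g <- rep(c("a", "b"), each = 60)
  res <- purrr::map_dfr(1:400, function(i) compare_groups(rnorm(120), g))
  # the rare replicates where the normality gate trips use the rank test,
  # whose discrete p-values would spuriously break the KS uniformity check
  p_t <- res$p_value[res$statistic_kind == "t"]
  expect_gt(length(p_t), 300)
  expect_gt(stats::ks.test(p_t, "punif")$p.value, 0.01)
  p_t <- res$p_value
  rate <- mean(p_t < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)
  p_z <- replicate(400, compare_groups(rexp(120), g)$p_value)
  rate_z <- mean(p_z < 0.05)
  expect_gte(rate_z, 0.02)
  expect_lte(rate_z, 0.08)
})

test_that("the covariate-adjusted group test nests the pooled t", {
  set.seed(41)
  y <- rnorm(80)
  g <- rep(c("patient", "control"), each = 40)
  plain <- glm_group_test(y, g)
  pooled <- t.test(y[g == "patient"], y[g == "control"],
                   var.equal = TRUE)
  expect_equal(plain$statistic, unname(pooled$statistic), tolerance = 1e-12)
  expect_equal(plain$p_value, pooled$p.value, tolerance = 1e-12)
})

test_that("orthogonal covariates leave the group coefficient unchanged", {
  set.seed(43)
  n <- 60
  g <- rep(c("patient", "control"), each = n / 2)
  g_ind <- as.numeric(g == "patient")
  z_raw <- rnorm(n)
  # orthogonalise z against [1, group] by construction
  z <- qr.resid(qr(cbind(1, g_ind)), z_raw)
  y_raw <- rnorm(n)
  y <- qr.resid(qr(cbind(1, z)), y_raw)  # y orthogonal to z too
  cohort <- tibble::tibble(z = z)
  with_cov <- glm_group_test(y, g, covariates = "z", cohort = cohort)
  without <- glm_group_test(y, g)
  expect_equal(with_cov$estimate, without$estimate, tolerance = 1e-9)
})

test_that("perfect collinearity is reported with the offending column", {
  y <- rnorm(40)
  g <- rep(c("patient", "control"), each = 20)
  cohort <- tibble::tibble(dup = as.numeric(g == "patient"))
  expect_error(glm_group_test(y, g, covariates = "dup", cohort = cohort),
               class = "morphnet_rank_error")
  expect_error(glm_group_test(y, g, covariates = c("a", "a"),
                              cohort = tibble::tibble(a = rnorm(40))),
               class = "morphnet_stat_error")
})

test_that("BH correction reproduces the step-up rule", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$reject))
  r1 <- bh_fdr(rep(1, 5))
  expect_false(any(r1$reject))
  expect_equal(r1$adjusted_p, rep(1, 5))
  r2 <- bh_fdr(0.03, q = 0.05)
  expect_true(r2$reject)
  expect_equal(r2$adjusted_p, 0.03)
  expect_error(bh_fdr(c(0.5, 1.2)), class = "morphnet_stat_error")
  # monotone transform of raw p, and adjusted >= raw
  set.seed(51)
  p <- runif(50)
  adj <- bh_fdr(p)$adjusted_p
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("partial correlation reduces to Pearson and removes confounds", {
  set.seed(61)
  x <- rnorm(50)
  y <- 0.5 * x + rnorm(50)
  plain <- partial_correlation(x, y)
  expect_equal(plain$statistic, cor(x, y), tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(plain$p_value, ct$p.value, tolerance = 1e-10)
  expect_equal(partial_correlation(x, x)$statistic, 1.0)
  # a covariate orthogonal to both variables barely changes r
  z <- qr.resid(qr(cbind(1, x, y)), rnorm(50))
  adj <- partial_correlation(x, y, covariates = "z",
                             cohort = tibble::tibble(z = z))
  expect_equal(adj$statistic, plain$statistic, tolerance = 1e-9)
  expect_error(partial_correlation(rnorm(4), rnorm(4),
                                   covariates = c("a", "b", "c"),
                                   cohort = tibble::tibble(a = rnorm(4),
                                                           b = rnorm(4),
                                                           c = rnorm(4))),
               class = "morphnet_stat_error")
})

test_that("shared confounds are removed in most simulated draws", {
  set.seed(71)
  n <- 150
  hits <- replicate(200, {
    z <- rnorm(n)
    x <- z + rnorm(n)
    y <- z + rnorm(n)
    r <- partial_correlation(x, y, covariates = "z",
                             cohort = tibble::tibble(z = z))
    abs(r$statistic) < 0.1
  })
  expect_gte(mean(hits), 0.70)  # |r| < 0.1 in the large majority of draws
})

test_that("nodal analysis applies FDR per metric family", {
  set.seed(81)
  n_sub <- 30
  regions <- paste0("R", 1:4)
  groups <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:n_sub),
    group = rep(c("patient", "control"), each = n_sub / 2)
  )
  tbl <- tidyr::expand_grid(subject_id = groups$subject_id,
                            region = regions)
  tbl <- dplyr::left_join(tbl, groups, by = "subject_id")
  tbl$ne <- rnorm(nrow(tbl))
  # inject a large effect in region R2 only
  tbl$ne[tbl$region == "R2" & tbl$group == "patient"] <-
    tbl$ne[tbl$region == "R2" & tbl$group == "patient"] + 3
  res <- nodal_group_analysis(tbl, metrics = "ne")
  expect_equal(nrow(res), 4L)
  expect_true(res$survivor[res$region == "R2"])
  expect_equal(res$adjusted_p, bh_fdr(res$p_value)$adjusted_p)
  # single-region table: FDR reduces to the raw comparison
  single <- dplyr::filter(tbl, region == "R1")
  res1 <- nodal_group_analysis(single, metrics = "ne")
  expect_equal(res1$adjusted_p, res1$p_value)
})

test_that("panel comparison covers numeric and categorical variables", {
  coh <- generate_cohort(small_cohort_config(seed = 19, n = 40L,
                                             n_regions = 2L,
                                             voxels = c(2L, 3L)))
  res <- compare_panel(coh$covariates)
  expect_setequal(res$variable, c("age", "sex", "education", "tiv"))
  expect_equal(res$statistic_kind[res$variable == "sex"], "chi2")
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})
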