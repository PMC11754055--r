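test_that("identical configurations generate bit-identical cohorts", {
  cfg <- small_cohort_config(seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$voxels, b$voxels)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$cognitive, b$cognitive)
  # a different seed changes the data
  c <- generate_cohort(small_cohort_config(seed = 8))
  expect_false(identical(a$voxels$value, c$voxels$value))
})

test_that("generated cohorts satisfy the voxel-table contract", {
  cfg <- small_cohort_config(seed = 3, n = 5L, n_regions = 9L)
  coh <- generate_cohort(cfg)
  expect_silent(validate_voxel_table(coh$voxels, n_regions = 9L))
  expect_true(all(coh$voxels$value >= 0))
  counts <- dplyr::count(coh$voxels, subject_id, region_id)
  expect_true(all(counts$n >= 2))
  expect_equal(length(unique(coh$voxels$subject_id)), 10L)
  # every subject sees all regions with identical voxel counts (fixed anatomy)
  per_region <- tidyr::pivot_wider(counts, names_from = region_id,
                                   values_from = n)
  expect_equal(nrow(dplyr::distinct(per_region[-1])), 1L)
})

test_that("clinical panel obeys the HOMA-IR formula exactly", {
  coh <- generate_cohort(small_cohort_config(seed = 11))
  expect_identical(coh$clinical$homa_ir,
                   coh$clinical$fins * coh$clinical$fbg / 22.5)
})

test_that("covariate and clinical scales resemble the emulated panel", {
  coh <- generate_cohort(cohort_config(n_group1 = 150, n_group2 = 130,
                                       n_regions = 2,
                                       voxels_per_region = c(2, 3),
                                       seed = 5))
  expect_true(all(coh$covariates$age >= 35 & coh$covariates$age <= 70))
  expect_equal(mean(coh$covariates$age), 50.8, tolerance = 0.05)
  expect_true(all(coh$covariates$sex %in% c("male", "female")))
  pat <- coh$clinical[coh$clinical$group == "patient", ]
  ctl <- coh$clinical[coh$clinical$group == "control", ]
  expect_gt(median(pat$hba1c), median(ctl$hba1c))
  expect_gt(median(pat$fbg), median(ctl$fbg))
  expect_equal(median(ctl$fbg), 5.14, tolerance = 0.1)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_group1 = 0), class = "morphnet_config_error")
  expect_error(cohort_config(n_regions = 10, effect_regions = 11L),
               class = "morphnet_config_error")
  expect_error(cohort_config(effect_size = -1),
               class = "morphnet_config_error")
  expect_error(cohort_config(variance_effect = 0),
               class = "morphnet_config_error")
  expect_error(cohort_config(voxels_per_region = c(100, 50)),
               class = "morphnet_config_error")
})

test_that("cohort write/read round-trips within float formatting", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(small_cohort_config(seed = 2, n = 3L,
                                             n_regions = 5L,
                                             voxels = c(10L, 15L)))
  write_cohort(coh, dir)
  back <- read_cohort(dir, n_regions = 5L)
  expect_equal(back$voxels$value, coh$voxels$value, tolerance = 1e-12)
  expect_identical(back$voxels$subject_id, coh$voxels$subject_id)
  expect_equal(back$clinical$homa_ir, coh$clinical$homa_ir,
               tolerance = 1e-12)
})

test_that("voxel TSV has one row per voxel", {
  # 2 subjects x 3 regions x exactly 10 voxels -> 60 value rows
  dir <- withr::local_tempdir()
  coh <- generate_cohort(cohort_config(n_group1 = 1, n_group2 = 1,
                                       n_regions = 3,
                                       voxels_per_region = c(10L, 10L),
                                       seed = 1))
  paths <- write_cohort(coh, dir)
  expect_equal(nrow(coh$voxels), 60L)
  expect_equal(length(readLines(paths[1])), 61L)  # header + 60 rows
})

test_that("null generator is calibrated: region-mean tests reject at ~alpha", {
  # zero effect, unit variance ratio: a fixed region's mean GMV compared
  # between groups should reject at close to the nominal 5% rate
  n_rep <- 400L
  p <- vapply(seq_len(n_rep), function(i) {
    coh <- generate_cohort(small_cohort_config(seed = 1000L + i, n = 15L,
                                               n_regions = 6L,
                                               voxels = c(40L, 60L)))
    m <- coh$voxels |>
      dplyr::filter(region_id == 3L) |>
      dplyr::group_by(subject_id, group) |>
      dplyr::summarise(gmv = mean(value), .groups = "drop")
    stats::t.test(gmv ~ group, data = m, var.equal = TRUE)$p.value
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("larger injected effects give larger region-level statistics", {
  # monotonicity of the designated regions' mean-GMV |t| in effect_size
  mean_abs_t <- function(es) {
    mean(vapply(1:20, function(i) {
      coh <- generate_cohort(
        small_cohort_config(seed = 300L + i, n = 12L, n_regions = 8L,
                            effect_size = es, effect_regions = c(2L, 5L),
                            voxels = c(40L, 60L)))
      mean(vapply(c(2L, 5L), function(r) {
        m <- coh$voxels |>
          dplyr::filter(region_id == r) |>
          dplyr::group_by(subject_id, group) |>
          dplyr::summarise(gmv = mean(value), .groups = "drop")
        abs(stats::t.test(gmv ~ group, data = m,
                          var.equal = TRUE)$statistic)
      }, numeric(1)))
    }, numeric(1)))
  }
  t_by_effect <- vapply(c(0, 0.5, 1.0), mean_abs_t, numeric(1))
  expect_true(all(diff(t_by_effect) > 0))
})
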