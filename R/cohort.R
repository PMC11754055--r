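#' Configuration for a synthetic morphometry cohort
#'
#' Bundles and validates the parameters of the synthetic cohort generator.
#' The defaults emulate a two-group case-control morphometry study: 150
#' patients vs 130 controls, 90 atlas regions whose voxel counts span small
#' to large AAL regions, latent-factor coupling between regional means (the
#' source of cross-region similarity structure), and a group effect
#' concentrated in limbic/paralimbic regions (anterior cingulate,
#' hippocampus, parahippocampal gyrus).
#'
#' @param n_group1 Number of subjects in the patient group.
#' @param n_group2 Number of subjects in the control group.
#' @param n_regions Number of atlas regions (nodes). Default 90 (AAL90).
#' @param voxels_per_region Length-2 integer range; each region's voxel count
#'   is drawn uniformly from it (once per cohort — region size is anatomy,
#'   not subject-level noise).
#' @param n_latent_factors Number of shared latent factors driving
#'   between-region covariance of regional means.
#' @param effect_regions Integer indices (1-based, `<= n_regions`) of the
#'   regions carrying the group effect.
#' @param effect_size Standardised downward shift (in units of the region's
#'   voxel-level spread) applied to patients' effect-region means;
#'   `0` disables the location effect.
#' @param variance_effect Multiplicative inflation of patients'
#'   effect-region voxel spread; `1` disables it.
#' @param seed Integer seed; identical configurations generate bit-identical
#'   cohorts.
#' @return A `cohort_config` list.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_group1 = 150L,
                          n_group2 = 130L,
                          n_regions = 90L,
                          voxels_per_region = c(200L, 2000L),
                          n_latent_factors = 5L,
                          effect_regions = limbic_regions(),
                          effect_size = 1.0,
                          variance_effect = 1.5,
                          seed = 1L) {
  if (missing(effect_regions)) {
    # default limbic set, restricted to the configured atlas size
    effect_regions <- effect_regions[effect_regions <= n_regions]
  }
  cfg <- list(
    n_group1 = as.integer(n_group1),
    n_group2 = as.integer(n_group2),
    n_regions = as.integer(n_regions),
    voxels_per_region = as.integer(voxels_per_region),
    n_latent_factors = as.integer(n_latent_factors),
    effect_regions = as.integer(unname(effect_regions)),
    effect_size = as.numeric(effect_size),
    variance_effect = as.numeric(variance_effect),
    seed = as.integer(seed)
  )
  if (any(c(cfg$n_group1, cfg$n_group2, cfg$n_regions,
            cfg$n_latent_factors) <= 0L)) {
    abort("group sizes, region count and latent factor count must be positive",
          class = "morphnet_config_error")
  }
  if (length(cfg$voxels_per_region) != 2L ||
      cfg$voxels_per_region[1] < 2L ||
      diff(cfg$voxels_per_region) < 0L) {
    abort("voxels_per_region must be an increasing range with lower bound >= 2",
          class = "morphnet_config_error")
  }
  if (length(cfg$effect_regions) &&
      (min(cfg$effect_regions) < 1L || max(cfg$effect_regions) > cfg$n_regions)) {
    abort(sprintf("effect_regions must lie in 1..%d", cfg$n_regions),
          class = "morphnet_config_error")
  }
  if (cfg$effect_size < 0) {
    abort("effect_size must be >= 0", class = "morphnet_config_error")
  }
  if (cfg$variance_effect <= 0) {
    abort("variance_effect must be > 0", class = "morphnet_config_error")
  }
  structure(cfg, class = "cohort_config")
}

# truncated-normal draws via inverse-CDF so the generator stays vectorised
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  p_lo <- pnorm(lower, mean, sd)
  p_hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

#' Generate a synthetic two-group morphometry cohort
#'
#' Draws a full synthetic data set with the structure the downstream
#' analysis assumes: per-subject, per-region voxel-level gray-matter-volume
#' samples, plus covariate, clinical-chemistry and cognitive-score tables
#' emulating a case-control panel.
#'
#' Each region's voxel values follow a two-component Gaussian mixture
#' truncated at zero, with fixed per-cohort "anatomy" (location, spread,
#' mixture weight, voxel count) and per-subject regional mean shifts driven
#' by shared latent factors — so regions with similar factor loadings stay
#' mutually similar within every subject, giving the similarity network
#' non-trivial, reproducible structure. Patients additionally receive a
#' downward mean shift of `effect_size` regional spreads and a
#' `variance_effect`-fold spread inflation in `effect_regions`, which
#' decouples those regions from the rest of the network.
#'
#' The insulin-resistance index is computed from the generated fasting
#' insulin and glucose as `HOMA-IR = FINS * FBG / 22.5` (see [homa_ir()]).
#'
#' @param config A [cohort_config()].
#' @return A `morph_cohort` list with elements `voxels` (long tibble:
#'   `subject_id`, `group`, `region_id`, `value`), `covariates` (age, sex,
#'   education, TIV), `clinical` (HbA1c, FBG, FINS, HOMA-IR, TG, TC, LDL),
#'   `cognitive` (MoCA, MMSE, DST backward, CDT) and the `config` used.
#' @examples
#' coh <- generate_cohort(cohort_config(n_group1 = 4, n_group2 = 4,
#'                                      n_regions = 10,
#'                                      voxels_per_region = c(50, 100),
#'                                      seed = 1))
#' dplyr::count(coh$voxels, group)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)

  n1 <- config$n_group1
  n2 <- config$n_group2
  n_sub <- n1 + n2
  R <- config$n_regions
  K <- config$n_latent_factors

  subject_id <- sprintf("S%04d", seq_len(n_sub))
  group <- c(rep("patient", n1), rep("control", n2))

  # ---- fixed cohort anatomy -------------------------------------------------
  mu_base   <- runif(R, 0.45, 0.65)        # regional GMV location (arb. units)
  tau_base  <- runif(R, 0.06, 0.12)        # voxel-level spread
  mix_w     <- runif(R, 0.35, 0.65)        # second-component weight
  mix_delta <- runif(R, 0, 2) * tau_base   # component separation
  vox_range <- seq(config$voxels_per_region[1], config$voxels_per_region[2])
  n_vox     <- vox_range[sample.int(length(vox_range), R, replace = TRUE)]

  # latent-factor loadings couple regional means across the cortex
  loadings <- matrix(rnorm(R * K, sd = 0.03), nrow = R)

  # ---- subject-level regional means ----------------------------------------
  factors <- matrix(rnorm(n_sub * K), nrow = n_sub)        # subjects x K
  mu_sr <- matrix(mu_base, n_sub, R, byrow = TRUE) +
    factors %*% t(loadings) +
    matrix(rnorm(n_sub * R, sd = 0.01), n_sub, R)
  tau_sr <- matrix(tau_base, n_sub, R, byrow = TRUE)

  if (length(config$effect_regions) && n1 > 0) {
    er <- config$effect_regions
    mu_sr[seq_len(n1), er] <- mu_sr[seq_len(n1), er] -
      config$effect_size * matrix(tau_base[er], n1, length(er), byrow = TRUE)
    tau_sr[seq_len(n1), er] <- tau_sr[seq_len(n1), er] * config$variance_effect
  }

  # ---- voxel draws (fully vectorised over subjects x regions x voxels) -----
  reg_rep <- rep(rep(seq_len(R), n_vox), times = n_sub)
  sub_rep <- rep(seq_len(n_sub), each = sum(n_vox))
  cell <- cbind(sub_rep, reg_rep)
  comp <- rbinom(length(reg_rep), 1L, mix_w[reg_rep])
  vals <- abs(rnorm(length(reg_rep),
                    mean = mu_sr[cell] + comp * mix_delta[reg_rep],
                    sd   = tau_sr[cell]))

  voxels <- tibble::tibble(
    subject_id = subject_id[sub_rep],
    group = group[sub_rep],
    region_id = as.integer(reg_rep),
    value = vals
  )

  # ---- covariate / clinical / cognitive panels -----------------------------
  is_pat <- group == "patient"
  age <- rnorm_trunc(n_sub, ifelse(is_pat, 50.54, 51.02),
                     ifelse(is_pat, 8.70, 9.13), 35, 70)
  sex <- ifelse(rbinom(n_sub, 1L, ifelse(is_pat, 88 / 150, 70 / 130)) == 1L,
                "male", "female")
  education <- pmin(pmax(round(rnorm(n_sub, ifelse(is_pat, 11.7, 11.2), 3)),
                         6L), 20L)
  tiv <- rnorm(n_sub, 1.45e6, 1.2e5) + 1e5 * (sex == "male")

  covariates <- tibble::tibble(
    subject_id = subject_id, group = group,
    age = age, sex = sex, education = as.integer(education), tiv = tiv
  )

  # log-normal panels parameterised from median / IQR scale,
  # normal panels from mean / sd scale
  rln <- function(med_p, s_p, med_c, s_c) {
    rlnorm(n_sub, log(ifelse(is_pat, med_p, med_c)), ifelse(is_pat, s_p, s_c))
  }
  fbg  <- rln(8.52, 0.313, 5.14, 0.088)
  fins <- rln(5.99, 0.895, 8.75, 0.549)
  clinical <- tibble::tibble(
    subject_id = subject_id, group = group,
    hba1c = rln(9.30, 0.171, 5.70, 0.052),
    fbg = fbg, fins = fins,
    homa_ir = homa_ir(fins, fbg),
    tg = rln(1.78, 0.568, 1.27, 0.472),
    tc = rnorm(n_sub, ifelse(is_pat, 4.91, 5.08), ifelse(is_pat, 1.09, 0.92)),
    ldl = rnorm(n_sub, ifelse(is_pat, 3.11, 3.33), ifelse(is_pat, 0.96, 0.76))
  )

  score <- function(m_p, s_p, m_c, s_c, max_score) {
    as.integer(pmin(pmax(round(rnorm(n_sub, ifelse(is_pat, m_p, m_c),
                                     ifelse(is_pat, s_p, s_c))), 0L),
                    max_score))
  }
  cognitive <- tibble::tibble(
    subject_id = subject_id, group = group,
    moca = score(25.4, 3.3, 27.3, 1.2, 30L),
    mmse = score(27.8, 1.6, 28.7, 1.3, 30L),
    dst_backward = score(4.0, 1.4, 4.2, 1.4, 12L),
    cdt = score(3.5, 0.7, 3.7, 0.6, 4L)
  )

  structure(
    list(voxels = voxels, covariates = covariates, clinical = clinical,
         cognitive = cognitive, config = config),
    class = "morph_cohort"
  )
}

#' @export
print.morph_cohort <- function(x, ...) {
  cat(sprintf(
    "<morph_cohort> %d patients + %d controls, %d regions, %s voxel rows\n",
    x$config$n_group1, x$config$n_group2, x$config$n_regions,
    format(nrow(x$voxels), big.mark = ",")
  ))
  invisible(x)
}

#' Validate a long voxel sample table
#'
#' Checks the contract every downstream stage relies on: required columns,
#' no missing values, non-negative values, every (subject, region) cell
#' present for regions `1..n_regions` with at least two voxels.
#'
#' @param voxels Long tibble with columns `subject_id`, `group`, `region_id`,
#'   `value`.
#' @param n_regions Expected number of atlas regions.
#' @return `voxels`, invisibly, if valid; otherwise an error.
#' @export
validate_voxel_table <- function(voxels, n_regions = 90L) {
  need <- c("subject_id", "group", "region_id", "value")
  missing_cols <- setdiff(need, names(voxels))
  if (length(missing_cols)) {
    abort(paste("voxel table lacks columns:",
                paste(missing_cols, collapse = ", ")),
          class = "morphnet_data_error")
  }
  if (anyNA(voxels[need])) {
    abort("voxel table contains missing values", class = "morphnet_data_error")
  }
  if (any(voxels$value < 0)) {
    abort("voxel values must be non-negative", class = "morphnet_data_error")
  }
  counts <- dplyr::count(voxels, .data$subject_id, .data$region_id)
  per_sub <- dplyr::summarise(
    dplyr::group_by(counts, .data$subject_id),
    n_regions_seen = dplyr::n(), min_vox = min(.data$n), .groups = "drop"
  )
  bad <- dplyr::filter(per_sub,
                       .data$n_regions_seen != n_regions | .data$min_vox < 2L)
  if (nrow(bad)) {
    abort(sprintf(
      "subject %s: expected %d regions with >= 2 voxels each (saw %d regions, min %d voxels)",
      bad$subject_id[1], n_regions, bad$n_regions_seen[1], bad$min_vox[1]
    ), class = "morphnet_data_error")
  }
  invisible(voxels)
}

#' Write a cohort to plain-text tables
#'
#' Serialises the voxel samples and the three per-subject panels as TSV
#' files (`voxels.tsv`, `covariates.tsv`, `clinical.tsv`, `cognitive.tsv`)
#' in `dir`.
#'
#' @param cohort A `morph_cohort`.
#' @param dir Output directory (created if absent).
#' @return The paths written, invisibly.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "morph_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    abort(sprintf("cannot create directory '%s'", dir),
          class = "morphnet_io_error")
  }
  paths <- file.path(dir, c("voxels.tsv", "covariates.tsv",
                            "clinical.tsv", "cognitive.tsv"))
  readr::write_tsv(cohort$voxels, paths[1])
  readr::write_tsv(cohort$covariates, paths[2])
  readr::write_tsv(cohort$clinical, paths[3])
  readr::write_tsv(cohort$cognitive, paths[4])
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the four TSV tables.
#' @param n_regions Expected region count (validation only); by default the
#'   largest region label found in the data.
#' @return A `morph_cohort` (with `config = NULL`: the generator settings are
#'   not serialised, only the data).
#' @export
read_cohort <- function(dir, n_regions = NULL) {
  voxels <- readr::read_tsv(file.path(dir, "voxels.tsv"),
                            show_col_types = FALSE)
  voxels$region_id <- as.integer(voxels$region_id)
  validate_voxel_table(voxels,
                       n_regions = n_regions %||% max(voxels$region_id))
  structure(
    list(
      voxels = voxels,
      covariates = readr::read_tsv(file.path(dir, "covariates.tsv"),
                                   show_col_types = FALSE),
      clinical = readr::read_tsv(file.path(dir, "clinical.tsv"),
                                 show_col_types = FALSE),
      cognitive = readr::read_tsv(file.path(dir, "cognitive.tsv"),
                                  show_col_types = FALSE),
      config = NULL
    ),
    class = "morph_cohort"
  )
}
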