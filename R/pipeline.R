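#' Extract regional voxel samples from an image + atlas pair
#'
#' Given a gray-matter volume and an integer-labelled atlas on the same
#' voxel grid, collects the volume values at each atlas label into the long
#' voxel table the rest of the pipeline consumes. Label 0 is background.
#' No registration or resampling is performed: the images must already be
#' aligned voxel-for-voxel.
#'
#' @param gm_volume 3D numeric array, or path to a NIfTI file (read with
#'   the RNifti package).
#' @param atlas 3D array of integer labels in `0..n_regions`, or a NIfTI
#'   path; same dimensions as `gm_volume`.
#' @param subject_id,group Identifiers attached to the output rows.
#' @param n_regions Expected number of atlas regions (default 90).
#' @param strict If `TRUE`, any label in `1..n_regions` with fewer than two
#'   voxels is an error naming the region.
#' @return A long voxel tibble (`subject_id`, `group`, `region_id`, `value`).
#' @export
extract_regional_samples <- function(gm_volume, atlas,
                                     subject_id = "S0001",
                                     group = "unknown",
                                     n_regions = 90L, strict = TRUE) {
  read_vol <- function(x) {
    if (is.character(x)) {
      if (!requireNamespace("RNifti", quietly = TRUE)) {
        abort("reading NIfTI paths requires the RNifti package",
              class = "morphnet_io_error")
      }
      x <- RNifti::readNifti(x)
    }
    as.array(x)
  }
  gm <- read_vol(gm_volume)
  at <- read_vol(atlas)
  if (!identical(dim(gm), dim(at))) {
    abort(sprintf("volume/atlas shape mismatch: %s vs %s",
                  paste(dim(gm), collapse = "x"),
                  paste(dim(at), collapse = "x")),
          class = "morphnet_io_error")
  }
  if (max(abs(at - round(at))) > 1e-6) {
    abort("atlas contains non-integer labels", class = "morphnet_io_error")
  }
  at <- as.integer(round(at))
  if (min(at) < 0L || max(at) > n_regions) {
    abort(sprintf("atlas labels must lie in 0..%d", n_regions),
          class = "morphnet_io_error")
  }
  counts <- tabulate(at, nbins = n_regions)
  if (strict && any(counts < 2L)) {
    abort(sprintf("region %d has %d voxel(s); every region needs >= 2",
                  which(counts < 2L)[1], counts[which(counts < 2L)[1]]),
          class = "morphnet_data_error")
  }
  keep <- at > 0L
  tibble::tibble(
    subject_id = subject_id,
    group = group,
    region_id = at[keep],
    value = as.numeric(gm)[keep]
  ) |>
    dplyr::arrange(.data$region_id)
}

#' Write one subject's voxel samples as a toy NIfTI pair
#'
#' Packs the subject's voxels into a compact 3D volume with a matching
#' integer-label atlas volume, so the NIfTI extraction path can be exercised
#' round-trip: `extract_regional_samples()` on the written pair reproduces
#' the subject's voxel table.
#'
#' @param voxels Long voxel table restricted to one subject.
#' @param gm_path,atlas_path Output NIfTI paths (`.nii` or `.nii.gz`).
#' @return Invisibly, the two paths.
#' @export
write_nifti_pair <- function(voxels, gm_path, atlas_path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("writing NIfTI requires the RNifti package",
          class = "morphnet_io_error")
  }
  stopifnot(length(unique(voxels$subject_id)) == 1L)
  voxels <- dplyr::arrange(voxels, .data$region_id)
  n <- nrow(voxels)
  side <- ceiling(n^(1 / 3))
  total <- side^3
  gm <- array(0, dim = c(side, side, side))
  at <- array(0L, dim = c(side, side, side))
  gm[seq_len(n)] <- voxels$value
  at[seq_len(n)] <- voxels$region_id
  RNifti::writeNifti(RNifti::asNifti(gm), gm_path, datatype = "double")
  RNifti::writeNifti(RNifti::asNifti(at), atlas_path, datatype = "int32")
  invisible(c(gm_path, atlas_path))
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with defaults matching
#' the canonical study settings: JSD similarity, sparsity 0.05-0.40 step
#' 0.01, 256-point KDE grid, 100 null networks, covariates age / sex /
#' education / TIV, two-sided alpha 0.05 and FDR q 0.05. `config` may also
#' be a YAML file of flat key-value overrides.
#'
#' @param ... Overrides of the defaults (see Details in the vignette).
#' @param file Optional YAML file whose keys override the defaults (values
#'   in `...` take precedence over the file).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(..., file = NULL) {
  defaults <- list(
    cohort_dir = NULL,          # read a written cohort; NULL => simulate
    simulate = list(),          # cohort_config() overrides when simulating
    method = "JSDs",            # "JSDs", "KLDs" or "both"
    s_min = 0.05, s_max = 0.40, step = 0.01,
    n_points = 256L,
    n_null = 100L,
    covariates = c("age", "sex", "education", "tiv"),
    alpha = 0.05, q = 0.05,
    seed = 1L,
    strict = TRUE,
    write_networks = TRUE,
    out_dir = NULL
  )
  overrides <- list(...)
  if (!is.null(file)) {
    from_file <- yaml::read_yaml(file)
    defaults <- modifyList(defaults, from_file)
  }
  cfg <- modifyList(defaults, overrides)
  if (!cfg$method %in% c("JSDs", "KLDs", "both")) {
    abort("method must be 'JSDs', 'KLDs' or 'both'",
          class = "morphnet_config_error")
  }
  sparsity_scheme(cfg$s_min, cfg$s_max, cfg$step)  # validates
  structure(cfg, class = "pipeline_config")
}

log_stage <- function(quiet, ...) {
  if (!quiet) message(sprintf("[morphnet] %s", sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Sequences every stage on one cohort: ingestion (reading a written cohort
#' or simulating one), per-subject network construction, the sparsity sweep
#' with AUC summarisation, and the group-level statistics (panel
#' comparisons, global-AUC covariate-adjusted tests, nodal FDR analysis,
#' and partial correlations of surviving nodal AUCs with cognitive scores
#' in the patient group). All outputs are tidy TSVs plus a plain-text
#' summary report; identical config and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage logging.
#' @return Invisibly, a list with the in-memory results (`cohort`, per-method
#'   `aucs`, `global_tests`, `nodal_tests`, `correlations`, `panel_tests`,
#'   `out_dir`).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir %||% tempfile("morphnet_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # -- stage 1: ingest --------------------------------------------------------
  if (is.null(config$cohort_dir)) {
    cc <- do.call(cohort_config, modifyList(list(seed = config$seed),
                                            config$simulate))
    log_stage(quiet, "simulate: %d + %d subjects, %d regions, seed %d",
              cc$n_group1, cc$n_group2, cc$n_regions, cc$seed)
    cohort <- generate_cohort(cc)
  } else {
    log_stage(quiet, "ingest: reading cohort from %s", config$cohort_dir)
    cohort <- read_cohort(config$cohort_dir)
  }
  validate_voxel_table(cohort$voxels,
                       n_regions = length(unique(cohort$voxels$region_id)))

  scheme <- sparsity_scheme(config$s_min, config$s_max, config$step)
  methods <- if (config$method == "both") c("JSDs", "KLDs") else config$method
  n_regions <- length(unique(cohort$voxels$region_id))
  groups <- dplyr::distinct(cohort$voxels, .data$subject_id, .data$group)

  results <- list(cohort = cohort, out_dir = out_dir, aucs = list(),
                  global_tests = list(), nodal_tests = list(),
                  correlations = list())

  # -- stage 2+3: per-subject networks and metric curves ---------------------
  for (method in methods) {
    log_stage(quiet,
              "networks (%s): %d subjects, %d thresholds, n_null = %d",
              method, nrow(groups), length(scheme$thresholds), config$n_null)
    net_dir <- file.path(out_dir, paste0("networks_", method))
    if (config$write_networks) {
      dir.create(net_dir, showWarnings = FALSE)
    }
    by_subject <- split(cohort$voxels, cohort$voxels$subject_id)
    per_subject <- purrr::map(groups$subject_id, function(id) {
      pmfs <- build_pmf_set(by_subject[[id]], n_points = config$n_points,
                            n_regions = n_regions, strict = config$strict)
      sim <- build_similarity_matrix(pmfs, method = method)
      if (config$write_networks) {
        write_similarity_matrix(sim, file.path(net_dir,
                                               paste0(id, ".tsv")))
      }
      subject_curves(sim, scheme = scheme, n_null = config$n_null,
                     seed = config$seed + match(id, groups$subject_id))
    })
    names(per_subject) <- groups$subject_id

    global_auc <- dplyr::left_join(
      groups, purrr::map_dfr(per_subject, "global_auc", .id = "subject_id"),
      by = "subject_id")
    nodal_auc <- dplyr::left_join(
      groups, purrr::map_dfr(per_subject, "nodal_auc", .id = "subject_id"),
      by = "subject_id")
    readr::write_tsv(global_auc,
                     file.path(out_dir, paste0("global_auc_", method, ".tsv")))
    readr::write_tsv(nodal_auc,
                     file.path(out_dir, paste0("nodal_auc_", method, ".tsv")))
    results$aucs[[method]] <- list(global = global_auc, nodal = nodal_auc)

    # -- stage 4: group statistics -------------------------------------------
    log_stage(quiet, "stats (%s): global + nodal group tests, q = %.3g",
              method, config$q)
    cov_tbl <- cohort$covariates
    metric_cols <- setdiff(names(global_auc), c("subject_id", "group"))
    global_tests <- purrr::map_dfr(metric_cols, function(m) {
      d <- dplyr::left_join(global_auc, cov_tbl,
                            by = c("subject_id", "group"))
      dplyr::mutate(
        glm_group_test(d[[m]], d$group, covariates = config$covariates,
                       cohort = d, alpha = config$alpha),
        metric = m, .before = 1)
    })
    nodal_tests <- nodal_group_analysis(
      nodal_auc, covariates = config$covariates, cohort = cov_tbl,
      q = config$q, alpha = config$alpha)
    readr::write_tsv(global_tests,
                     file.path(out_dir, paste0("global_tests_", method, ".tsv")))
    readr::write_tsv(nodal_tests,
                     file.path(out_dir, paste0("nodal_tests_", method, ".tsv")))
    results$global_tests[[method]] <- global_tests
    results$nodal_tests[[method]] <- nodal_tests

    # -- stage 5: partial correlations for FDR survivors ---------------------
    survivors <- dplyr::filter(nodal_tests, .data$survivor)
    if (nrow(survivors) && !is.null(cohort$cognitive)) {
      log_stage(quiet, "correlations (%s): %d surviving region metrics",
                method, nrow(survivors))
      pat <- dplyr::filter(nodal_auc, .data$group == "patient")
      pat <- dplyr::left_join(pat, cov_tbl, by = c("subject_id", "group"))
      pat <- dplyr::left_join(pat, cohort$cognitive,
                              by = c("subject_id", "group"))
      scores <- setdiff(names(cohort$cognitive), c("subject_id", "group"))
      correlations <- purrr::pmap_dfr(
        survivors[c("region", "metric")], function(region, metric) {
          d <- dplyr::filter(pat, .data$region == .env$region)
          purrr::map_dfr(scores, function(sc) {
            dplyr::mutate(
              partial_correlation(d[[metric]], d[[sc]],
                                  covariates = config$covariates, cohort = d,
                                  alpha = config$alpha),
              region = region, metric = metric, score = sc, .before = 1)
          })
        })
      readr::write_tsv(correlations,
                       file.path(out_dir,
                                 paste0("correlations_", method, ".tsv")))
      results$correlations[[method]] <- correlations
    }
  }

  # -- stage 6: panel comparisons and report ---------------------------------
  panel_tests <- purrr::map_dfr(
    list(covariates = cohort$covariates, clinical = cohort$clinical,
         cognitive = cohort$cognitive)[
           !vapply(list(cohort$covariates, cohort$clinical,
                        cohort$cognitive), is.null, logical(1))],
    compare_panel, alpha = config$alpha, .id = "panel")
  readr::write_tsv(panel_tests, file.path(out_dir, "panel_tests.tsv"))
  results$panel_tests <- panel_tests

  write_report(results, config, file.path(out_dir, "report.txt"))
  log_stage(quiet, "done: outputs in %s", out_dir)
  invisible(results)
}

write_report <- function(results, config, path) {
  lines <- c(
    "morphnet pipeline report",
    strrep("=", 60),
    sprintf("subjects: %d | regions: %d | method: %s | seed: %d",
            length(unique(results$cohort$voxels$subject_id)),
            length(unique(results$cohort$voxels$region_id)),
            config$method, config$seed),
    sprintf("sparsity: %.2f-%.2f step %.2f | kde points: %d | n_null: %d",
            config$s_min, config$s_max, config$step, config$n_points,
            config$n_null),
    sprintf("covariates: %s | alpha = %g | q = %g",
            paste(config$covariates, collapse = ", "),
            config$alpha, config$q),
    ""
  )
  for (method in names(results$nodal_tests)) {
    gt <- results$global_tests[[method]]
    sig <- gt$metric[gt$significant]
    surv <- dplyr::filter(results$nodal_tests[[method]], .data$survivor)
    lines <- c(
      lines,
      sprintf("[%s] significant global AUC differences: %s", method,
              if (length(sig)) paste(sig, collapse = ", ") else "none"),
      sprintf("[%s] nodal FDR survivors: %s", method,
              if (nrow(surv))
                paste(sprintf("%s/%s (%s)", surv$region, surv$metric,
                              ifelse(surv$estimate > 0, "higher in patients",
                                     "lower in patients")),
                      collapse = "; ")
              else "none")
    )
  }
  writeLines(lines, path)
  invisible(path)
}
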