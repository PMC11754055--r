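#' Build a subject's shared evaluation grid
#'
#' All of a subject's regional densities are evaluated on one uniform grid so
#' that every pairwise divergence compares distributions with common support.
#' The grid spans the subject's pooled voxel-value range padded by three times
#' the largest regional bandwidth (`h_max`), i.e.
#' `[min - 3 h_max, max + 3 h_max]`, which keeps essentially all Gaussian
#' kernel mass of every region on-grid.
#'
#' @param voxels Long voxel table restricted to one subject.
#' @param n_points Number of grid points (>= 16; default 256).
#' @param strict If `TRUE`, a zero pooled range (all values identical) is an
#'   error; if `FALSE` a unit-width interval around the value is used.
#' @return A `value_grid`: list with `points` (increasing numeric vector) and
#'   `spacing` (positive scalar).
#' @export
build_subject_grid <- function(voxels, n_points = 256L, strict = TRUE) {
  if (n_points < 16L) {
    abort("n_points must be at least 16", class = "morphnet_grid_error")
  }
  if (length(unique(voxels$subject_id)) != 1L) {
    abort("build_subject_grid() expects exactly one subject",
          class = "morphnet_grid_error")
  }
  values <- voxels$value
  rng <- range(values)
  if (diff(rng) == 0) {
    if (strict) {
      abort("all voxel values identical: cannot build a grid in strict mode",
            class = "morphnet_degenerate_error")
    }
    rng <- rng + c(-0.5, 0.5)
  }
  h_max <- max(vapply(split(values, voxels$region_id),
                      silverman_bw, numeric(1), strict = strict))
  value_grid(rng[1] - 3 * h_max, rng[2] + 3 * h_max, n_points)
}

#' @rdname build_subject_grid
#' @param lower,upper Grid end points.
#' @export
value_grid <- function(lower, upper, n_points = 256L) {
  if (n_points < 16L) {
    abort("n_points must be at least 16", class = "morphnet_grid_error")
  }
  if (!(upper > lower)) {
    abort("grid upper bound must exceed lower bound",
          class = "morphnet_grid_error")
  }
  points <- seq(lower, upper, length.out = n_points)
  structure(list(points = points, spacing = points[2] - points[1]),
            class = "value_grid")
}

# Silverman rule-of-thumb bandwidth; degenerate samples are an error in
# strict mode, and get a tiny positive fallback bandwidth otherwise.
silverman_bw <- function(values, strict = TRUE) {
  if (length(values) < 2L) {
    abort("need at least 2 voxel values per region",
          class = "morphnet_degenerate_error")
  }
  if (sd(values) == 0) {
    if (strict) {
      abort("zero-variance voxel sample in strict mode",
            class = "morphnet_degenerate_error")
    }
    warn("zero-variance voxel sample: substituting a nominal bandwidth")
    return(max(1e-6, 1e-6 * abs(mean(values))))
  }
  bw.nrd0(values)
}

#' Estimate a discrete probability mass function by Gaussian KDE
#'
#' Evaluates a Gaussian-kernel density estimate (Silverman rule-of-thumb
#' bandwidth) of `values` at the grid points, multiplies by the grid spacing
#' and renormalises, yielding a discrete distribution that sums to exactly 1.
#' Divergences between two such rows are then ordinary discrete JSD/KLD:
#' bounded, and free of quadrature error terms.
#'
#' @param values Numeric vector of voxel values (length >= 2).
#' @param grid A `value_grid` shared across the subject's regions.
#' @param strict Degenerate (zero-variance) samples error when `TRUE`;
#'   otherwise a nominal bandwidth `max(1e-6, 1e-6 |mean|)` is substituted
#'   with a warning.
#' @return Numeric vector of length `length(grid$points)`, non-negative,
#'   summing to 1.
#' @examples
#' g <- value_grid(-4, 4, 64)
#' p <- estimate_pmf(rnorm(500), g)
#' sum(p)
#' @export
estimate_pmf <- function(values, grid, strict = TRUE) {
  stopifnot(inherits(grid, "value_grid"))
  h <- silverman_bw(values, strict = strict)
  # mean of Gaussian kernels, evaluated at each grid point
  dens <- colMeans(dnorm(outer(values, grid$points, "-") / h)) / h
  pmf <- dens * grid$spacing
  total <- sum(pmf)
  if ((total <= 0 || !is.finite(total)) && !strict && h < grid$spacing) {
    # nominal fallback bandwidth narrower than the grid can resolve:
    # widen to one grid spacing so the sample keeps mass on-grid
    warn("bandwidth below grid resolution: widening to one grid spacing")
    h <- grid$spacing
    dens <- colMeans(dnorm(outer(values, grid$points, "-") / h)) / h
    pmf <- dens * grid$spacing
    total <- sum(pmf)
  }
  if (total <= 0 || !is.finite(total)) {
    abort("density vanished on the grid: grid does not cover the sample",
          class = "morphnet_grid_error")
  }
  pmf / total
}

#' Build a subject's full regional PMF set
#'
#' Applies [estimate_pmf()] to every region of one subject on the shared
#' subject grid, producing the matrix of discrete regional GMV distributions
#' from which the individual similarity network is built.
#'
#' @param voxels Long voxel table restricted to one subject; regions
#'   `1..n_regions` must all be present.
#' @param n_points Grid resolution (default 256).
#' @param n_regions Expected region count (default 90).
#' @param strict See [estimate_pmf()].
#' @return A `morph_pmf_set`: list with `subject_id`, `grid` and `pmf`
#'   (`n_regions` x `n_points` matrix; each row sums to 1).
#' @export
build_pmf_set <- function(voxels, n_points = 256L, n_regions = 90L,
                          strict = TRUE) {
  subject <- unique(voxels$subject_id)
  if (length(subject) != 1L) {
    abort("build_pmf_set() expects exactly one subject",
          class = "morphnet_data_error")
  }
  present <- unique(voxels$region_id)
  missing_regions <- setdiff(seq_len(n_regions), present)
  if (length(missing_regions)) {
    abort(sprintf("subject %s: missing region(s) %s", subject,
                  paste(head(missing_regions, 5), collapse = ", ")),
          class = "morphnet_data_error")
  }
  grid <- build_subject_grid(voxels, n_points = n_points, strict = strict)
  by_region <- split(voxels$value, voxels$region_id)
  pmf <- t(vapply(as.character(seq_len(n_regions)),
                  function(r) estimate_pmf(by_region[[r]], grid,
                                           strict = strict),
                  numeric(n_points)))
  rownames(pmf) <- if (n_regions == 90L) aal90_labels() else
    paste0("region_", seq_len(n_regions))
  structure(list(subject_id = subject, grid = grid, pmf = pmf),
            class = "morph_pmf_set")
}

#' @export
print.morph_pmf_set <- function(x, ...) {
  cat(sprintf("<morph_pmf_set> subject %s: %d regions x %d grid points\n",
              x$subject_id, nrow(x$pmf), ncol(x$pmf)))
  invisible(x)
}

#' Serialise a PMF set as a matrix-with-header TSV
#'
#' First column `region`, remaining columns the grid points (named by their
#' value), one row per region — convenient for inspection or plotting
#' outside R.
#'
#' @param pmf_set A `morph_pmf_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pmf_set <- function(pmf_set, path) {
  stopifnot(inherits(pmf_set, "morph_pmf_set"))
  tbl <- tibble::as_tibble(pmf_set$pmf, .name_repair = "minimal")
  names(tbl) <- sprintf("x_%.6g", pmf_set$grid$points)
  tbl <- dplyr::bind_cols(tibble::tibble(region = rownames(pmf_set$pmf)), tbl)
  readr::write_tsv(tbl, path)
  invisible(path)
}
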