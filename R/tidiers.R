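#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a subject's metric curves
#'
#' Long tibble with one row per metric per threshold; nodal metrics
#' additionally carry `node` and `region` (global rows have `NA` there).
#'
#' @param x A `morph_curves` from [subject_curves()].
#' @param which `"global"`, `"nodal"` or `"both"`.
#' @param ... Unused.
#' @return A tibble: `subject_id`, `scope`, `metric`, `node`, `region`,
#'   `threshold`, `value`.
#' @export
tidy.morph_curves <- function(x, which = c("both", "global", "nodal"), ...) {
  which <- match.arg(which)
  out <- list()
  if (which != "nodal") {
    out$global <- tidyr::pivot_longer(x$global, -"threshold",
                                      names_to = "metric") |>
      dplyr::mutate(scope = "global", node = NA_integer_,
                    region = NA_character_)
  }
  if (which != "global") {
    th <- x$scheme$thresholds
    out$nodal <- purrr::imap_dfr(x$nodal, function(mat, metric) {
      tibble::tibble(
        metric = metric,
        node = rep(seq_len(nrow(mat)), times = length(th)),
        region = rep(rownames(mat), times = length(th)),
        threshold = rep(th, each = nrow(mat)),
        value = as.vector(mat)
      )
    }) |>
      dplyr::mutate(scope = "nodal")
  }
  dplyr::bind_rows(out) |>
    dplyr::mutate(subject_id = x$subject_id) |>
    dplyr::select("subject_id", "scope", "metric", "node", "region",
                  "threshold", "value")
}

#' Glance at a subject's metric curves
#'
#' One row per global metric with its AUC over the sparsity range, plus the
#' disconnection flag.
#'
#' @param x A `morph_curves`.
#' @param ... Unused.
#' @return A tibble: `subject_id`, `metric`, `auc`, `disconnected`.
#' @export
glance.morph_curves <- function(x, ...) {
  tidyr::pivot_longer(x$global_auc, dplyr::everything(),
                      names_to = "metric", values_to = "auc") |>
    dplyr::mutate(subject_id = x$subject_id, disconnected = x$disconnected,
                  .before = 1)
}

#' Tidy a similarity matrix into an edge list
#'
#' @param x A `morph_similarity`.
#' @param ... Unused.
#' @return A tibble with one row per unordered region pair: `subject_id`,
#'   `method`, `from`, `to`, `from_region`, `to_region`, `weight`.
#' @export
tidy.morph_similarity <- function(x, ...) {
  ij <- which(upper.tri(x$weights), arr.ind = TRUE)
  labels <- rownames(x$weights)
  tibble::tibble(
    subject_id = x$subject_id,
    method = x$method,
    from = ij[, 1], to = ij[, 2],
    from_region = labels[ij[, 1]], to_region = labels[ij[, 2]],
    weight = x$weights[ij]
  ) |>
    dplyr::arrange(.data$from, .data$to)
}
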