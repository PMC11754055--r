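#' Sparsity thresholding scheme
#'
#' The sparsity `S` of a binary graph is the ratio of retained edges to the
#' maximum possible `N (N - 1) / 2`. Metrics are computed over a sweep of
#' sparsities and summarised by area under the curve; the default sweep is
#' 0.05 to 0.40 in steps of 0.01 — 36 thresholds.
#'
#' @param s_min,s_max Sparsity range, `0 < s_min < s_max <= 1`.
#' @param step Positive increment.
#' @return A `sparsity_scheme` with the derived `thresholds` vector.
#' @examples
#' length(sparsity_scheme()$thresholds)  # 36
#' @export
sparsity_scheme <- function(s_min = 0.05, s_max = 0.40, step = 0.01) {
  if (!(s_min > 0 && s_min < s_max && s_max <= 1 && step > 0)) {
    abort("need 0 < s_min < s_max <= 1 and step > 0",
          class = "morphnet_scheme_error")
  }
  n <- round((s_max - s_min) / step) + 1L
  structure(
    list(s_min = s_min, s_max = s_max, step = step,
         thresholds = s_min + step * (seq_len(n) - 1L)),
    class = "sparsity_scheme"
  )
}

# weight matrix from either a morph_similarity or a plain symmetric matrix
as_weight_matrix <- function(weights) {
  if (inherits(weights, "morph_similarity")) weights <- weights$weights
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  weights
}

# upper-triangle edge candidates ordered by descending weight, ties broken
# by ascending (i, j) lexicographic order; shared by all thresholds so the
# retained edge sets are nested across sparsities
edge_order <- function(W) {
  ij <- which(upper.tri(W), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  w <- W[ij]
  list(ij = ij[order(-w, ij[, 1], ij[, 2]), , drop = FALSE], n = nrow(W))
}

adjacency_from_topk <- function(ord, k) {
  A <- matrix(0L, ord$n, ord$n)
  if (k > 0) {
    keep <- ord$ij[seq_len(k), , drop = FALSE]
    A[keep] <- 1L
    A[keep[, c(2, 1), drop = FALSE]] <- 1L
  }
  A
}

#' Binarise a similarity matrix at a sparsity threshold
#'
#' Keeps the `K = round(S N (N - 1) / 2)` largest-weight edges (ties broken
#' by ascending lexicographic node pair, for determinism) and returns the
#' binary graph. Because selection is top-K, the edge set at a lower
#' sparsity is always a subset of the edge set at a higher one.
#'
#' @param weights A `morph_similarity` or symmetric numeric matrix with zero
#'   diagonal.
#' @param S Sparsity in `(0, 1]`.
#' @return A `binary_graph`: list with `adjacency` (0/1 symmetric matrix),
#'   `n_nodes`, `n_edges`.
#' @examples
#' W <- matrix(runif(90 * 90), 90); W <- (W + t(W)) / 2; diag(W) <- 0
#' threshold_at_sparsity(W, 0.05)$n_edges  # round(0.05 * 4005) = 200
#' @export
threshold_at_sparsity <- function(weights, S) {
  if (!(S > 0 && S <= 1)) {
    abort("sparsity S must lie in (0, 1]", class = "morphnet_scheme_error")
  }
  W <- as_weight_matrix(weights)
  ord <- edge_order(W)
  k <- round(S * ord$n * (ord$n - 1) / 2)
  binary_graph(adjacency_from_topk(ord, k))
}

#' @rdname threshold_at_sparsity
#' @param adjacency 0/1 symmetric matrix with zero diagonal.
#' @export
binary_graph <- function(adjacency) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  if (any(diag(adjacency) != 0)) {
    abort("self-loops are not allowed", class = "morphnet_graph_error")
  }
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
    abort("adjacency must be symmetric", class = "morphnet_graph_error")
  }
  storage.mode(adjacency) <- "integer"
  structure(
    list(adjacency = adjacency, n_nodes = nrow(adjacency),
         n_edges = sum(adjacency) / 2),
    class = "binary_graph"
  )
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
}

# inverse-distance matrix with 0 for unreachable pairs and the diagonal
inv_distance <- function(D) {
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  inv
}

#' Global graph metrics
#'
#' `clustering_coefficient()` is the mean over nodes of the local clustering
#' coefficient (triangles over possible neighbour pairs; nodes of degree < 2
#' contribute 0). `characteristic_path_length()` is the mean shortest-path
#' length over reachable ordered pairs; if the graph is disconnected the
#' unreachable pairs are excluded and the result carries
#' `attr(, "disconnected") = TRUE`. `global_efficiency()` is the mean of
#' inverse shortest-path lengths over ordered pairs (0 for unreachable
#' pairs), and `local_efficiency()` the mean over nodes of the global
#' efficiency of each node's neighbour-induced subgraph (0 for degree < 2).
#'
#' @param g A `binary_graph`.
#' @return A scalar.
#' @examples
#' k4 <- binary_graph(matrix(1, 4, 4) - diag(4))
#' clustering_coefficient(k4)       # 1
#' characteristic_path_length(k4)   # 1
#' @export
clustering_coefficient <- function(g) {
  mean(.cpp_local_clustering(g$adjacency))
}

#' @rdname clustering_coefficient
#' @export
characteristic_path_length <- function(g) {
  if (g$n_edges == 0) {
    abort("characteristic path length is undefined on an edgeless graph",
          class = "morphnet_graph_error")
  }
  D <- .cpp_distances(g$adjacency)
  finite <- is.finite(D) & upper.tri(D)
  lp <- mean(D[finite])
  attr(lp, "disconnected") <- any(!is.finite(D[upper.tri(D)]))
  lp
}

#' @rdname clustering_coefficient
#' @export
global_efficiency <- function(g) {
  n <- g$n_nodes
  if (n < 2) return(0)
  sum(inv_distance(.cpp_distances(g$adjacency))) / (n * (n - 1))
}

#' @rdname clustering_coefficient
#' @export
local_efficiency <- function(g) {
  mean(.cpp_nodal_local_efficiency(g$adjacency))
}

#' Nodal graph metrics
#'
#' Per-node metrics of a binary graph: nodal efficiency
#' `Ne(i) = mean over j != i of 1 / d(i, j)` (0 for unreachable `j`), degree
#' centrality `DC`, nodal local efficiency `NLe` (global efficiency of the
#' neighbour-induced subgraph) and unnormalised shortest-path betweenness
#' centrality `BC`.
#'
#' @param g A `binary_graph`.
#' @return A tibble with columns `node`, `region`, `ne`, `dc`, `nle`, `bc`.
#' @export
nodal_metrics <- function(g) {
  inv <- inv_distance(.cpp_distances(g$adjacency))
  n <- g$n_nodes
  labels <- rownames(g$adjacency) %||%
    (if (n == 90L) aal90_labels() else paste0("node_", seq_len(n)))
  tibble::tibble(
    node = seq_len(n),
    region = labels,
    ne = rowSums(inv) / (n - 1),
    dc = as.numeric(rowSums(g$adjacency != 0)),
    nle = .cpp_nodal_local_efficiency(g$adjacency),
    bc = as.numeric(.cpp_betweenness(g$adjacency))
  )
}

#' Degree-preserving random rewiring (null model)
#'
#' Generates a random graph with exactly the degree sequence of `g` by
#' repeated edge swaps (the Maslov-Sneppen procedure), keeping the graph
#' simple. Used as the reference for the normalised clustering coefficient
#' and path length.
#'
#' @param g A `binary_graph` with at least two independent edges.
#' @param n_swaps Number of swap attempts (default `10 * n_edges`).
#' @param seed Optional integer seed for reproducibility.
#' @return A rewired `binary_graph` with the same degree sequence.
#' @export
rewire_null <- function(g, n_swaps = NULL, seed = NULL) {
  if (g$n_edges < 2) {
    abort("need at least two edges to rewire", class = "morphnet_graph_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n_swaps <- n_swaps %||% as.integer(10 * g$n_edges)
  ig <- igraph::rewire(as_igraph(g),
                       igraph::keeping_degseq(loops = FALSE,
                                              niter = n_swaps))
  A <- as.matrix(igraph::as_adjacency_matrix(ig, sparse = FALSE))
  storage.mode(A) <- "integer"
  dimnames(A) <- dimnames(g$adjacency)
  binary_graph(A)
}

#' Small-world indices
#'
#' Normalises clustering and path length by the means of `n_null`
#' degree-preserving random rewirings: `gamma = Cp / <Cp_null>`,
#' `lambda = Lp / <Lp_null>`, `sigma = gamma / lambda`. A network is
#' small-world when `gamma > 1`, `lambda` is near 1 and `sigma > 1`.
#'
#' @param g A `binary_graph`.
#' @param n_null Number of null networks (>= 1).
#' @param seed Optional integer seed.
#' @return One-row tibble: `cp`, `lp`, `gamma`, `lambda`, `sigma`.
#' @export
small_world <- function(g, n_null = 100L, seed = NULL) {
  if (n_null < 1) {
    abort("n_null must be >= 1", class = "morphnet_graph_error")
  }
  if (!is.null(seed)) set.seed(seed)
  cp <- clustering_coefficient(g)
  lp <- as.numeric(characteristic_path_length(g))
  null_stats <- vapply(seq_len(n_null), function(i) {
    gn <- rewire_null(g)  # consumes the RNG stream seeded above
    c(clustering_coefficient(gn),
      as.numeric(characteristic_path_length(gn)))
  }, numeric(2))
  cp_null <- mean(null_stats[1, ])
  lp_null <- mean(null_stats[2, ])
  if (cp_null <= 0 || lp_null <= 0) {
    warn("null networks have zero mean clustering or path length; gamma/lambda undefined")
    gamma <- lambda <- sigma <- NA_real_
  } else {
    gamma <- cp / cp_null
    lambda <- lp / lp_null
    sigma <- gamma / lambda
  }
  tibble::tibble(cp = cp, lp = lp, gamma = gamma, lambda = lambda,
                 sigma = sigma)
}

#' Area under a metric-versus-sparsity curve
#'
#' Trapezoidal integral of a metric curve against the sparsity variable —
#' the per-subject summary statistic carried into group statistics. Exact
#' for curves linear in the sparsity.
#'
#' @param values Metric values, one per threshold.
#' @param scheme The [sparsity_scheme()] that produced them.
#' @return The scalar AUC.
#' @examples
#' auc_over_thresholds(rep(1, 36), sparsity_scheme())  # 0.35
#' @export
auc_over_thresholds <- function(values, scheme) {
  stopifnot(inherits(scheme, "sparsity_scheme"))
  th <- scheme$thresholds
  if (length(values) != length(th) || length(values) < 2) {
    abort("values must match the scheme's thresholds (length >= 2)",
          class = "morphnet_scheme_error")
  }
  if (any(!is.finite(values))) {
    abort("metric curve contains non-finite values",
          class = "morphnet_scheme_error")
  }
  sum(diff(th) * (head(values, -1) + values[-1]) / 2)
}

#' Metric curves over the sparsity sweep for one subject
#'
#' Thresholds the subject's similarity matrix at every sparsity in the
#' scheme and computes all global metrics (Cp, Lp, gamma, lambda, sigma, Eg,
#' Eloc) and nodal metrics (Ne, DC, NLe, BC), plus the AUC of each curve.
#' With `n_null = 0` the normalised metrics (gamma, lambda, sigma) are
#' skipped, which is substantially faster when only raw and efficiency
#' metrics are needed.
#'
#' @param weights A `morph_similarity` or symmetric weight matrix.
#' @param scheme A [sparsity_scheme()].
#' @param n_null Null networks per threshold for gamma/lambda/sigma
#'   (0 skips them).
#' @param seed Integer seed governing the null-model randomness.
#' @return A `morph_curves`: list with `global` (tibble, one row per
#'   threshold), `nodal` (list of node x threshold matrices per metric),
#'   `global_auc` (one-row tibble), `nodal_auc` (tibble, one row per node),
#'   `scheme`, `subject_id`, `disconnected` (any threshold disconnected).
#' @export
subject_curves <- function(weights, scheme = sparsity_scheme(),
                           n_null = 100L, seed = 1L) {
  W <- as_weight_matrix(weights)
  subject <- if (inherits(weights, "morph_similarity")) weights$subject_id
             else NA_character_
  ord <- edge_order(W)
  n <- ord$n
  th <- scheme$thresholds
  k_per <- as.integer(round(th * n * (n - 1) / 2))
  labels <- rownames(W) %||%
    (if (n == 90L) aal90_labels() else paste0("node_", seq_len(n)))

  sweep <- .cpp_sweep(ord$ij, n, k_per)
  glob <- sweep$global
  nodal <- lapply(sweep[c("ne", "dc", "nle", "bc")], function(m) {
    dimnames(m) <- list(labels, NULL)
    m
  })
  disconnected <- any(sweep$disconnected)

  if (n_null > 0) {
    # gamma/lambda/sigma: normalise cp and lp by degree-preserving nulls
    set.seed(seed)
    norm <- t(vapply(seq_along(th), function(t_i) {
      g <- binary_graph(adjacency_from_topk(ord, k_per[t_i]))
      sw <- small_world(g, n_null = n_null)  # uses the seeded RNG stream
      c(gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma)
    }, numeric(3)))
    glob <- cbind(glob[, c("cp", "lp"), drop = FALSE], norm,
                  glob[, c("eg", "eloc"), drop = FALSE])
  }

  global <- tibble::as_tibble(glob)
  global <- dplyr::bind_cols(tibble::tibble(threshold = th), global)
  if (anyNA(glob)) {
    warn(paste("normalised metrics undefined at some thresholds",
               "(degenerate null networks); their AUC is NA"))
  }
  global_auc <- tibble::as_tibble(as.list(apply(glob, 2, function(v) {
    if (all(is.finite(v))) auc_over_thresholds(v, scheme = scheme)
    else NA_real_
  })))
  nodal_auc <- tibble::tibble(
    node = seq_len(n), region = labels,
    ne = apply(nodal$ne, 1, auc_over_thresholds, scheme = scheme),
    dc = apply(nodal$dc, 1, auc_over_thresholds, scheme = scheme),
    nle = apply(nodal$nle, 1, auc_over_thresholds, scheme = scheme),
    bc = apply(nodal$bc, 1, auc_over_thresholds, scheme = scheme)
  )
  structure(
    list(subject_id = subject, global = global, nodal = nodal,
         global_auc = global_auc, nodal_auc = nodal_auc, scheme = scheme,
         disconnected = disconnected),
    class = "morph_curves"
  )
}

#' @export
print.morph_curves <- function(x, ...) {
  cat(sprintf(
    "<morph_curves> subject %s: %d thresholds [%.2f, %.2f]%s\n",
    x$subject_id %||% "?", length(x$scheme$thresholds),
    x$scheme$s_min, x$scheme$s_max,
    if (x$disconnected) " (disconnected at some thresholds)" else ""
  ))
  invisible(x)
}

#' Per-subject metric AUCs for a whole cohort
#'
#' Runs the full construction — shared grid, regional KDE distributions,
#' similarity matrix, sparsity sweep — for every subject and collects the
#' AUC summaries used by the group statistics.
#'
#' @param cohort A `morph_cohort` (or any list with a valid `voxels` table).
#' @param method `"JSDs"` or `"KLDs"`.
#' @param scheme A [sparsity_scheme()].
#' @param n_points KDE grid resolution.
#' @param n_null Null networks per threshold (0 skips gamma/lambda/sigma).
#' @param seed Base seed; subject `i` uses `seed + i` for its null models.
#' @param strict Propagated to the density estimation.
#' @return List with tibbles `global` (one row per subject: AUCs of each
#'   global metric) and `nodal` (one row per subject x node: AUCs of each
#'   nodal metric), both carrying `subject_id` and `group`.
#' @export
cohort_network_aucs <- function(cohort, method = c("JSDs", "KLDs"),
                                scheme = sparsity_scheme(),
                                n_points = 256L, n_null = 0L, seed = 1L,
                                strict = TRUE) {
  method <- match.arg(method)
  voxels <- cohort$voxels
  n_regions <- length(unique(voxels$region_id))
  groups <- dplyr::distinct(voxels, .data$subject_id, .data$group)
  subjects <- groups$subject_id

  per_subject <- purrr::imap(split(voxels, voxels$subject_id), function(v, id) {
    pmfs <- build_pmf_set(v, n_points = n_points, n_regions = n_regions,
                          strict = strict)
    sim <- build_similarity_matrix(pmfs, method = method)
    i <- match(id, subjects)
    subject_curves(sim, scheme = scheme, n_null = n_null, seed = seed + i)
  })
  per_subject <- per_subject[subjects]  # original subject order

  global <- purrr::map_dfr(per_subject, "global_auc", .id = "subject_id")
  nodal <- purrr::map_dfr(per_subject, "nodal_auc", .id = "subject_id")
  list(
    global = dplyr::left_join(groups, global, by = "subject_id"),
    nodal = dplyr::left_join(groups, nodal, by = "subject_id")
  )
}
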