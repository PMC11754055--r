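# Brute-force graph-metric oracles, deliberately naive and independent of
# the package's implementations: Floyd-Warshall distances, explicit triangle
# counts, and exhaustive simple-path enumeration for betweenness. Only ever
# used on tiny graphs (n <= 6 in the equivalence suites).

bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A != 0] <- 1
  diag(D) <- 0
  for (m in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, m] + D[m, j] < D[i, j]) D[i, j] <- D[i, m] + D[m, j]
  D
}

bf_local_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1))
      for (b in (a + 1):k)
        if (A[nb[a], nb[b]] != 0) links <- links + 1
    2 * links / (k * (k - 1))
  }, numeric(1))
}

bf_cp <- function(A) mean(bf_local_clustering(A))

bf_lp <- function(A) {
  D <- bf_distances(A)
  up <- D[upper.tri(D)]
  mean(up[is.finite(up)])
}

bf_eg <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- bf_distances(A)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

bf_ne <- function(A) {
  n <- nrow(A)
  D <- bf_distances(A)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

bf_nle <- function(A) {
  vapply(seq_len(nrow(A)), function(i) {
    nb <- which(A[i, ] != 0)
    if (length(nb) < 2) return(0)
    bf_eg(A[nb, nb, drop = FALSE])
  }, numeric(1))
}

# all simple paths from s to t, by depth-first enumeration
bf_simple_paths <- function(A, s, t) {
  paths <- list()
  recurse <- function(v, visited, path) {
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible(NULL))
    }
    for (w in which(A[v, ] != 0))
      if (!visited[w]) recurse(w, replace(visited, w, TRUE), c(path, w))
  }
  visited <- rep(FALSE, nrow(A))
  visited[s] <- TRUE
  recurse(s, visited, s)
  paths
}

# unnormalised betweenness: for each unordered pair, the fraction of
# shortest simple paths passing through v
bf_bc <- function(A) {
  n <- nrow(A)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- bf_simple_paths(A, s, t)
      if (!length(paths)) next
      lens <- lengths(paths) - 1
      geo <- paths[lens == min(lens)]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- vapply(geo, function(p) v %in% p, logical(1))
        bc[v] <- bc[v] + sum(through) / length(geo)
      }
    }
  }
  bc
}

# every non-isomorphic graph on 1..max_nodes nodes, as adjacency matrices
# (the igraph atlas enumerates all graphs up to 7 nodes, ordered by size)
atlas_graphs <- function(max_nodes = 6L) {
  counts <- c(1L, 2L, 4L, 11L, 34L, 156L, 1044L)  # graphs on 1..7 nodes
  idx_max <- sum(counts[seq_len(max_nodes)])
  lapply(seq_len(idx_max), function(i) {
    g <- igraph::graph_from_atlas(i)
    as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  })
}

# small named test graphs used across the metric tests
k4_adj <- function() matrix(1, 4, 4) - diag(4)
path4_adj <- function() {
  A <- matrix(0, 4, 4)
  A[cbind(1:3, 2:4)] <- 1
  A + t(A)
}
star4_adj <- function() {
  A <- matrix(0, 4, 4)
  A[1, 2:4] <- 1
  A + t(A)
}

# compact synthetic voxel table for distribution/similarity tests
tiny_voxels <- function(n_regions = 6, n_vox = 80, subject = "T01",
                        seed = 42, shift = numeric(n_regions)) {
  set.seed(seed)
  tibble::tibble(
    subject_id = subject,
    group = "control",
    region_id = rep(seq_len(n_regions), each = n_vox),
    value = abs(rnorm(n_regions * n_vox,
                      mean = rep(0.5 + shift, each = n_vox), sd = 0.1))
  )
}

small_cohort_config <- function(seed, n = 10L, n_regions = 12L,
                                effect_size = 0, variance_effect = 1,
                                effect_regions = integer(0),
                                voxels = c(60L, 120L)) {
  cohort_config(
    n_group1 = n, n_group2 = n, n_regions = n_regions,
    voxels_per_region = voxels, n_latent_factors = 3L,
    effect_regions = effect_regions, effect_size = effect_size,
    variance_effect = variance_effect, seed = seed
  )
}
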