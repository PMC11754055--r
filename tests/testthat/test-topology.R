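test_that("the default sparsity scheme has 36 thresholds", {
  sch <- sparsity_scheme()
  expect_length(sch$thresholds, 36L)
  expect_equal(sch$thresholds[1], 0.05)
  expect_equal(sch$thresholds[36], 0.40)
  expect_error(sparsity_scheme(0.4, 0.05), class = "morphnet_scheme_error")
  expect_error(sparsity_scheme(0, 0.4), class = "morphnet_scheme_error")
})

test_that("top-K thresholding keeps the expected edge counts and tie order", {
  set.seed(1)
  W <- matrix(runif(90 * 90), 90)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  expect_equal(threshold_at_sparsity(W, 0.05)$n_edges, 200)  # round(.05*4005)
  expect_equal(threshold_at_sparsity(W, 1)$n_edges, 4005)
  expect_error(threshold_at_sparsity(W, 0), class = "morphnet_scheme_error")
  # all-equal weights, N = 4, S = 0.5: the 3 lexicographically first pairs
  Weq <- matrix(1, 4, 4); diag(Weq) <- 0
  g <- threshold_at_sparsity(Weq, 0.5)
  expect_equal(g$n_edges, 3)
  expect_equal(which(g$adjacency[upper.tri(g$adjacency)] == 1), c(1L, 2L, 4L))
  # upper.tri order (1,2),(1,3),(2,3),(1,4): kept pairs (1,2),(1,3),(1,4)
})

test_that("global metrics match closed forms on canonical small graphs", {
  k4 <- binary_graph(k4_adj())
  p4 <- binary_graph(path4_adj())
  s4 <- binary_graph(star4_adj())
  expect_equal(clustering_coefficient(k4), 1.0)
  expect_equal(clustering_coefficient(p4), 0.0)
  # K4 minus one edge: local values 2/3, 2/3, 1, 1
  k4m <- k4_adj(); k4m[1, 2] <- k4m[2, 1] <- 0
  expect_equal(clustering_coefficient(binary_graph(k4m)), 5 / 6)
  expect_equal(as.numeric(characteristic_path_length(k4)), 1.0)
  expect_equal(as.numeric(characteristic_path_length(p4)), 5 / 3)
  expect_equal(global_efficiency(k4), 1.0)
  expect_equal(global_efficiency(p4), 13 / 18)
  expect_equal(local_efficiency(k4), 1.0)
  expect_equal(local_efficiency(s4), 0.0)
  expect_error(characteristic_path_length(
    binary_graph(matrix(0, 3, 3))), class = "morphnet_graph_error")
})

test_that("disconnected graphs average over reachable pairs and set the flag", {
  two_cliques <- matrix(0, 4, 4)
  two_cliques[1, 2] <- two_cliques[2, 1] <- 1
  two_cliques[3, 4] <- two_cliques[4, 3] <- 1
  lp <- characteristic_path_length(binary_graph(two_cliques))
  expect_equal(as.numeric(lp), 1.0)
  expect_true(attr(lp, "disconnected"))
  lp_conn <- characteristic_path_length(binary_graph(path4_adj()))
  expect_false(attr(lp_conn, "disconnected"))
})

test_that("nodal metrics match closed forms on the star and complete graph", {
  s4 <- nodal_metrics(binary_graph(star4_adj()))
  expect_equal(s4$ne[1], 1.0)          # center reaches all leaves directly
  expect_equal(s4$dc[1], 3)
  expect_equal(s4$bc[1], 3.0)          # center on all 3 leaf-pair geodesics
  expect_equal(s4$ne[2], 2 / 3)        # leaf distances 1, 2, 2
  expect_equal(s4$nle, rep(0, 4))
  k4 <- nodal_metrics(binary_graph(k4_adj()))
  expect_equal(k4$bc, rep(0, 4))
  expect_equal(k4$ne, rep(1, 4))
})

test_that("all metrics agree with brute force on every graph with <= 5 nodes", {
  for (A in atlas_graphs(5L)) {
    storage.mode(A) <- "integer"
    g <- binary_graph(A)
    expect_equal(clustering_coefficient(g), bf_cp(A), tolerance = 1e-12)
    expect_equal(global_efficiency(g), bf_eg(A), tolerance = 1e-12)
    expect_equal(local_efficiency(g), mean(bf_nle(A)), tolerance = 1e-12)
    if (g$n_edges > 0) {
      expect_equal(as.numeric(characteristic_path_length(g)), bf_lp(A),
                   tolerance = 1e-12)
    }
    nm <- nodal_metrics(g)
    expect_equal(nm$ne, bf_ne(A), tolerance = 1e-12)
    expect_equal(nm$nle, bf_nle(A), tolerance = 1e-12)
    expect_equal(nm$bc, bf_bc(A), tolerance = 1e-9)
    expect_equal(nm$dc, rowSums(A), ignore_attr = TRUE)
  }
})

test_that("degree-preserving rewiring preserves degrees, reproducibly", {
  set.seed(2)
  A <- matrix(rbinom(400, 1, 0.3), 20)
  A <- 1 * ((A + t(A)) > 0)
  diag(A) <- 0
  g <- binary_graph(A)
  null1 <- rewire_null(g, seed = 42)
  null2 <- rewire_null(g, seed = 42)
  expect_identical(null1$adjacency, null2$adjacency)
  expect_equal(sort(rowSums(null1$adjacency)), sort(rowSums(A)))
  expect_equal(diag(null1$adjacency), rep(0L, 20), ignore_attr = TRUE)
  # a triangle admits no legal swap
  k3 <- matrix(1, 3, 3) - diag(3)
  expect_identical(rewire_null(binary_graph(k3), seed = 1)$adjacency,
                   binary_graph(k3)$adjacency)
  expect_error(rewire_null(binary_graph(star4_adj() * 0)),
               class = "morphnet_graph_error")
})

test_that("sigma is exactly gamma over lambda", {
  set.seed(3)
  A <- matrix(rbinom(900, 1, 0.2), 30)
  A <- 1 * ((A + t(A)) > 0)
  diag(A) <- 0
  sw <- small_world(binary_graph(A), n_null = 20, seed = 5)
  expect_equal(sw$sigma, sw$gamma / sw$lambda, tolerance = 1e-12)
})

test_that("AUC integration matches closed-form integrals", {
  sch <- sparsity_scheme()
  expect_equal(auc_over_thresholds(rep(1, 36), sch), 0.35, tolerance = 1e-12)
  # values equal to the thresholds: integral of identity over [0.05, 0.40]
  expect_equal(auc_over_thresholds(sch$thresholds, sch),
               (0.40^2 - 0.05^2) / 2, tolerance = 1e-12)
  expect_error(auc_over_thresholds(c(1, 2), sch),
               class = "morphnet_scheme_error")
  expect_error(
    auc_over_thresholds(1, sparsity_scheme(0.05, 0.06, 0.01)),
    class = "morphnet_scheme_error")
})

test_that("thresholded edge sets are nested and Eg grows with sparsity", {
  pm <- build_pmf_set(tiny_voxels(n_regions = 15, n_vox = 60, seed = 13),
                      n_points = 64, n_regions = 15)
  sim <- build_similarity_matrix(pm, "JSDs")
  g_lo <- threshold_at_sparsity(sim, 0.10)
  g_hi <- threshold_at_sparsity(sim, 0.40)
  expect_true(all(g_hi$adjacency[g_lo$adjacency == 1] == 1))
  sch <- sparsity_scheme(0.10, 0.40, 0.05)
  cur <- subject_curves(sim, scheme = sch, n_null = 0)
  expect_true(all(diff(cur$global$eg) >= 0))
})

test_that("subject curves cover every metric at every threshold without NaN", {
  pm <- build_pmf_set(tiny_voxels(n_regions = 90, n_vox = 40, seed = 17),
                      n_points = 64, n_regions = 90)
  sim <- build_similarity_matrix(pm, "JSDs")
  cur <- subject_curves(sim, n_null = 2, seed = 9)
  expect_equal(nrow(cur$global), 36L)
  expect_named(cur$global, c("threshold", "cp", "lp", "gamma", "lambda",
                             "sigma", "eg", "eloc"))
  expect_true(all(is.finite(as.matrix(cur$global))))
  expect_true(all(vapply(cur$nodal, function(m) all(is.finite(m)),
                         logical(1))))
  expect_equal(cur$global$sigma, cur$global$gamma / cur$global$lambda,
               tolerance = 1e-12)
  expect_equal(dim(cur$nodal$ne), c(90L, 36L))
  # determinism under a fixed seed
  cur2 <- subject_curves(sim, n_null = 2, seed = 9)
  expect_identical(cur$global, cur2$global)
  # tidy/glance accessors agree with the stored curves
  td <- tidy(cur, which = "global")
  expect_equal(nrow(td), 36L * 7L)
  gl <- glance(cur)
  expect_equal(gl$auc[gl$metric == "eg"], cur$global_auc$eg)
})

test_that("the sweep agrees with the per-threshold module functions", {
  pm <- build_pmf_set(tiny_voxels(n_regions = 12, n_vox = 40, seed = 23),
                      n_points = 64, n_regions = 12)
  sim <- build_similarity_matrix(pm, "JSDs")
  cur <- subject_curves(sim, n_null = 0)
  for (S in c(0.05, 0.20, 0.40)) {
    i <- which(abs(cur$scheme$thresholds - S) < 1e-9)
    g <- threshold_at_sparsity(sim, S)
    expect_equal(cur$global$cp[i], clustering_coefficient(g),
                 tolerance = 1e-12)
    expect_equal(cur$global$eloc[i], local_efficiency(g), tolerance = 1e-12)
    nm <- nodal_metrics(g)
    expect_equal(cur$nodal$bc[, i], nm$bc, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(cur$nodal$ne[, i], nm$ne, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})
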