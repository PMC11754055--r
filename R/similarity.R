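# shared input checks for the pairwise divergence operations
check_pmf_pair <- function(P, Q, tol = 1e-9) {
  if (length(P) != length(Q)) {
    abort("P and Q must have the same length", class = "morphnet_pmf_error")
  }
  if (any(P < 0) || any(Q < 0) ||
      abs(sum(P) - 1) > tol || abs(sum(Q) - 1) > tol) {
    abort("P and Q must be non-negative and sum to 1",
          class = "morphnet_pmf_error")
  }
  invisible(NULL)
}

# Shannon entropy in bits with the 0 log 0 = 0 convention
entropy_bits <- function(p) {
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Jensen-Shannon divergence-based similarity
#'
#' The JSD between two discrete distributions, with base-2 logarithms, is
#' `JSD(P, Q) = H(M) - (H(P) + H(Q)) / 2` where `M = (P + Q) / 2` and `H` is
#' Shannon entropy in bits; it is symmetric and bounded in `[0, 1]`. The
#' similarity used as an edge weight is `1 - JSD` (optionally
#' `1 - sqrt(JSD)`, the metric form), so identical regional distributions
#' score 1 and disjoint-support distributions score 0.
#'
#' @param P,Q Discrete distributions on the same grid (non-negative, each
#'   summing to 1 within 1e-9).
#' @param transform `"one_minus_jsd"` (default) or `"one_minus_sqrt_jsd"`.
#' @return Similarity in `[0, 1]`.
#' @examples
#' jsd_similarity(c(0.5, 0.5, 0), c(0, 0.5, 0.5))  # 0.5
#' @export
jsd_similarity <- function(P, Q,
                           transform = c("one_minus_jsd",
                                         "one_minus_sqrt_jsd")) {
  transform <- match.arg(transform)
  check_pmf_pair(P, Q)
  jsd <- entropy_bits((P + Q) / 2) - (entropy_bits(P) + entropy_bits(Q)) / 2
  jsd <- min(max(jsd, 0), 1)  # clamp float jitter at the boundary
  if (transform == "one_minus_sqrt_jsd") 1 - sqrt(jsd) else 1 - jsd
}

#' Symmetric Kullback-Leibler divergence-based similarity
#'
#' Zero entries are floored at `eps` and rows renormalised (KL is undefined
#' where `Q` has zeros), then the similarity is
#' `exp(-(KL(P || Q) + KL(Q || P)))` with natural logarithms: symmetric,
#' bounded in `(0, 1]`, and exactly 1 iff the floored distributions are
#' equal.
#'
#' @inheritParams jsd_similarity
#' @param eps Flooring constant applied before taking logarithms.
#' @return Similarity in `(0, 1]`.
#' @examples
#' kld_similarity(c(0.5, 0.5), c(0.25, 0.75))  # exp(-0.274653) = 0.75984
#' @export
kld_similarity <- function(P, Q, eps = 1e-12) {
  check_pmf_pair(P, Q)
  P <- pmax(P, eps); P <- P / sum(P)
  Q <- pmax(Q, eps); Q <- Q / sum(Q)
  # KL(P||Q) + KL(Q||P) collapses to sum (p - q)(log p - log q) >= 0
  sym_kl <- sum((P - Q) * (log(P) - log(Q)))
  exp(-sym_kl)
}

#' Build an individual similarity network
#'
#' Evaluates the chosen divergence-based similarity for every unordered pair
#' of a subject's regional distributions, producing the symmetric
#' region-by-region edge-weight matrix of the individual morphological brain
#' network. The diagonal is 0: self-similarity is not an edge and never
#' enters thresholding.
#'
#' @param pmf_set A `morph_pmf_set` from [build_pmf_set()].
#' @param method `"JSDs"` (Jensen-Shannon based, default) or `"KLDs"`
#'   (symmetric Kullback-Leibler based).
#' @param jsd_transform Passed to [jsd_similarity()] when `method = "JSDs"`.
#' @return A `morph_similarity`: list with `subject_id`, `method` and
#'   `weights` (symmetric matrix, zero diagonal, region labels as dimnames).
#' @export
build_similarity_matrix <- function(pmf_set, method = c("JSDs", "KLDs"),
                                    jsd_transform = c("one_minus_jsd",
                                                      "one_minus_sqrt_jsd")) {
  stopifnot(inherits(pmf_set, "morph_pmf_set"))
  method <- match.arg(method)
  jsd_transform <- match.arg(jsd_transform)
  X <- pmf_set$pmf
  R <- nrow(X)
  W <- matrix(0, R, R, dimnames = list(rownames(X), rownames(X)))

  if (method == "JSDs") {
    H <- apply(X, 1L, entropy_bits)
    for (i in seq_len(R - 1L)) {
      js <- (i + 1L):R
      M <- (X[js, , drop = FALSE] +
              matrix(X[i, ], length(js), ncol(X), byrow = TRUE)) / 2
      Hm <- apply(M, 1L, entropy_bits)
      jsd <- pmin(pmax(Hm - (H[i] + H[js]) / 2, 0), 1)
      W[i, js] <- if (jsd_transform == "one_minus_sqrt_jsd") 1 - sqrt(jsd)
                  else 1 - jsd
    }
  } else {
    eps <- 1e-12
    Xf <- pmax(X, eps)
    Xf <- Xf / rowSums(Xf)
    L <- log(Xf)
    for (i in seq_len(R - 1L)) {
      js <- (i + 1L):R
      dP <- Xf[js, , drop = FALSE] -
        matrix(Xf[i, ], length(js), ncol(X), byrow = TRUE)
      dL <- L[js, , drop = FALSE] -
        matrix(L[i, ], length(js), ncol(X), byrow = TRUE)
      W[i, js] <- exp(-rowSums(dP * dL))
    }
  }
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  structure(list(subject_id = pmf_set$subject_id, method = method,
                 weights = W),
            class = "morph_similarity")
}

#' @export
print.morph_similarity <- function(x, ...) {
  w <- x$weights[upper.tri(x$weights)]
  cat(sprintf(
    "<morph_similarity> subject %s, %s: %d x %d, edge weights [%.3f, %.3f]\n",
    x$subject_id, x$method, nrow(x$weights), ncol(x$weights),
    min(w), max(w)
  ))
  invisible(x)
}

#' Write a similarity matrix as a labelled square TSV
#'
#' @param sim A `morph_similarity`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(sim, path) {
  stopifnot(inherits(sim, "morph_similarity"))
  tbl <- tibble::as_tibble(sim$weights, .name_repair = "minimal")
  tbl <- dplyr::bind_cols(tibble::tibble(region = rownames(sim$weights)), tbl)
  readr::write_tsv(tbl, path)
  invisible(path)
}
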