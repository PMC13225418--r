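#' Cluster the final embedding into spatial domains
#'
#' Fits a Gaussian mixture model with shared full covariance (mclust model
#' "EEE") to the embedding by EM and assigns each spot to the maximum
#' posterior component. mclust's hierarchical initialization makes the fit
#' deterministic for a given embedding; `seed` governs only the k-means
#' fallback used if the EEE fit degenerates.
#'
#' @param E n x d embedding matrix (or a `TrainResult`).
#' @param n_domains number of domains (>= 2).
#' @param seed integer seed for the fallback initialization.
#' @return `DomainLabels` list: integer `labels` in `0..n_domains-1`,
#'   `n_domains`, `method`, and `posterior` (n x k, rows sum to 1).
#' @export
cluster_embedding <- function(E, n_domains, seed = 100L) {
  if (inherits(E, "TrainResult")) E <- E$E_final
  E <- as.matrix(E)
  if (n_domains < 2L) stop("n_domains must be >= 2")
  if (any(!is.finite(E))) stop("embedding must be finite")
  # Mclust resolves helpers like mclustBIC in the caller's scope; make them
  # visible without requiring the package to be attached
  mclustBIC <- mclust::mclustBIC
  fit <- tryCatch(
    mclust::Mclust(E, G = n_domains, modelNames = "EEE", verbose = FALSE),
    error = function(e) NULL)
  if (!is.null(fit) && !is.null(fit$classification)) {
    labels <- as.integer(fit$classification) - 1L
    post <- fit$z
    method <- "gmm_eee"
  } else {
    # degenerate EM fit: one seeded k-means restart, then give up
    set_global_seed(seed + 1L)
    km <- tryCatch(stats::kmeans(E, centers = n_domains, nstart = 10L),
                   error = function(e) NULL)
    if (is.null(km)) stop("clustering failed: degenerate GMM and k-means fallback")
    labels <- as.integer(km$cluster) - 1L
    post <- matrix(0, nrow(E), n_domains)
    post[cbind(seq_len(nrow(E)), labels + 1L)] <- 1
    method <- "kmeans_fallback"
  }
  structure(list(labels = labels, n_domains = as.integer(n_domains),
                 method = method, posterior = post),
            class = "DomainLabels")
}

contingency <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  table(factor(a), factor(b))
}

#' Adjusted Rand Index
#'
#' Chance-adjusted pair-counting agreement between two labelings; 1 for
#' identical partitions, ~0 for random agreement. Invariant to label
#' permutation.
#'
#' @param true,pred equal-length label vectors.
#' @return ARI in \[-1, 1\].
#' @export
score_ari <- function(true, pred) {
  ct <- contingency(true, pred)
  n <- sum(ct)
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (max_index - expected)
}

entropy_ <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized Mutual Information
#'
#' Mutual information between the two labelings divided by the arithmetic
#' mean of their entropies; in \[0, 1\], and 0 when either labeling is a
#' single cluster.
#'
#' @inheritParams score_ari
#' @return NMI in \[0, 1\].
#' @export
score_nmi <- function(true, pred) {
  ct <- contingency(true, pred)
  n <- sum(ct)
  pij <- ct / n
  pi_ <- rowSums(pij); pj <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj)[nz]))
  denom <- (entropy_(pi_) + entropy_(pj)) / 2
  if (denom == 0) return(0)
  mi / denom
}

#' Fowlkes-Mallows Index
#'
#' `FMI = TP / sqrt((TP + FP)(TP + FN))` over co-membership spot pairs.
#' Returns 0 with a warning when either labeling has no same-cluster pair.
#'
#' @inheritParams score_ari
#' @return FMI in \[0, 1\].
#' @export
score_fmi <- function(true, pred) {
  ct <- contingency(true, pred)
  tp <- sum(choose(ct, 2))
  pairs_a <- sum(choose(rowSums(ct), 2))
  pairs_b <- sum(choose(colSums(ct), 2))
  if (pairs_a == 0 || pairs_b == 0) {
    warning("degenerate labeling: no same-cluster pairs")
    return(0)
  }
  tp / sqrt(pairs_a * pairs_b)
}

#' All three clustering agreement scores
#'
#' @inheritParams score_ari
#' @return named list with `ari`, `nmi`, `fmi`.
#' @export
score_clustering <- function(true, pred) {
  list(ari = score_ari(true, pred), nmi = score_nmi(true, pred),
       fmi = score_fmi(true, pred))
}
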