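#' Spatial adjacency matrix from spot coordinates
#'
#' Two spots are adjacent when the Euclidean distance between their centers
#' is strictly smaller than the radius `r`. The diagonal is 1 (a spot is at
#' distance 0 from itself).
#'
#' @param coords numeric matrix, one row per spot, columns x and y
#'   (full-resolution pixel units).
#' @param r positive radius in the same units as `coords`.
#' @return binary integer matrix, n x n, symmetric.
#' @export
spatial_adjacency <- function(coords, r) {
  coords <- as.matrix(coords)
  if (!is.numeric(r) || length(r) != 1L || r <= 0) stop("radius r must be a positive scalar")
  if (any(!is.finite(coords))) stop("coords must be finite")
  D <- as.matrix(stats::dist(coords))
  A <- (D < r) * 1L
  storage.mode(A) <- "integer"
  dimnames(A) <- NULL
  if (any(rowSums(A) == 1L)) {
    warning("spatial_adjacency: ", sum(rowSums(A) == 1L),
            " spot(s) have no neighbor within r (only self)")
  }
  A
}

#' Row-wise cosine similarity matrix
#'
#' `S[i, j] = x_i . x_j / (|x_i| |x_j|)`. Rows with zero norm get similarity
#' 0 to everything (with a warning); the diagonal is set to 1.
#'
#' @param X numeric matrix (spots x features).
#' @return symmetric n x n similarity matrix with unit diagonal.
#' @export
cosine_similarity <- function(X) {
  X <- as.matrix(X)
  nrm <- sqrt(rowSums(X^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning("cosine_similarity: ", sum(zero), " zero row(s); similarities set to 0")
    nrm[zero] <- 1
  }
  S <- tcrossprod(X / nrm)
  S[zero, ] <- 0; S[, zero] <- 0
  diag(S) <- 1
  S
}

#' Row-wise Pearson correlation matrix
#'
#' Pearson correlation between the feature vectors of every pair of spots
#' (rows of `M`). Zero-variance rows get correlation 0 with a warning; the
#' diagonal is 1.
#'
#' @param M numeric matrix (spots x features), at least 2 columns.
#' @return symmetric n x n correlation matrix.
#' @export
pearson_similarity <- function(M) {
  M <- as.matrix(M)
  if (ncol(M) < 2L) stop("pearson_similarity needs at least 2 feature columns")
  v <- apply(M, 1L, stats::var)
  zero <- v == 0
  Mc <- M - rowMeans(M)
  nrm <- sqrt(rowSums(Mc^2))
  nrm[zero] <- 1
  if (any(zero)) {
    warning("pearson_similarity: ", sum(zero), " zero-variance row(s); similarities set to 0")
  }
  S <- tcrossprod(Mc / nrm)
  S[zero, ] <- 0; S[, zero] <- 0
  diag(S) <- 1
  S
}

#' k-nearest-neighbor adjacency from a similarity matrix
#'
#' For each spot the `k` most similar other spots (self excluded) become its
#' neighbors; ties are broken toward the smaller spot index so the graph is
#' reproducible. By default the directed kNN relation is symmetrized by
#' logical OR so that the symmetric normalization is well defined; the
#' directed variant is available with `symmetrize = "none"`. The diagonal is
#' set to 1 afterwards (uniform self-loops across all graphs).
#'
#' @param S symmetric similarity matrix.
#' @param k number of neighbors, `1 <= k < n`.
#' @param symmetrize `"or"` (default) or `"none"`.
#' @return binary integer adjacency matrix.
#' @export
knn_adjacency <- function(S, k, symmetrize = c("or", "none")) {
  symmetrize <- match.arg(symmetrize)
  S <- as.matrix(S)
  n <- nrow(S)
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < n")
  A <- matrix(0L, n, n)
  idx <- seq_len(n)
  for (i in idx) {
    s <- S[i, ]
    s[i] <- -Inf
    top <- order(-s, idx)[seq_len(k)]
    A[i, top] <- 1L
  }
  if (symmetrize == "or") A <- (A | t(A)) * 1L
  storage.mode(A) <- "integer"
  diag(A) <- 1L
  A
}

#' Symmetric normalization of an adjacency matrix
#'
#' Computes `D^{-1/2} A D^{-1/2}` with `D` the degree matrix of `A`. Self
#' loops must be present (they guarantee nonzero degree); the spectral
#' radius of the result is at most 1.
#'
#' @param A square nonnegative adjacency matrix with self-loops.
#' @return dense symmetric real matrix.
#' @export
symmetric_normalize <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("A must be square")
  if (any(A < 0)) stop("A must be nonnegative")
  d <- rowSums(A)
  if (any(d == 0)) stop("zero-degree row without self-loop; add self-loops first")
  inv_sqrt <- 1 / sqrt(d)
  A * outer(inv_sqrt, inv_sqrt)
}

neighbor_sets <- function(A) {
  n <- nrow(A)
  lapply(seq_len(n), function(i) {
    j <- which(A[i, ] != 0)
    j[j != i]
  })
}

#' Build the three-view graph bundle
#'
#' Constructs the spatial (radius) adjacency `A_s`, the expression
#' (cosine-kNN) adjacency `A_f` and, when morphological features are given,
#' the morphological (Pearson-kNN) adjacency `A_m`, together with their
#' symmetric normalizations and per-spot neighbor sets (used by the
#' regularization loss). When `r` is `NULL` it defaults to 1.3 times the
#' minimum nonzero pairwise spot distance, which captures the six hexagonal
#' neighbors on a Visium-style array and the four rook neighbors on a square
#' lattice.
#'
#' @param X normalized expression matrix (spots x genes).
#' @param coords spot coordinates (spots x 2).
#' @param M optional morphological feature matrix (spots x d) or a
#'   `MorphFeatureMatrix`; `NULL` switches to image-free mode.
#' @param k_expr,k_morph neighbor counts for the expression and
#'   morphological kNN graphs.
#' @param r spatial radius; `NULL` for the data-driven default.
#' @param symmetrize kNN symmetrization mode, see [knn_adjacency()].
#' @return an object of class `GraphBundle`.
#' @export
build_graph_bundle <- function(X, coords, M = NULL, k_expr = 10L, k_morph = 10L,
                               r = NULL, symmetrize = "or") {
  X <- as.matrix(X); coords <- as.matrix(coords)
  if (nrow(X) != nrow(coords)) stop("X and coords must be row-aligned")
  if (inherits(M, "MorphFeatureMatrix")) M <- M$M
  if (!is.null(M) && nrow(as.matrix(M)) != nrow(X)) stop("M must be row-aligned with X")
  if (is.null(r)) {
    D <- stats::dist(coords)
    r <- 1.3 * min(D[D > 0])
  }
  A_s <- spatial_adjacency(coords, r)
  A_f <- knn_adjacency(cosine_similarity(X), k_expr, symmetrize = symmetrize)
  A_m <- if (!is.null(M)) {
    knn_adjacency(pearson_similarity(as.matrix(M)), k_morph, symmetrize = symmetrize)
  } else NULL
  gb <- list(
    A_s = A_s, A_f = A_f, A_m = A_m,
    A_s_norm = symmetric_normalize(A_s),
    A_f_norm = symmetric_normalize(A_f),
    A_m_norm = if (!is.null(A_m)) symmetric_normalize(A_m) else NULL,
    radius_r = r, k_expr = k_expr, k_morph = k_morph,
    neighbor_sets = list(
      s = neighbor_sets(A_s),
      f = neighbor_sets(A_f),
      m = if (!is.null(A_m)) neighbor_sets(A_m) else NULL
    )
  )
  class(gb) <- "GraphBundle"
  gb
}

#' @export
print.GraphBundle <- function(x, ...) {
  n <- nrow(x$A_s)
  cat("GraphBundle:", n, "spots; r =", signif(x$radius_r, 4),
      "; k_expr =", x$k_expr,
      if (!is.null(x$A_m)) paste0("; k_morph = ", x$k_morph) else "; (image-free)",
      "\n")
  invisible(x)
}

#' Export a graph bundle's adjacencies
#'
#' Writes each adjacency as a MatrixMarket sparse matrix plus a 0-based
#' edge-list TSV, and a JSON provenance sidecar recording `r` and `k`.
#'
#' @param gb a `GraphBundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_graph_bundle <- function(gb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mats <- list(A_s = gb$A_s, A_f = gb$A_f, A_m = gb$A_m)
  for (nm in names(mats)) {
    A <- mats[[nm]]
    if (is.null(A)) next
    Matrix::writeMM(methods::as(Matrix::Matrix(A * 1, sparse = TRUE), "generalMatrix"),
                    file.path(dir, paste0(nm, ".mtx")))
    ij <- which(A != 0, arr.ind = TRUE)
    utils::write.table(data.frame(from = ij[, 1] - 1L, to = ij[, 2] - 1L),
                       file.path(dir, paste0(nm, "_edges.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(radius_r = gb$radius_r, k_expr = gb$k_expr, k_morph = gb$k_morph),
    file.path(dir, "graph_provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
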