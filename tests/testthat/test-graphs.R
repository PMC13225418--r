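test_that("spatial adjacency thresholds strictly at the radius", {
  coords <- rbind(c(0, 0), c(3, 4))   # distance 5
  expect_equal(spatial_adjacency(coords, 10), matrix(1L, 2, 2))
  A <- suppressWarnings(spatial_adjacency(coords, 5))   # boundary: d == r is NOT adjacent
  expect_equal(A, diag(2L))
  expect_error(spatial_adjacency(coords, 0), "positive")
})

test_that("spatial adjacency matches brute-force thresholding on random points", {
  set.seed(7)
  coords <- matrix(runif(100, 0, 10), 50, 2)
  r <- 2.5
  A <- suppressWarnings(spatial_adjacency(coords, r))
  B <- matrix(0L, 50, 50)
  for (i in 1:50) for (j in 1:50) {
    if (sqrt(sum((coords[i, ] - coords[j, ])^2)) < r) B[i, j] <- 1L
  }
  expect_identical(unname(A), B)
})

test_that("spatial adjacency is invariant to rigid motions", {
  set.seed(8)
  coords <- matrix(runif(60), 30, 2)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- coords %*% R + matrix(c(5, -3), 30, 2, byrow = TRUE)
  expect_equal(suppressWarnings(spatial_adjacency(coords, 0.2)),
               suppressWarnings(spatial_adjacency(moved, 0.2)))
})

test_that("cosine similarity matches its formula and is scale invariant", {
  X <- rbind(c(1, 2), c(2, 4), c(2, -1))
  S <- cosine_similarity(X)
  expect_equal(S[1, 2], 1)                 # parallel rows
  expect_equal(S[1, 3], 0)                 # orthogonal rows
  expect_equal(S, t(S))
  expect_equal(diag(S), rep(1, 3))
  # positive row rescaling leaves the kNN graph unchanged
  D <- diag(c(2, 0.5, 7))
  expect_equal(cosine_similarity(D %*% X), S)
  expect_warning(cosine_similarity(rbind(c(0, 0), c(1, 1))), "zero row")
})

test_that("pearson similarity equals the textbook covariance formula", {
  set.seed(9)
  M <- matrix(rnorm(50), 10, 5)
  S <- pearson_similarity(M)
  for (i in 1:10) for (j in 1:10) {
    expect_equal(S[i, j], if (i == j) 1 else
      stats::cov(M[i, ], M[j, ]) / (stats::sd(M[i, ]) * stats::sd(M[j, ])),
      tolerance = 1e-12)
  }
  expect_equal(pearson_similarity(rbind(M[1, ], -M[1, ] + 3))[1, 2], -1)
})

test_that("kNN adjacency picks the top-k with index tie-breaks and OR-symmetrization", {
  S <- rbind(c(1, .9, .1), c(.2, 1, .8), c(.9, .3, 1))
  A <- knn_adjacency(S, 1, symmetrize = "none")
  expect_equal(unname(A), rbind(c(1L, 1L, 0L), c(0L, 1L, 1L), c(1L, 0L, 1L)))
  A2 <- knn_adjacency(S, 1)
  expect_equal(unname(A2), rbind(c(1L, 1L, 1L), c(1L, 1L, 1L), c(1L, 1L, 1L)))
  expect_equal(unname(knn_adjacency(S, 2)), matrix(1L, 3, 3))   # k = n-1: complete
  # tie between columns 2 and 3 resolves to the smaller index
  St <- rbind(c(1, .5, .5, .1), c(.5, 1, .1, .1), c(.5, .1, 1, .1), c(.1, .1, .1, 1))
  expect_equal(which(knn_adjacency(St, 1, symmetrize = "none")[1, ] == 1L), c(1L, 2L))
  expect_error(knn_adjacency(S, 3), "k must")
})

test_that("kNN construction is permutation-equivariant", {
  set.seed(10)
  X <- matrix(runif(80, 0.1, 1), 20, 4)
  S <- cosine_similarity(X)
  A <- knn_adjacency(S, 4)
  perm <- sample(20)
  Ap <- knn_adjacency(cosine_similarity(X[perm, ]), 4)
  expect_equal(unname(Ap), unname(A[perm, perm]))
})

test_that("pre-symmetrization rows have exactly k neighbors, and at least k after OR", {
  set.seed(11)
  S <- cosine_similarity(matrix(runif(200, 0.1, 1), 40, 5))
  k <- 6
  A_dir <- knn_adjacency(S, k, symmetrize = "none")
  expect_true(all(rowSums(A_dir) - 1L == k))       # minus the self-loop
  A_or <- knn_adjacency(S, k)
  expect_true(all(rowSums(A_or) - 1L >= k))
})

test_that("symmetric normalization equals D^-1/2 A D^-1/2 with bounded spectrum", {
  expect_equal(symmetric_normalize(diag(3)), diag(3))
  A2 <- matrix(1, 2, 2)
  expect_equal(symmetric_normalize(A2), matrix(0.5, 2, 2))
  set.seed(12)
  A <- suppressWarnings(spatial_adjacency(matrix(runif(60, 0, 5), 30, 2), 1.2))
  An <- symmetric_normalize(A)
  D <- diag(1 / sqrt(rowSums(A)))
  expect_equal(An, D %*% A %*% D)
  ev <- eigen(An, symmetric = TRUE, only.values = TRUE)$values
  expect_lte(max(abs(ev)), 1 + 1e-8)
  expect_equal(An, t(An))
  expect_error(symmetric_normalize(matrix(0, 2, 2)), "zero-degree")
})

test_that("graph bundle composes the three views and records provenance", {
  set.seed(13)
  ds <- tiny_dataset()
  fm <- preprocess_dataset(ds, n_top = 60L)
  M <- matrix(rnorm(nrow(fm$X) * 5), ncol = 5)
  gb <- build_graph_bundle(fm$X, fm$dataset$coords, M = M, k_expr = 5L, k_morph = 5L)
  n <- nrow(fm$X)
  expect_equal(dim(gb$A_s), c(n, n))
  # default radius captures the lattice rook neighbors: 4 + self in the interior
  expect_equal(max(rowSums(gb$A_s)), 5)
  expect_equal(gb$radius_r, 1.3 * 6)   # 1.3 x lattice step (6 px/spot)
  # brute-force rebuild of each piece
  expect_equal(gb$A_f, knn_adjacency(cosine_similarity(fm$X), 5L))
  expect_equal(gb$A_m, knn_adjacency(pearson_similarity(M), 5L))
  expect_equal(gb$A_s_norm, symmetric_normalize(gb$A_s))
  # neighbor sets exclude self and match the adjacency
  expect_true(all(vapply(seq_len(n), function(i)
    setequal(gb$neighbor_sets$f[[i]], setdiff(which(gb$A_f[i, ] == 1L), i)), TRUE)))
  # image-free mode
  gb0 <- build_graph_bundle(fm$X, fm$dataset$coords, M = NULL, k_expr = 5L)
  expect_null(gb0$A_m)
  expect_null(gb0$A_m_norm)
})

test_that("expression graph is invariant to positive row rescaling of X", {
  set.seed(14)
  X <- matrix(runif(120, 0.1, 2), 30, 4)
  sc <- runif(30, 0.5, 3)
  b1 <- knn_adjacency(cosine_similarity(X), 4L)
  b2 <- knn_adjacency(cosine_similarity(X * sc), 4L)
  expect_equal(b1, b2)
})

test_that("adjacencies export as MTX, edge lists and provenance sidecar", {
  set.seed(15)
  X <- matrix(runif(40, 0.1, 1), 10, 4)
  gb <- suppressWarnings(
    build_graph_bundle(X, matrix(runif(20, 0, 5), 10, 2), k_expr = 3L, r = 2))
  dir <- withr::local_tempdir()
  export_graph_bundle(gb, dir)
  expect_true(all(file.exists(file.path(dir,
    c("A_s.mtx", "A_f.mtx", "A_s_edges.tsv", "graph_provenance.json")))))
  # binary adjacencies round-trip through MTX pattern form
  back <- as.matrix(Matrix::readMM(file.path(dir, "A_f.mtx"))) * 1L
  expect_equal(unname(back), unname(gb$A_f), ignore_attr = TRUE)
  prov <- jsonlite::read_json(file.path(dir, "graph_provenance.json"))
  expect_equal(prov$k_expr, 3L)
})
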