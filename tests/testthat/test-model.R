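test_that("gcn layer follows the propagation rule exactly", {
  set.seed(50)
  E <- matrix(runif(20), 5, 4)
  # identity graph, identity weights: output equals nonnegative input
  expect_equal(gcn_layer(diag(5), E, diag(4)), E)
  # nonpositive input through ReLU: all zeros
  A <- symmetric_normalize(matrix(1, 5, 5))
  expect_equal(gcn_layer(A, -E, diag(4)), matrix(0, 5, 4))
  # random instance vs hand-rolled dense product
  W <- matrix(rnorm(12), 4, 3)
  An <- symmetric_normalize(suppressWarnings(spatial_adjacency(matrix(runif(10), 5, 2), 0.5)))
  expect_equal(gcn_layer(An, E, W), pmax(An %*% E %*% W, 0), tolerance = 1e-10)
  expect_equal(gcn_layer(An, E, W, activate = FALSE), An %*% E %*% W, tolerance = 1e-10)
})

make_small_model <- function(n = 12, g = 20, seed = 60) {
  set_global_seed(seed)
  X <- matrix(runif(n * g, 0, 4), n, g)
  coords <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  M <- matrix(rnorm(n * 6), n, 6)
  bundle <- suppressWarnings(
    build_graph_bundle(X, coords, M = M, k_expr = 3L, k_morph = 3L, r = 4))
  params <- init_params(g, dims = c(8L, 6L), d_hidden = 4L, decoder_hidden = 7L)
  list(X = X, bundle = bundle, params = params)
}

test_that("encoder produces aligned view embeddings with exact collaborative mean", {
  m <- make_small_model()
  emb <- encode(m$X, m$bundle, m$params)
  for (nm in c("E_s", "E_f", "E_m", "E_cs", "E_cf", "E_cm", "E_c")) {
    expect_equal(dim(emb[[nm]]), c(12, 6))
  }
  expect_equal(emb$E_c, (emb$E_cs + emb$E_cf + emb$E_cm) / 3)
  # identity graphs + identical weights collapse all branches
  p2 <- m$params
  for (v in c("s", "f", "m")) {
    p2[[paste0("W_", v, "1")]] <- p2$W_c1
    p2[[paste0("W_", v, "2")]] <- p2$W_c2
  }
  idb <- m$bundle
  idb$A_s_norm <- idb$A_f_norm <- idb$A_m_norm <- diag(12)
  emb2 <- encode(m$X, idb, p2)
  expect_equal(emb2$E_s, emb2$E_f)
  expect_equal(emb2$E_s, emb2$E_m)
  expect_equal(emb2$E_s, emb2$E_c)
})

test_that("the whole encoder is permutation-equivariant", {
  m <- make_small_model()
  emb <- encode(m$X, m$bundle, m$params)
  fus <- attention_fuse(list(s = emb$E_s, f = emb$E_f, m = emb$E_m, c = emb$E_c), m$params)
  perm <- sample(12)
  pb <- m$bundle
  for (nm in c("A_s_norm", "A_f_norm", "A_m_norm")) pb[[nm]] <- pb[[nm]][perm, perm]
  emb_p <- encode(m$X[perm, ], pb, m$params)
  fus_p <- attention_fuse(list(s = emb_p$E_s, f = emb_p$E_f, m = emb_p$E_m, c = emb_p$E_c),
                          m$params)
  expect_equal(emb_p$E_s, emb$E_s[perm, ], tolerance = 1e-10)
  expect_equal(fus_p$E_final, fus$E_final[perm, ], tolerance = 1e-10)
})

test_that("attention weights match a scalar-loop oracle and sum to one", {
  m <- make_small_model()
  emb <- encode(m$X, m$bundle, m$params)
  E_list <- list(s = emb$E_s, f = emb$E_f, m = emb$E_m, c = emb$E_c)
  fus <- attention_fuse(E_list, m$params)
  expect_equal(unname(rowSums(fus$omega)), rep(1, 12), tolerance = 1e-6)
  expect_true(all(fus$omega >= 0))
  # scalar-loop oracle per spot and view
  W1 <- m$params$W1; b1 <- m$params$b1; W2 <- m$params$W2
  for (i in 1:12) {
    raw <- vapply(E_list, function(E) {
      as.numeric(W2 %*% tanh(W1 %*% E[i, ] + b1))
    }, 1)
    w <- exp(raw - max(raw)); w <- w / sum(w)
    expect_equal(unname(fus$omega[i, ]), unname(w), tolerance = 1e-6)
    ef <- Reduce(`+`, Map(function(E, wv) wv * E[i, ], E_list, as.list(w)))
    expect_equal(unname(fus$E_fusion[i, ]), unname(ef), tolerance = 1e-6)
  }
  expect_equal(fus$E_final,
               fus$E_fusion %*% m$params$W_linear +
                 matrix(m$params$b_linear, 12, 6, byrow = TRUE),
               tolerance = 1e-10)
})

test_that("attention degenerates correctly for equal and dominant scores", {
  # all raw scores equal -> uniform weights
  n <- 5; d <- 6
  E <- matrix(0.3, n, d)
  p <- init_params(4, dims = c(3L, d), d_hidden = 4L)
  fus <- attention_fuse(list(s = E, f = E, m = E, c = E), p)
  expect_equal(unname(fus$omega), matrix(0.25, n, 4), tolerance = 1e-12)
  expect_error(attention_fuse(list(s = E), p), "at least 2")
})

test_that("NB decoder outputs strictly positive finite mu and theta", {
  m <- make_small_model()
  emb <- encode(m$X, m$bundle, m$params)
  fus <- attention_fuse(list(s = emb$E_s, f = emb$E_f, m = emb$E_m, c = emb$E_c), m$params)
  dec <- nb_decode(fus$E_final, m$params)
  expect_equal(dim(dec$mu), c(12, 20))
  expect_true(all(dec$mu > 0) && all(is.finite(dec$mu)))
  expect_true(all(dec$theta > 0) && all(dec$theta <= 1e4 + 1e-9))
  # zero input, zero weights: softplus(0) + eps everywhere
  p0 <- m$params
  for (nm in c("W_dec", "b_dec", "bn_beta", "W_mu", "b_mu", "W_theta", "b_theta")) {
    p0[[nm]] <- p0[[nm]] * 0
  }
  d0 <- nb_decode(matrix(0, 4, 6), p0)
  expect_equal(unname(d0$mu), matrix(log(2) + 1e-4, 4, 20), tolerance = 1e-12)
  expect_equal(unname(d0$theta), matrix(log(2) + 1e-4, 4, 20), tolerance = 1e-12)
})

test_that("NB likelihood matches closed forms and the Poisson limit", {
  # f_NB(0 | mu=1, theta=1) = 1/2 ; f_NB(1 | mu=1, theta=1) = 1/4
  expect_equal(nb_neg_loglik(matrix(0), matrix(1), matrix(1)), log(2), tolerance = 1e-9)
  expect_equal(nb_neg_loglik(matrix(1), matrix(1), matrix(1)), log(4), tolerance = 1e-9)
  # direct gamma-formula evaluation on small integers
  set.seed(61)
  X <- matrix(0:5, 2, 3)
  mu <- matrix(runif(6, 0.5, 3), 2, 3)
  th <- matrix(runif(6, 0.5, 3), 2, 3)
  fnb <- gamma(X + th) / (gamma(X + 1) * gamma(th)) *
    (th / (th + mu))^th * (mu / (mu + th))^X
  expect_equal(nb_neg_loglik(X, mu, th), mean(-log(fnb)), tolerance = 1e-9)
  # theta -> infinity recovers the Poisson likelihood
  Xp <- matrix(rpois(20, 3), 4, 5)
  mup <- matrix(runif(20, 1, 5), 4, 5)
  pois_nll <- mean(-stats::dpois(Xp, mup, log = TRUE))
  expect_equal(nb_neg_loglik(Xp, mup, matrix(1e6, 4, 5)), pois_nll, tolerance = 1e-3)
  expect_error(nb_neg_loglik(matrix(1), matrix(-1), matrix(1)), "positive")
})

test_that("consistency loss matches a double-loop oracle and its invariances", {
  set.seed(62)
  E1 <- matrix(rnorm(8), 4, 2)
  E2 <- matrix(rnorm(8), 4, 2)
  E3 <- matrix(rnorm(8), 4, 2)
  # identical embeddings: zero
  expect_equal(consistency_loss(list(E1, E1, E1)), 0)
  # row-scale invariance in similarity mode
  expect_equal(consistency_loss(list(E1, 2 * E1)), 0, tolerance = 1e-12)
  # double-loop oracle
  oracle <- function(Es) {
    Ks <- lapply(Es, function(E) {
      En <- E / sqrt(rowSums(E^2))
      En %*% t(En)
    })
    total <- 0
    for (i in 1:(length(Ks) - 1)) for (j in (i + 1):length(Ks)) {
      d <- 0
      for (a in 1:4) for (b in 1:4) d <- d + (Ks[[i]][a, b] - Ks[[j]][a, b])^2
      total <- total + d / 16
    }
    total
  }
  expect_equal(consistency_loss(list(E1, E2, E3)), oracle(list(E1, E2, E3)),
               tolerance = 1e-6)
  # embedding mode is the literal normalized-difference form
  En1 <- E1 / sqrt(rowSums(E1^2)); En2 <- E2 / sqrt(rowSums(E2^2))
  expect_equal(consistency_loss(list(E1, E2), mode = "embedding"),
               mean((En1 - En2)^2), tolerance = 1e-9)
})

test_that("regularization loss matches a double-loop oracle in full-complement mode", {
  set.seed(63)
  n <- 6
  E <- matrix(rnorm(n * 3), n, 3)
  A <- suppressWarnings(spatial_adjacency(matrix(runif(n * 2, 0, 2), n, 2), 1.2))
  nbrs <- stesh:::neighbor_sets(A)
  out <- regularization_loss(E, nbr_s = nbrs, negatives = "full")
  En <- E / sqrt(rowSums(E^2))
  mat <- En %*% t(En)
  sig <- function(x) 1 / (1 + exp(-x))
  tot <- 0; cnt <- 0
  for (i in 1:n) {
    for (j in nbrs[[i]]) { tot <- tot - log(sig(mat[i, j])); cnt <- cnt + 1 }
    if (length(nbrs[[i]]) > 0) {
      for (k in setdiff(1:n, c(i, nbrs[[i]]))) {
        tot <- tot - log(1 - sig(mat[i, k])); cnt <- cnt + 1
      }
    }
  }
  expect_equal(out$L_reg_s, tot / cnt, tolerance = 1e-6)
  expect_equal(out$L_reg, out$L_reg_s)   # no morphological graph
  # identical rows: similarity 1 everywhere, closed-form value
  E_same <- matrix(1, 4, 3) * rep(1, 4)
  nb_all <- lapply(1:4, function(i) setdiff(1:4, i))
  out2 <- suppressWarnings(
    regularization_loss(E_same, nbr_s = nb_all, negatives = "full"))
  expect_equal(out2$L_reg_s, -log(sig(1)), tolerance = 1e-9)  # only positives exist
  # no neighbors anywhere: zero
  out3 <- regularization_loss(E, nbr_s = lapply(1:n, function(i) integer(0)),
                              negatives = "full")
  expect_equal(out3$L_reg_s, 0)
})

test_that("total loss combines components with the published weights", {
  expect_equal(total_loss(1, 1, 1), 11.1)
  expect_equal(total_loss(3.5, 1.25, 0), 3.5 + 12.5)
  expect_equal(total_loss(2, 0.3, 0.7, beta = 0, gamma = 0), 2)
  expect_equal(total_loss(2, 0.3, 0.7), 2 * total_loss(1, 0.15, 0.35))
  expect_error(total_loss(1, 1, 1, alpha = -1), "nonnegative")
})
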