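# Multi-view graph convolutional autoencoder: four-branch GCN encoder,
# attention-based view fusion, negative binomial decoder, and the loss
# terms. Every forward function below is written against the autodiff ops,
# so it evaluates numerically on plain matrices and differentiably on
# ad_nodes — the public API and the training path share one code path.

glorot <- function(fan_in, fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -a, a), fan_in, fan_out)
}

#' Initialize encoder/attention/decoder parameters
#'
#' Glorot-uniform weights drawn from the current RNG state (seed it with
#' [set_global_seed()]). View-specific branches get their own weights; the
#' collaborative branch has a dedicated shared weight set applied to all
#' graphs, which is what makes the cross-graph consistency constraint
#' meaningful. The encoder is `input -> 128 -> 64` by default (ReLU after
#' the first layer, linear second layer).
#'
#' @param input_dim number of input genes (columns of X).
#' @param views character subset of `c("s", "f", "m")` naming the available
#'   graph views.
#' @param dims hidden and latent dimensions, default `c(128, 64)`.
#' @param d_hidden attention hidden dimension (default 16).
#' @param decoder_hidden decoder intermediate width (default 128).
#' @param n_genes decoder output dimension (defaults to `input_dim`).
#' @return a named list of parameter matrices/vectors (class
#'   `EncoderParams`).
#' @export
init_params <- function(input_dim, views = c("s", "f", "m"), dims = c(128L, 64L),
                        d_hidden = 16L, decoder_hidden = 128L, n_genes = input_dim) {
  d1 <- dims[1]; d2 <- dims[2]
  p <- list()
  for (v in c(views, "c")) {
    p[[paste0("W_", v, "1")]] <- glorot(input_dim, d1)
    p[[paste0("W_", v, "2")]] <- glorot(d1, d2)
  }
  p$W1 <- glorot(d_hidden, d2)        # attention layer 1 (d_hidden x d_latent)
  p$b1 <- rep(0, d_hidden)
  p$W2 <- glorot(1L, d_hidden)        # attention layer 2, bias-free
  p$W_linear <- glorot(d2, d2)
  p$b_linear <- rep(0, d2)
  p$W_dec <- glorot(d2, decoder_hidden)
  p$b_dec <- rep(0, decoder_hidden)
  p$bn_gamma <- rep(1, decoder_hidden)
  p$bn_beta <- rep(0, decoder_hidden)
  p$W_mu <- glorot(decoder_hidden, n_genes)
  p$b_mu <- rep(0, n_genes)
  p$W_theta <- glorot(decoder_hidden, n_genes)
  p$b_theta <- rep(0, n_genes)
  structure(p, class = "EncoderParams", views = views,
            dims = c(input_dim, dims), d_hidden = d_hidden,
            decoder_hidden = decoder_hidden, n_genes = n_genes)
}

#' One graph convolution layer
#'
#' The propagation rule `E' = ReLU(A_norm E W)`; with `activate = FALSE`
#' the output is linear (used for the final encoder layer so latent
#' embeddings can be signed).
#'
#' @param A_norm symmetric-normalized adjacency (dense or sparse constant).
#' @param E input embedding (matrix or ad_node).
#' @param W weight matrix (matrix or ad_node).
#' @param activate apply ReLU (default `TRUE`).
#' @return the propagated embedding.
#' @export
gcn_layer <- function(A_norm, E, W, activate = TRUE) {
  out <- ad_mm(ad_mm(A_norm, E), W)
  if (activate) out <- ad_relu(out)
  v <- ad_value(out)
  if (any(!is.finite(v))) stop("non-finite values in GCN layer output")
  out
}

# Layer-1 inputs A_norm %*% X are constant throughout training; callers may
# pass them precomputed via `AX`.
encode_views <- function(X, A_list, params, AX = NULL) {
  views <- names(A_list)
  if (is.null(AX)) AX <- lapply(A_list, function(A) as_dense(A %*% ad_value(X)))
  out <- list()
  for (v in views) {                       # view-specific branches
    H1 <- ad_relu(ad_mm(AX[[v]], params[[paste0("W_", v, "1")]]))
    out[[paste0("E_", v)]] <- gcn_layer(A_list[[v]], H1, params[[paste0("W_", v, "2")]],
                                        activate = FALSE)
  }
  collab <- list()
  for (v in views) {                       # collaborative branch, shared W_c
    H1 <- ad_relu(ad_mm(AX[[v]], params$W_c1))
    collab[[v]] <- gcn_layer(A_list[[v]], H1, params$W_c2, activate = FALSE)
  }
  for (v in views) out[[paste0("E_c", v)]] <- collab[[v]]
  acc <- collab[[1]]
  if (length(collab) > 1L) for (i in 2:length(collab)) acc <- ad_add(acc, collab[[i]])
  out$E_c <- ad_scale(acc, 1 / length(collab))
  out
}

#' Encode all views
#'
#' Runs the view-specific branches (own weights, own graphs) and the
#' collaborative branch (shared weights on every graph), and averages the
#' collaborative embeddings into `E_c`. When the bundle has no
#' morphological graph the `m` branch is skipped and downstream fusion runs
#' over three views (image-free mode).
#'
#' @param X feature matrix (spots x genes).
#' @param bundle a `GraphBundle`.
#' @param params an `EncoderParams`.
#' @return a `ViewEmbeddings` list: `E_s`, `E_f`, (`E_m`), `E_cs`, `E_cf`,
#'   (`E_cm`), `E_c`.
#' @export
encode <- function(X, bundle, params) {
  if (inherits(X, "FeatureMatrix")) X <- X$X
  A_list <- list(s = bundle$A_s_norm, f = bundle$A_f_norm)
  if (!is.null(bundle$A_m_norm) && "m" %in% attr(params, "views")) {
    A_list$m <- bundle$A_m_norm
  }
  out <- encode_views(X, A_list, params)
  class(out) <- "ViewEmbeddings"
  out
}

#' Attention fusion of view embeddings
#'
#' Per spot and view, a raw score `omega_hat = W2 tanh(W1 e + b1)` from a
#' two-layer projection with Tanh activation; scores are softmax-normalized
#' over views into weights `omega` (nonnegative, summing to 1), the fused
#' embedding is the weighted sum of view embeddings, and a final linear
#' layer gives `E_final = E_fusion W_linear + b_linear`.
#'
#' @param E_list named list of view embeddings (order defines the view
#'   axis), e.g. `list(s = E_s, f = E_f, m = E_m, c = E_c)`; at least 2.
#' @param params an `EncoderParams` (uses `W1`, `b1`, `W2`, `W_linear`,
#'   `b_linear`).
#' @return a `FusionResult` list: `omega_hat` (n x V), `omega` (n x V),
#'   `E_fusion`, `E_final`.
#' @export
attention_fuse <- function(E_list, params) {
  if (length(E_list) < 2L) stop("attention fusion needs at least 2 views")
  scores <- lapply(E_list, function(E) {
    ad_mm(ad_tanh(ad_add(ad_mm(E, ad_t(params$W1)), params$b1)), ad_t(params$W2))
  })
  omega_hat <- ad_cbind(unname(scores))
  omega <- ad_row_softmax(omega_hat)
  fusion <- NULL
  for (v in seq_along(E_list)) {
    term <- ad_rowscale(E_list[[v]], ad_col(omega, v))
    fusion <- if (is.null(fusion)) term else ad_add(fusion, term)
  }
  E_final <- ad_add(ad_mm(fusion, params$W_linear), params$b_linear)
  res <- list(omega_hat = omega_hat, omega = omega,
              E_fusion = fusion, E_final = E_final, views = names(E_list))
  class(res) <- "FusionResult"
  res
}

#' Negative binomial decoder
#'
#' Maps the fused embedding through a linear layer + batch normalization +
#' ReLU, then two linear heads produce the NB mean `mu` and dispersion
#' `theta`, each pushed through `softplus + 1e-4` for positivity; `theta`
#' is clamped to `[1e-4, 1e4]`.
#'
#' @param E_final n x d embedding (matrix or ad_node).
#' @param params an `EncoderParams`.
#' @return `NBDecoderOutput` list with `mu` and `theta` (both n x G,
#'   strictly positive).
#' @export
nb_decode <- function(E_final, params) {
  h <- ad_relu(ad_batchnorm(ad_add(ad_mm(E_final, params$W_dec), params$b_dec),
                            params$bn_gamma, params$bn_beta))
  mu <- ad_add(ad_softplus(ad_add(ad_mm(h, params$W_mu), params$b_mu)), 1e-4)
  theta <- ad_clamp(ad_add(ad_softplus(ad_add(ad_mm(h, params$W_theta), params$b_theta)), 1e-4),
                    1e-4, 1e4)
  if (any(!is.finite(ad_value(mu))) || any(!is.finite(ad_value(theta)))) {
    stop("non-finite decoder output")
  }
  structure(list(mu = mu, theta = theta), class = "NBDecoderOutput")
}

#' Negative binomial negative log-likelihood
#'
#' Mean over all entries of `-log f_NB(X | mu, theta)` with
#' `f_NB(X) = Gamma(X + theta) / (Gamma(X + 1) Gamma(theta)) *
#' (theta/(theta+mu))^theta * (mu/(mu+theta))^X`, evaluated in log space
#' via log-gamma. `X` may be real-valued (the gamma function generalizes
#' the factorial).
#'
#' @param X observed expression matrix (nonnegative).
#' @param mu,theta positive NB mean and dispersion (matrices or ad_nodes),
#'   recycled to the shape of `X` if scalar.
#' @return scalar mean negative log-likelihood.
#' @export
nb_neg_loglik <- function(X, mu, theta) {
  X <- as.matrix(ad_value(X) * 1)
  if (any(X < 0)) stop("X must be nonnegative")
  if (any(ad_value(mu) <= 0) || any(ad_value(theta) <= 0)) stop("mu and theta must be positive")
  ad_nb_nll(X, mu, theta)
}

#' Cross-graph consistency loss
#'
#' Pushes the collaborative embeddings from different graphs toward
#' agreement. In the default `"similarity"` mode each embedding is
#' row-L2-normalized and its spot-spot similarity matrix `K = E E^T` is
#' formed; the loss is the sum over view pairs of the mean squared entry
#' difference of `K` (scale-invariant per row). The `"embedding"` mode
#' computes the mean squared difference of the normalized embeddings
#' directly.
#'
#' @param E_list list of (>= 2) collaborative embeddings, e.g.
#'   `list(E_cm, E_cs, E_cf)`.
#' @param mode `"similarity"` (default) or `"embedding"`.
#' @return scalar loss (>= 0).
#' @export
consistency_loss <- function(E_list, mode = c("similarity", "embedding")) {
  mode <- match.arg(mode)
  if (length(E_list) < 2L) stop("consistency loss needs at least 2 embeddings")
  reps <- lapply(E_list, function(E) {
    En <- ad_row_l2norm(E)
    if (mode == "similarity") ad_tcrossprod(En) else En
  })
  total <- NULL
  for (i in seq_len(length(reps) - 1L)) {
    for (j in (i + 1L):length(reps)) {
      d <- ad_sub(reps[[i]], reps[[j]])
      term <- ad_mean(ad_emul(d, d))
      total <- if (is.null(total)) term else ad_add(total, term)
    }
  }
  total
}

# Non-neighbor candidate list per node (computed once per run).
reg_complements <- function(nbrs, n) {
  all_idx <- seq_len(n)
  lapply(all_idx, function(i) {
    non <- all_idx[-c(i, nbrs[[i]])]
    if (length(non) == 0L) warning("node ", i, " has no non-neighbors; negatives skipped")
    non
  })
}

# Draw |N_i| non-neighbor indices per node (or the full complement).
# Returns linear indices into an n x n matrix, split into positive and
# negative index vectors.
reg_pair_indices <- function(nbrs, n, negatives = c("sampled", "full"),
                             complements = NULL) {
  negatives <- match.arg(negatives)
  if (is.null(complements)) complements <- reg_complements(nbrs, n)
  deg <- lengths(nbrs)
  pos_i <- rep.int(seq_len(n), deg)
  pos_j <- unlist(nbrs, use.names = FALSE)
  neg <- lapply(seq_len(n), function(i) {
    non <- complements[[i]]
    if (deg[i] == 0L || length(non) == 0L) return(integer(0))
    if (negatives == "sampled") non[sample.int(length(non), min(deg[i], length(non)))]
    else non
  })
  neg_i <- rep.int(seq_len(n), lengths(neg))
  neg_j <- unlist(neg, use.names = FALSE)
  list(pos = (pos_j - 1L) * n + pos_i, neg = (neg_j - 1L) * n + neg_i)
}

#' Graph regularization loss
#'
#' For the spatial and morphological graphs, encourages the cosine
#' similarity `mat` of the final embedding to be high between graph
#' neighbors and low between non-neighbors:
#' `L = -(sum_{j in N_i} log sigma(mat_ij) + sum_{k notin N_i} log(1 -
#' sigma(mat_ik)))`, averaged over the pairs used. Negatives are drawn per
#' node as `|N_i|` uniform non-neighbors from the current RNG stream
#' (`negatives = "full"` uses the whole complement, for small-n oracles).
#' `L_reg = (L_reg_m + L_reg_s) / 2`; with no morphological graph,
#' `L_reg = L_reg_s`.
#'
#' @param E_final final embedding (matrix or ad_node).
#' @param nbr_s,nbr_m per-spot neighbor index lists (from the graph
#'   bundle); `nbr_m = NULL` in image-free mode.
#' @param negatives `"sampled"` or `"full"`.
#' @param indices optional precomputed output of an earlier draw (list with
#'   `s` and `m` entries) to reuse fixed pairs.
#' @param complements optional precomputed non-neighbor candidate lists
#'   (list with `s` and `m` entries), to avoid recomputation across epochs.
#' @return list with `L_reg_m`, `L_reg_s`, `L_reg` (scalars; ad_nodes when
#'   `E_final` is one).
#' @export
regularization_loss <- function(E_final, nbr_s, nbr_m = NULL,
                                negatives = "sampled", indices = NULL,
                                complements = NULL) {
  n <- nrow(ad_value(E_final))
  mat <- ad_tcrossprod(ad_row_l2norm(E_final))
  one_graph <- function(idx) {
    cnt <- length(idx$pos) + length(idx$neg)
    if (cnt == 0L) return(0)
    total <- NULL
    if (length(idx$pos)) {
      total <- ad_sum(ad_softplus(ad_scale(ad_gather(mat, idx$pos), -1)))
    }
    if (length(idx$neg)) {
      nt <- ad_sum(ad_softplus(ad_gather(mat, idx$neg)))
      total <- if (is.null(total)) nt else ad_add(total, nt)
    }
    ad_scale(total, 1 / cnt)
  }
  if (is.null(indices)) {
    indices <- list(
      s = reg_pair_indices(nbr_s, n, negatives, complements = complements$s),
      m = if (!is.null(nbr_m)) {
        reg_pair_indices(nbr_m, n, negatives, complements = complements$m)
      })
  }
  L_s <- one_graph(indices$s)
  L_m <- if (!is.null(indices$m)) one_graph(indices$m) else NULL
  L <- if (is.null(L_m)) L_s else ad_scale(ad_add(L_m, L_s), 0.5)
  list(L_reg_m = L_m, L_reg_s = L_s, L_reg = L, indices = indices)
}

#' Weighted total loss
#'
#' `L = alpha L_nb + beta L_con + gamma L_reg` with defaults
#' `alpha = 1, beta = 10, gamma = 0.1`.
#'
#' @param L_nb,L_con,L_reg loss components (scalars or ad_nodes).
#' @param alpha,beta,gamma nonnegative weights.
#' @return scalar total loss.
#' @export
total_loss <- function(L_nb, L_con, L_reg, alpha = 1, beta = 10, gamma = 0.1) {
  if (alpha < 0 || beta < 0 || gamma < 0) stop("loss weights must be nonnegative")
  ad_add(ad_add(ad_scale(L_nb, alpha), ad_scale(L_con, beta)), ad_scale(L_reg, gamma))
}
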