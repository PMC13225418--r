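#' Seed every stochastic component
#'
#' Sets R's global RNG (Mersenne-Twister / Inversion / Rejection) from one
#' integer. Weight initialization, negative sampling, augmentation draws
#' and clustering fallbacks all read from this stream, so a whole run is a
#' pure function of (data, config, seed). The default seed is 100.
#'
#' @param seed integer seed.
#' @return `seed`, invisibly.
#' @export
set_global_seed <- function(seed = 100L) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  invisible(seed)
}

#' Training configuration
#'
#' Collects every tunable of the model and optimizer with the package
#' defaults: Adam at `lr = 0.001` for 200 epochs, loss weights
#' `alpha = 1, beta = 10, gamma = 0.1`, encoder `input -> 128 -> 64`,
#' `k = 10` expression/morphology neighbors, seed 100. All fields are plain
#' scalars/strings so the config serializes losslessly to JSON/YAML.
#'
#' @param lr learning rate (> 0).
#' @param epochs training epochs (>= 1).
#' @param seed global seed.
#' @param alpha,beta,gamma loss weights.
#' @param dims encoder hidden/latent dims.
#' @param d_hidden attention hidden width.
#' @param decoder_hidden decoder intermediate width.
#' @param k_expr,k_morph kNN neighbor counts.
#' @param r spatial radius (`NULL` = data-driven default).
#' @param n_top number of highly variable genes.
#' @param norm_mode,log_transform normalization options, see
#'   [normalize_counts()].
#' @param consistency_mode see [consistency_loss()].
#' @param negatives negative-sampling mode, see [regularization_loss()].
#' @param use_image use the morphological view when an image is present.
#' @param crop,out_size,pca_dim histology patch options.
#' @return list of class `TrainConfig`.
#' @export
stesh_config <- function(lr = 0.001, epochs = 200L, seed = 100L,
                         alpha = 1, beta = 10, gamma = 0.1,
                         dims = c(128L, 64L), d_hidden = 16L,
                         decoder_hidden = 128L,
                         k_expr = 10L, k_morph = 10L, r = NULL,
                         n_top = 3000L, norm_mode = "per_spot_total",
                         log_transform = FALSE,
                         consistency_mode = "similarity",
                         negatives = "sampled", use_image = TRUE,
                         crop = 50L, out_size = 56L, pca_dim = 50L) {
  stopifnot(lr > 0, epochs >= 1L)
  structure(as.list(environment()), class = "TrainConfig")
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

model_forward <- function(params_nodes, X, A_list, AX, nbrs, cfg,
                          reg_indices = NULL, complements = NULL) {
  emb <- encode_views(X, A_list, params_nodes, AX = AX)
  view_names <- names(A_list)
  E_list <- c(stats::setNames(lapply(view_names, function(v) emb[[paste0("E_", v)]]), view_names),
              list(c = emb$E_c))
  fus <- attention_fuse(E_list, params_nodes)
  dec <- nb_decode(fus$E_final, params_nodes)
  L_nb <- nb_neg_loglik(X, dec$mu, dec$theta)
  L_con <- consistency_loss(lapply(view_names, function(v) emb[[paste0("E_c", v)]]),
                            mode = cfg$consistency_mode)
  reg <- regularization_loss(fus$E_final, nbr_s = nbrs$s, nbr_m = nbrs$m,
                             negatives = cfg$negatives, indices = reg_indices,
                             complements = complements)
  L <- total_loss(L_nb, L_con, reg$L_reg, cfg$alpha, cfg$beta, cfg$gamma)
  list(loss = L, L_nb = L_nb, L_con = L_con, reg = reg, fusion = fus,
       embeddings = emb, decoder = dec)
}

#' Train the multi-view graph convolutional autoencoder
#'
#' Full-batch (whole-graph) optimization with Adam for `cfg$epochs` steps.
#' Deterministic given (`fm`, `bundle`, `cfg`): the run starts by seeding
#' the global RNG with `cfg$seed`, and every stochastic component (Glorot
#' initialization, per-epoch negative sampling) reads from that stream.
#'
#' @param fm a `FeatureMatrix` (or plain matrix X, spots x genes).
#' @param bundle a `GraphBundle` over the same spots.
#' @param cfg a `TrainConfig`.
#' @return list of class `TrainResult`: `E_final` (n x latent), `omega`
#'   (final per-spot attention weights), `loss_history` (data.frame with
#'   per-epoch `L_nb`, `L_con`, `L_reg`, `L_total`), `attention_history`
#'   (per-epoch mean weight per view), trained `params`, and `config`.
#' @export
train <- function(fm, bundle, cfg = stesh_config()) {
  X <- if (inherits(fm, "FeatureMatrix")) fm$X else as.matrix(fm)
  set_global_seed(cfg$seed)
  A_list <- list(s = bundle$A_s_norm, f = bundle$A_f_norm)
  nbrs <- list(s = bundle$neighbor_sets$s, m = NULL)
  if (!is.null(bundle$A_m_norm) && isTRUE(cfg$use_image)) {
    A_list$m <- bundle$A_m_norm
    nbrs$m <- bundle$neighbor_sets$m
  }
  # normalized adjacencies are >90% zero; sparse products cut the cost of
  # every propagation step without changing its result
  A_list <- lapply(A_list, function(A) Matrix::Matrix(A, sparse = TRUE))
  views <- names(A_list)
  params <- init_params(ncol(X), views = setdiff(views, "c"), dims = cfg$dims,
                        d_hidden = cfg$d_hidden, decoder_hidden = cfg$decoder_hidden)
  AX <- lapply(A_list, function(A) as_dense(A %*% X))
  n <- nrow(X)
  complements <- list(s = reg_complements(nbrs$s, n),
                      m = if (!is.null(nbrs$m)) reg_complements(nbrs$m, n))
  state <- list(m = list(), v = list())
  n_view <- length(views) + 1L
  loss_hist <- matrix(NA_real_, cfg$epochs, 4L,
                      dimnames = list(NULL, c("L_nb", "L_con", "L_reg", "L_total")))
  att_hist <- matrix(NA_real_, cfg$epochs, n_view,
                     dimnames = list(NULL, paste0("omega_", c(views, "c"))))
  for (epoch in seq_len(cfg$epochs)) {
    tape <- ad_tape()
    pn <- lapply(params, function(p) ad_param(tape, p))
    attributes(pn) <- attributes(params)
    fwd <- model_forward(pn, X, A_list, AX, nbrs, cfg, complements = complements)
    comps <- c(L_nb = ad_value(fwd$L_nb), L_con = ad_value(fwd$L_con),
               L_reg = ad_value(fwd$reg$L_reg), L_total = ad_value(fwd$loss))
    if (any(!is.finite(comps))) {
      stop("non-finite loss at epoch ", epoch, ": ",
           paste(names(comps)[!is.finite(comps)], collapse = ", "))
    }
    loss_hist[epoch, ] <- comps
    att_hist[epoch, ] <- colMeans(ad_value(fwd$fusion$omega))
    ad_backward(fwd$loss)
    grads <- lapply(pn, function(nd) nd$grad)
    upd <- adam_step(params, grads, state, cfg$lr, epoch)
    params <- upd$params; state <- upd$state
  }
  final <- model_forward(params, X, A_list, AX, nbrs, cfg, complements = complements)
  structure(list(E_final = ad_value(final$fusion$E_final),
                 omega = ad_value(final$fusion$omega),
                 loss_history = as.data.frame(loss_hist),
                 attention_history = as.data.frame(att_hist),
                 params = params, views = views, config = cfg),
            class = "TrainResult")
}

#' @export
print.TrainResult <- function(x, ...) {
  ep <- nrow(x$loss_history)
  cat("TrainResult:", nrow(x$E_final), "spots,", ncol(x$E_final), "latent dims;",
      ep, "epochs\n")
  cat("  L_total:", signif(x$loss_history$L_total[1], 5), "->",
      signif(x$loss_history$L_total[ep], 5), "\n")
  cat("  mean attention:", paste(sprintf("%s=%.3f", colnames(x$attention_history),
                                         as.numeric(x$attention_history[ep, ])),
                                 collapse = " "), "\n")
  invisible(x)
}

#' Export training artifacts as CSV
#'
#' Writes `embedding.csv` (spot x latent), `loss_history.csv` and
#' `attention_history.csv` into `dir`, plus `provenance.json` with the
#' config and seed.
#'
#' @param tr a `TrainResult`.
#' @param dir output directory.
#' @param spot_ids optional spot identifiers for the embedding rows.
#' @return `dir`, invisibly.
#' @export
export_train_result <- function(tr, dir, spot_ids = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emb <- as.data.frame(tr$E_final)
  if (!is.null(spot_ids)) emb <- cbind(spot_id = spot_ids, emb)
  utils::write.csv(emb, file.path(dir, "embedding.csv"), row.names = FALSE)
  utils::write.csv(cbind(epoch = seq_len(nrow(tr$loss_history)), tr$loss_history),
                   file.path(dir, "loss_history.csv"), row.names = FALSE)
  utils::write.csv(cbind(epoch = seq_len(nrow(tr$attention_history)), tr$attention_history),
                   file.path(dir, "attention_history.csv"), row.names = FALSE)
  cfg <- tr$config
  cfg$r <- cfg$r %||% NA
  jsonlite::write_json(unclass(cfg), file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
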