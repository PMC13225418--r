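# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every op accepts either a plain numeric matrix/vector (treated as a
# constant) or an `ad_node`; when no node is among the arguments the op
# computes the plain value, so the same forward code serves both numeric
# evaluation (public API) and gradient-based training.
#
# Nodes live on a tape in creation order; ad_backward() walks the tape in
# reverse. Constants are never wrapped, so no gradient work is spent on them.

is_ad_node <- function(x) inherits(x, "ad_node")

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  class(tp) <- "ad_tape"
  tp
}

ad_value <- function(x) if (is_ad_node(x)) x$value else x

# parents: list whose ad_node entries receive gradients; backfn(g, node)
# must return a list of gradients aligned with parents (NULL for constants).
ad_new_node <- function(tape, value, parents, backfn) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$tape <- tape
  class(nd) <- "ad_node"
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

# Wrap a parameter matrix as a differentiable leaf.
ad_param <- function(tape, value) ad_new_node(tape, value, list(), NULL)

ad_find_tape <- function(...) {
  for (a in list(...)) if (is_ad_node(a)) return(a$tape)
  NULL
}

ad_accumulate <- function(node, g) {
  if (!is_ad_node(node) || is.null(g)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

ad_backward <- function(loss) {
  stopifnot(is_ad_node(loss), length(loss$value) == 1L)
  tape <- loss$tape
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad, nd)
    for (j in seq_along(nd$parents)) ad_accumulate(nd$parents[[j]], gs[[j]])
  }
  invisible(NULL)
}

# -- op helper -----------------------------------------------------------

ad_op <- function(value, args, backfn) {
  tape <- do.call(ad_find_tape, args)
  if (is.null(tape)) return(value)
  ad_new_node(tape, value, args, backfn)
}

as_dense <- function(x) if (is.matrix(x) || is.vector(x)) x else as.matrix(x)

# -- linear algebra ------------------------------------------------------

ad_mm <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_op(as_dense(av %*% bv), list(a, b), function(g, nd) {
    list(
      if (is_ad_node(a)) as_dense(g %*% t(bv)) else NULL,
      if (is_ad_node(b)) {
        if (methods::is(av, "Matrix")) as_dense(Matrix::crossprod(av, g))
        else as_dense(crossprod(av, g))
      } else NULL
    )
  })
}

ad_t <- function(a) {
  ad_op(t(ad_value(a)), list(a), function(g, nd) list(t(g)))
}

# K = X X^T (symmetric similarity matrices)
ad_tcrossprod <- function(a) {
  av <- ad_value(a)
  ad_op(tcrossprod(av), list(a), function(g, nd) list((g + t(g)) %*% av))
}

# -- elementwise arithmetic ---------------------------------------------

ad_add <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  # supports matrix + matrix (same dim) and matrix + row-broadcast bias vector
  bias <- is.matrix(av) && !is.matrix(bv) && length(bv) == ncol(av)
  val <- if (bias) sweep(av, 2L, bv, "+") else av + bv
  ad_op(val, list(a, b), function(g, nd) {
    ga <- if (is_ad_node(a)) g else NULL
    gb <- if (is_ad_node(b)) { if (bias) colSums(g) else g } else NULL
    list(ga, gb)
  })
}

ad_sub <- function(a, b) ad_add(a, ad_scale(b, -1))

ad_emul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_op(av * bv, list(a, b), function(g, nd) {
    list(if (is_ad_node(a)) g * bv else NULL,
         if (is_ad_node(b)) g * av else NULL)
  })
}

ad_scale <- function(a, s) {   # s: plain scalar
  ad_op(ad_value(a) * s, list(a), function(g, nd) list(g * s))
}

# scale the rows of matrix a (n x d) by vector w (length n)
ad_rowscale <- function(a, w) {
  av <- ad_value(a); wv <- as.vector(ad_value(w))
  ad_op(av * wv, list(a, w), function(g, nd) {
    list(if (is_ad_node(a)) g * wv else NULL,
         if (is_ad_node(w)) rowSums(g * av) else NULL)
  })
}

ad_col <- function(a, j) {
  av <- ad_value(a)
  ad_op(av[, j, drop = FALSE], list(a), function(g, nd) {
    G <- matrix(0, nrow(av), ncol(av)); G[, j] <- g; list(G)
  })
}

ad_cbind <- function(args) {
  vals <- lapply(args, ad_value)
  widths <- vapply(vals, function(v) ncol(as.matrix(v)), 1L)
  ends <- cumsum(widths); starts <- ends - widths + 1L
  ad_op(do.call(cbind, vals), args, function(g, nd) {
    lapply(seq_along(args), function(i) {
      if (is_ad_node(args[[i]])) g[, starts[i]:ends[i], drop = FALSE] else NULL
    })
  })
}

# pick linear indices idx out of a matrix; gradient scatters back
ad_gather <- function(a, idx) {
  av <- ad_value(a)
  ad_op(av[idx], list(a), function(g, nd) {
    G <- matrix(0, nrow(av), ncol(av))
    # idx may repeat under sampling with replacement guards; accumulate
    gi <- rowsum(g, idx)
    G[as.integer(rownames(gi))] <- gi
    list(G)
  })
}

# -- nonlinearities ------------------------------------------------------

ad_relu <- function(a) {
  av <- ad_value(a)
  val <- pmax(av, 0)
  ad_op(val, list(a), function(g, nd) list(g * (av > 0)))
}

ad_tanh <- function(a) {
  val <- tanh(ad_value(a))
  ad_op(val, list(a), function(g, nd) list(g * (1 - val^2)))
}

stable_softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

sigmoid_ <- function(x) 1 / (1 + exp(-x))

ad_softplus <- function(a) {
  av <- ad_value(a)
  ad_op(stable_softplus(av), list(a), function(g, nd) list(g * sigmoid_(av)))
}

ad_log <- function(a) {
  av <- ad_value(a)
  ad_op(log(av), list(a), function(g, nd) list(g / av))
}

ad_lgamma <- function(a) {
  av <- ad_value(a)
  ad_op(lgamma(av), list(a), function(g, nd) list(g * digamma(av)))
}

# fused mean negative log-likelihood of X ~ NB(mu, theta); one op instead
# of a long elementwise chain keeps the tape small on n x G matrices.
# ll = lgamma(X+th) - lgamma(th) - lgamma(X+1)
#    + th*(log th - log(th+mu)) + X*(log mu - log(mu+th))
ad_nb_nll <- function(X, mu, theta) {
  mv <- ad_value(mu); tv <- ad_value(theta)
  if (length(mv) == 1L) mv <- array(mv, dim = dim(X))
  if (length(tv) == 1L) tv <- array(tv, dim = dim(X))
  tpm <- tv + mv
  ll <- lgamma(X + tv) - lgamma(tv) - lgamma(X + 1) +
    tv * (log(tv) - log(tpm)) + X * (log(mv) - log(tpm))
  N <- length(X)
  ad_op(-sum(ll) / N, list(mu, theta), function(g, nd) {
    s <- -g / N
    ratio <- (X + tv) / tpm
    list(
      if (is_ad_node(mu)) s * (X / mv - ratio) else NULL,
      if (is_ad_node(theta)) {
        s * (digamma(X + tv) - digamma(tv) + log(tv) + 1 - log(tpm) - ratio)
      } else NULL
    )
  })
}

# hard clamp; gradient is zero outside [lo, hi]
ad_clamp <- function(a, lo, hi) {
  av <- ad_value(a)
  val <- pmin(pmax(av, lo), hi)
  ad_op(val, list(a), function(g, nd) list(g * (av >= lo & av <= hi)))
}

# -- reductions ----------------------------------------------------------

ad_sum <- function(a) {
  av <- ad_value(a)
  ad_op(sum(av), list(a), function(g, nd) list(array(g, dim = dim(as.matrix(av)))))
}

ad_mean <- function(a) {
  av <- ad_value(a); n <- length(av)
  ad_op(mean(av), list(a), function(g, nd) list(array(g / n, dim = dim(as.matrix(av)))))
}

# -- row-wise structured ops --------------------------------------------

ad_row_softmax <- function(a) {
  av <- ad_value(a)
  m <- av - apply(av, 1L, max)
  e <- exp(m)
  p <- e / rowSums(e)
  ad_op(p, list(a), function(g, nd) list(p * (g - rowSums(g * p))))
}

ad_row_l2norm <- function(a, eps = 1e-12) {
  av <- ad_value(a)
  nrm <- sqrt(rowSums(av^2)) + eps
  y <- av / nrm
  ad_op(y, list(a), function(g, nd) list((g - y * rowSums(g * y)) / nrm))
}

# column-wise batch normalization with learnable gain/shift; full-batch
# statistics (population mode), so train and eval coincide for whole-graph
# training
ad_batchnorm <- function(a, gamma, beta, eps = 1e-5) {
  av <- ad_value(a); gv <- as.vector(ad_value(gamma)); bv <- as.vector(ad_value(beta))
  n <- nrow(av)
  mu <- colMeans(av)
  v <- colMeans(av^2) - mu^2
  sd_ <- sqrt(v + eps)
  xhat <- sweep(sweep(av, 2L, mu, "-"), 2L, sd_, "/")
  val <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  ad_op(val, list(a, gamma, beta), function(g, nd) {
    dxhat <- sweep(g, 2L, gv, "*")
    ga <- if (is_ad_node(a)) {
      s1 <- colSums(dxhat); s2 <- colSums(dxhat * xhat)
      sweep(dxhat - sweep(xhat, 2L, s2 / n, "*") -
              matrix(s1 / n, n, length(s1), byrow = TRUE), 2L, sd_, "/")
    } else NULL
    list(ga,
         if (is_ad_node(gamma)) colSums(g * xhat) else NULL,
         if (is_ad_node(beta)) colSums(g) else NULL)
  })
}
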