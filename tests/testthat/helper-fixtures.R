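# Small fixtures shared across test files; everything is generated in code.

tiny_spec <- function(...) {
  defaults <- list(grid = c(10L, 10L), n_domains = 2L, n_genes = 60L,
                   image_px_per_spot = 6L, seed = 100L)
  do.call(synthetic_spec, utils::modifyList(defaults, list(...)))
}

tiny_dataset <- function(...) make_dataset(tiny_spec(...))

tiny_config <- function(...) {
  defaults <- list(epochs = 5L, n_top = 60L, out_size = 24L, crop = 12L,
                   pca_dim = 10L, k_expr = 5L, k_morph = 5L)
  args <- utils::modifyList(defaults, list(...))
  do.call(stesh_config, args)
}

# central finite-difference gradient of scalar-valued f at x
num_grad <- function(f, x, h = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# pair-count clustering agreement oracles (O(n^2) enumeration)
pair_counts <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1L
    else if (sa && !sb) n10 <- n10 + 1L
    else if (!sa && sb) n01 <- n01 + 1L
    else n00 <- n00 + 1L
  }
  c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
}

oracle_ari <- function(a, b) {
  pc <- pair_counts(a, b)
  num <- 2 * (pc["n11"] * pc["n00"] - pc["n10"] * pc["n01"])
  den <- (pc["n11"] + pc["n10"]) * (pc["n10"] + pc["n00"]) +
    (pc["n11"] + pc["n01"]) * (pc["n01"] + pc["n00"])
  if (den == 0) return(1)
  unname(num / den)
}

oracle_fmi <- function(a, b) {
  pc <- pair_counts(a, b)
  tp <- pc["n11"]
  if ((tp + pc["n10"]) == 0 || (tp + pc["n01"]) == 0) return(0)
  unname(tp / sqrt((tp + pc["n10"]) * (tp + pc["n01"])))
}

oracle_nmi <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  mi <- 0
  for (x in ua) for (y in ub) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) mi <- mi + pxy * log(pxy / (sum(a == x) / n * sum(b == y) / n))
  }
  ha <- -sum(vapply(ua, function(x) { p <- sum(a == x) / n; p * log(p) }, 1))
  hb <- -sum(vapply(ub, function(y) { p <- sum(b == y) / n; p * log(p) }, 1))
  if ((ha + hb) == 0) return(0)
  mi / ((ha + hb) / 2)
}
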