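#' Specification for a synthetic spatial transcriptomics dataset
#'
#' Defines the study conditions for the generator: a `rows x cols` lattice
#' of spots carved into spatially contiguous domains, negative-binomially
#' distributed counts with domain-specific differential expression, and a
#' rendered histology image whose color/texture varies by domain.
#'
#' Defaults describe the fixture used throughout the package: a 30 x 30
#' lattice with 4 banded domains (mimicking cortical laminae), 300 genes of
#' which 20% per domain are differentially expressed at log fold change 1.5,
#' negative binomial dispersion 10, mean library size 5000, a 10 px/spot
#' image at texture contrast 0.7, seed 100.
#'
#' @param grid integer vector `c(rows, cols)`.
#' @param n_domains number of planted domains.
#' @param n_genes number of genes.
#' @param de_frac fraction of genes differentially expressed per domain, in
#'   (0, 1\].
#' @param log_fc natural-log fold change of DE genes in their domain.
#' @param nb_dispersion negative binomial dispersion theta (> 0).
#' @param depth mean library size per spot.
#' @param image_px_per_spot pixels per lattice step in the rendered image
#'   (>= 3).
#' @param texture_contrast image domain-signal strength in \[0, 1\]; 0 gives
#'   a uniform image.
#' @param seed integer seed governing all generator draws.
#' @param geometry `"bands"` (horizontal layers) or `"rings"` (concentric).
#' @return an object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(grid = c(30L, 30L), n_domains = 4L, n_genes = 300L,
                           de_frac = 0.2, log_fc = 1.5, nb_dispersion = 10,
                           depth = 5000, image_px_per_spot = 10L,
                           texture_contrast = 0.7, seed = 100L,
                           geometry = c("bands", "rings")) {
  geometry <- match.arg(geometry)
  stopifnot(length(grid) == 2L, all(grid >= 1L),
            n_domains >= 1L, n_domains <= prod(grid),
            n_genes >= 1L, de_frac > 0, de_frac <= 1,
            nb_dispersion > 0, depth > 0, image_px_per_spot >= 3L,
            texture_contrast >= 0, texture_contrast <= 1)
  structure(list(grid = as.integer(grid), n_domains = as.integer(n_domains),
                 n_genes = as.integer(n_genes), de_frac = de_frac,
                 log_fc = log_fc, nb_dispersion = nb_dispersion, depth = depth,
                 image_px_per_spot = as.integer(image_px_per_spot),
                 texture_contrast = texture_contrast, seed = as.integer(seed),
                 geometry = geometry),
            class = "SyntheticSpec")
}

#' Plant spatial domains on a lattice
#'
#' Places spots on a regular `rows x cols` lattice (pixel units, spot
#' centers at `(col + 0.5, row + 0.5) * px_per_spot`) and assigns contiguous
#' domain labels: horizontal bands by default (cortical-lamina-like) or
#' concentric rings.
#'
#' @param spec a `SyntheticSpec`.
#' @return list with `coords` (n x 2) and integer `labels` in
#'   `0..n_domains-1`.
#' @export
plant_domains <- function(spec) {
  rows <- spec$grid[1]; cols <- spec$grid[2]
  px <- spec$image_px_per_spot
  ij <- expand.grid(row = seq_len(rows) - 1L, col = seq_len(cols) - 1L)
  coords <- cbind(x = (ij$col + 0.5) * px, y = (ij$row + 0.5) * px)
  if (spec$geometry == "bands") {
    if (spec$n_domains > rows) stop("n_domains exceeds the number of lattice rows")
    labels <- as.integer(floor(ij$row * spec$n_domains / rows))
  } else {
    ctr <- c((cols / 2 - 0.5), (rows / 2 - 0.5))
    dist_ <- sqrt((ij$col - ctr[1])^2 + (ij$row - ctr[2])^2)
    q <- stats::quantile(dist_, probs = seq(0, 1, length.out = spec$n_domains + 1L))
    labels <- as.integer(cut(dist_, breaks = unique(q), include.lowest = TRUE)) - 1L
  }
  if (length(unique(labels)) != spec$n_domains) stop("a planted domain is empty")
  list(coords = coords, labels = labels)
}

# Domain-specific NB mean matrix: baseline gene means (log-normal), per
# domain a seeded subset of genes boosted by exp(log_fc); a single global
# scale sets the average domain total to `depth`, so DE ratios between
# domains are exactly exp(log_fc).
domain_means <- function(spec) {
  base <- stats::rlnorm(spec$n_genes, meanlog = 0, sdlog = 1)
  mu <- matrix(rep(base, each = spec$n_domains), spec$n_domains, spec$n_genes)
  n_de <- max(1L, round(spec$de_frac * spec$n_genes))
  de_sets <- lapply(seq_len(spec$n_domains), function(d) sample.int(spec$n_genes, n_de))
  for (d in seq_len(spec$n_domains)) {
    mu[d, de_sets[[d]]] <- mu[d, de_sets[[d]]] * exp(spec$log_fc)
  }
  mu <- mu * spec$depth / mean(rowSums(mu))
  list(mu = mu, de_sets = de_sets, baseline = base)
}

#' Simulate negative binomial counts for planted domains
#'
#' Each domain has its own mean vector: a shared log-normal baseline with
#' `de_frac` of genes multiplied by `exp(log_fc)` (gene sets drawn per
#' domain from the seeded generator). Counts are drawn from
#' `NB(mu, theta = nb_dispersion)`; a single global scale makes the average
#' domain total equal `depth`, so row totals are approximately `depth` and
#' the in-domain/out-of-domain mean ratio of a DE gene is exactly
#' `exp(log_fc)`.
#'
#' @param labels integer domain labels (`0`-based).
#' @param spec a `SyntheticSpec`.
#' @return integer count matrix (spots x genes) with attributes `de_sets`
#'   and `mean_matrix`.
#' @export
simulate_counts <- function(labels, spec) {
  if (any(labels < 0 | labels >= spec$n_domains)) stop("labels out of range")
  withr_seed(spec$seed, {
    dm <- domain_means(spec)
    n <- length(labels)
    counts <- matrix(0L, n, spec$n_genes)
    for (i in seq_len(n)) {
      counts[i, ] <- stats::rnbinom(spec$n_genes, mu = dm$mu[labels[i] + 1L, ],
                                    size = spec$nb_dispersion)
    }
    attr(counts, "de_sets") <- dm$de_sets
    attr(counts, "mean_matrix") <- dm$mu
    counts
  })
}

#' Render a synthetic histology image
#'
#' Paints each domain with a distinct base color plus a domain-specific
#' sinusoidal texture frequency and seeded per-pixel noise. The parameter
#' `texture_contrast` interpolates between a perfectly uniform mid-gray
#' image (0) and full domain signal (1).
#'
#' @param labels integer domain labels.
#' @param coords spot coordinates from [plant_domains()].
#' @param spec a `SyntheticSpec`.
#' @return RGB array (height x width x 3, values 0-255).
#' @export
render_histology <- function(labels, coords, spec) {
  rows <- spec$grid[1]; cols <- spec$grid[2]; px <- spec$image_px_per_spot
  h <- rows * px; w <- cols * px
  base_palette <- matrix(c(215, 150, 185,   # H&E-like pinks/purples
                           160, 120, 200,
                           230, 190, 160,
                           120, 170, 210,
                           200, 220, 140,
                           240, 140, 140,
                           140, 220, 200,
                           180, 180, 120), ncol = 3, byrow = TRUE)
  cols_dom <- base_palette[(seq_len(spec$n_domains) - 1L) %% nrow(base_palette) + 1L, , drop = FALSE]
  # domain id per pixel: nearest spot row/col
  pix_row <- pmin(floor((seq_len(h) - 0.5) / px), rows - 1L)
  pix_col <- pmin(floor((seq_len(w) - 0.5) / px), cols - 1L)
  lab_grid <- matrix(labels, rows, cols)  # labels ordered row-major over expand.grid(row, col)
  dom_px <- lab_grid[cbind(rep(pix_row + 1L, times = w), rep(pix_col + 1L, each = h))]
  dom_px <- matrix(dom_px, h, w)
  gray <- 127.5
  img <- array(gray, dim = c(h, w, 3L))
  withr_seed(spec$seed + 1L, {
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (d in seq_len(spec$n_domains) - 1L) {
      mask <- dom_px == d
      freq <- 0.2 + 0.15 * d
      tex <- 25 * sin(freq * xx[mask]) * sin(freq * yy[mask])
      for (ch in 1:3) {
        target <- cols_dom[d + 1L, ch] + tex
        img[, , ch][mask] <- gray + spec$texture_contrast * (target - gray)
      }
    }
    noise <- array(stats::rnorm(h * w * 3L, sd = 8), dim = c(h, w, 3L))
    img <- clamp255(img + spec$texture_contrast * noise)
  })
  img
}

#' Generate a complete synthetic dataset
#'
#' Composes [plant_domains()], [simulate_counts()] and [render_histology()]
#' into a pipeline-ready `SpatialDataset` with ground-truth labels stored in
#' `meta$domain` and the full generator spec in `meta$synthetic_spec`.
#'
#' @param spec a `SyntheticSpec`.
#' @param with_image render and attach the histology image (default `TRUE`).
#' @return a `SpatialDataset`.
#' @export
make_dataset <- function(spec = synthetic_spec(), with_image = TRUE) {
  pd <- plant_domains(spec)
  counts <- simulate_counts(pd$labels, spec)
  attributes(counts) <- attributes(counts)["dim"]
  image <- if (with_image) render_histology(pd$labels, pd$coords, spec) else NULL
  spatial_dataset(counts, pd$coords,
                  spot_ids = sprintf("spot_%04d", seq_len(nrow(counts))),
                  gene_ids = sprintf("gene_%04d", seq_len(ncol(counts))),
                  image = image,
                  meta = list(domain = pd$labels, synthetic_spec = unclass(spec)))
}

#' Write a synthetic fixture to disk
#'
#' Writes the MTX directory (counts, barcodes, features, coords, labels), a
#' PNG of the rendered image, and a JSON copy of the generator spec. When
#' `h5ad = TRUE` also writes `dataset.h5ad` through the Python bridge.
#'
#' @param ds a `SpatialDataset` from [make_dataset()].
#' @param dir output directory.
#' @param h5ad also write an h5ad copy.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(ds, dir, h5ad = FALSE) {
  write_dataset_mtx(ds, dir, image_file = if (!is.null(ds$image)) "image.png" else NULL)
  if (!is.null(ds$meta$synthetic_spec)) {
    jsonlite::write_json(ds$meta$synthetic_spec, file.path(dir, "synthetic_spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (h5ad) write_dataset_h5ad(ds, file.path(dir, "dataset.h5ad"))
  invisible(dir)
}
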