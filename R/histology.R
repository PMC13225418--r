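# ImageNet channel statistics used to standardize patches before feature
# extraction (applied on [0,1]-scaled pixels).
IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_SD <- c(0.229, 0.224, 0.225)

#' Read an RGB image into a 0-255 array
#'
#' @param path PNG/TIFF/JPEG file.
#' @return numeric array height x width x 3, values in \[0, 255\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else {
    as.array(EBImage::readImage(path))
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (ext != "png") img <- aperm(img, c(2L, 1L, 3L))  # EBImage stores x,y
  img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write a 0-255 RGB array as PNG
#'
#' @param img array height x width x 3 in \[0, 255\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}

resize_patch <- function(patch, out_size) {
  if (dim(patch)[1] == out_size && dim(patch)[2] == out_size) return(patch)
  # EBImage uses (x, y, channel) ordering
  res <- EBImage::resize(EBImage::Image(aperm(patch / 255, c(2L, 1L, 3L)),
                                        colormode = "Color"),
                         w = out_size, h = out_size)
  aperm(as.array(res), c(2L, 1L, 3L)) * 255
}

#' Crop per-spot image patches
#'
#' Cuts the `crop` x `crop` pixel window centered on each spot, zero-padding
#' (black) where the window exceeds the image bounds, then resizes every
#' patch to `out_size` x `out_size`. The padded fraction of each window is
#' recorded in `pad_mask` (computed on the pre-resize window).
#'
#' @param image RGB array (height x width x 3, values 0-255).
#' @param coords spot coordinates (x = column, y = row, 0-based pixels).
#' @param crop crop window side in pixels (default 50).
#' @param out_size output side after resizing (default 224).
#' @return a `PatchSet`: list with `patches` (n x out x out x 3 array),
#'   `centers`, `pad_mask`, `standardized` flag.
#' @export
extract_patches <- function(image, coords, crop = 50L, out_size = 224L) {
  stopifnot(crop >= 1L, out_size >= 1L)
  coords <- as.matrix(coords)
  h <- dim(image)[1]; w <- dim(image)[2]
  n <- nrow(coords)
  before <- floor((crop - 1) / 2)
  patches <- array(0, dim = c(n, out_size, out_size, 3L))
  pad_mask <- numeric(n)
  for (i in seq_len(n)) {
    cx <- round(coords[i, 1]); cy <- round(coords[i, 2])
    rows <- (cy - before):(cy - before + crop - 1)   # 0-based
    cols <- (cx - before):(cx - before + crop - 1)
    ok_r <- rows >= 0 & rows < h
    ok_c <- cols >= 0 & cols < w
    window <- array(0, dim = c(crop, crop, 3L))
    if (any(ok_r) && any(ok_c)) {
      window[which(ok_r), which(ok_c), ] <- image[rows[ok_r] + 1L, cols[ok_c] + 1L, , drop = FALSE]
    } else {
      warning("spot ", i, " lies fully outside the image; patch is all padding")
    }
    pad_mask[i] <- 1 - sum(ok_r) * sum(ok_c) / (crop * crop)
    patches[i, , , ] <- resize_patch(window, out_size)
  }
  structure(list(patches = patches, centers = coords, pad_mask = pad_mask,
                 crop = crop, out_size = out_size, standardized = FALSE),
            class = "PatchSet")
}

#' Standardize patches with ImageNet channel statistics
#'
#' Scales pixels to \[0, 1\] and applies per-channel centering/scaling with
#' the fixed ImageNet constants (mean 0.485/0.456/0.406, sd
#' 0.229/0.224/0.225). Standardization is not idempotent, so a state flag
#' guards against double application.
#'
#' @param ps a `PatchSet`.
#' @return the standardized `PatchSet` (`standardized = TRUE`).
#' @export
standardize_patches <- function(ps) {
  if (isTRUE(ps$standardized)) stop("patches are already standardized")
  if (dim(ps$patches)[4] != 3L) stop("standardization requires RGB patches")
  for (ch in 1:3) {
    ps$patches[, , , ch] <- (ps$patches[, , , ch] / 255 - IMAGENET_MEAN[ch]) / IMAGENET_SD[ch]
  }
  ps$standardized <- TRUE
  ps
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

augment_one <- function(p, rng_draws) {
  # rng_draws: named list of pre-drawn random values, one set per patch
  s <- dim(p)[1]
  # 1. autocontrast (per channel rescale to full range)
  if (rng_draws$apply[1]) {
    for (ch in 1:3) {
      v <- p[, , ch]; rg <- range(v)
      if (diff(rg) > 0) p[, , ch] <- (v - rg[1]) / diff(rg) * 255
    }
  }
  # 2. Gaussian blur
  if (rng_draws$apply[2]) {
    img <- EBImage::Image(aperm(p / 255, c(2L, 1L, 3L)), colormode = "Color")
    p <- aperm(as.array(EBImage::gblur(img, sigma = rng_draws$blur_sigma)), c(2L, 1L, 3L)) * 255
  }
  # 3. random affine: integer translation with zero fill
  if (rng_draws$apply[3]) {
    dx <- rng_draws$shift[1]; dy <- rng_draws$shift[2]
    q <- array(0, dim = dim(p))
    src_r <- intersect(seq_len(s), seq_len(s) - dy)
    src_c <- intersect(seq_len(s), seq_len(s) - dx)
    q[src_r + dy, src_c + dx, ] <- p[src_r, src_c, ]
    p <- q
  }
  # 4. horizontal flip
  if (rng_draws$apply[4]) p <- p[, s:1, , drop = FALSE]
  # 5. vertical flip
  if (rng_draws$apply[5]) p <- p[s:1, , , drop = FALSE]
  # 6. rotation by a multiple of 90 degrees
  if (rng_draws$apply[6]) {
    k <- rng_draws$rot_k
    for (r in seq_len(k)) p <- aperm(p, c(2L, 1L, 3L))[s:1, , , drop = FALSE]
  }
  # 7. color jitter: per-channel brightness scaling
  if (rng_draws$apply[7]) {
    for (ch in 1:3) p[, , ch] <- clamp255(p[, , ch] * rng_draws$jitter[ch])
  }
  p
}

#' Seeded random patch augmentation
#'
#' Applies a fixed suite of seven augmentations (autocontrast, Gaussian
#' blur, random translation, horizontal flip, vertical flip, 90-degree
#' rotation, per-channel color jitter), each switched on per patch with
#' probability 1/2, all draws taken from a generator seeded with `seed` so
#' the output is reproducible. With `enabled = FALSE` the input is returned
#' unchanged. Augmentation operates on raw (unstandardized) patches.
#'
#' @param ps a `PatchSet` (not yet standardized).
#' @param seed integer seed.
#' @param enabled logical master switch (default `FALSE`).
#' @return an augmented `PatchSet`.
#' @export
augment_patches <- function(ps, seed = 100L, enabled = FALSE) {
  if (!enabled) return(ps)
  if (isTRUE(ps$standardized)) stop("augment before standardization")
  n <- dim(ps$patches)[1]
  draws <- withr_seed(seed, {
    lapply(seq_len(n), function(i) {
      list(apply = stats::runif(7) < 0.5,
           blur_sigma = stats::runif(1, 0.5, 2),
           shift = sample(-3:3, 2, replace = TRUE),
           rot_k = sample(1:3, 1),
           jitter = stats::runif(3, 0.8, 1.2))
    })
  })
  for (i in seq_len(n)) {
    ps$patches[i, , , ] <- augment_one(ps$patches[i, , , , drop = TRUE], draws[[i]])
  }
  ps
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Built-in deterministic patch feature extractor
#'
#' Returns an extractor function mapping a standardized patch array
#' (n x h x w x 3) to an n x d feature matrix built from per-channel
#' intensity histograms plus a downsampled pixel grid. It is fully
#' deterministic, needs no pretrained weights, and serves as the default
#' backbone behind the pluggable extractor interface; any function with the
#' same signature (e.g. wrapping a pretrained CNN) can be supplied instead.
#'
#' @param bins histogram bins per channel (default 16).
#' @param pool downsampled grid side (default 8).
#' @return a function `(patches) -> matrix` with attribute `extractor_id`.
#' @export
stub_extractor <- function(bins = 16L, pool = 8L) {
  f <- function(patches) {
    n <- dim(patches)[1]
    out <- matrix(0, n, 3L * bins + pool * pool * 3L)
    brks <- seq(-3, 3, length.out = bins + 1L)
    for (i in seq_len(n)) {
      p <- patches[i, , , , drop = TRUE]
      hists <- unlist(lapply(1:3, function(ch) {
        v <- pmin(pmax(p[, , ch], -3 + 1e-9), 3 - 1e-9)
        as.vector(table(cut(v, brks))) / length(v)
      }))
      s <- dim(p)[1]
      grp_r <- ceiling(seq_len(s) / (s / pool))
      pooled <- unlist(lapply(1:3, function(ch) {
        as.vector(rowsum(t(rowsum(p[, , ch], grp_r)), grp_r)) / (s / pool)^2
      }))
      out[i, ] <- c(hists, pooled)
    }
    out
  }
  attr(f, "extractor_id") <- sprintf("histogram%d+pool%d", bins, pool)
  f
}

#' Embed patches with a feature extractor
#'
#' Runs the extractor over patches in batches (inference only; results are
#' independent of `batch_size`) and checks the output dimension is constant
#' across batches.
#'
#' @param ps a standardized `PatchSet`.
#' @param extractor a function `(patches) -> matrix`; default
#'   [stub_extractor()].
#' @param batch_size patches per extractor call.
#' @return raw feature matrix (spots x raw_dim) with attribute
#'   `extractor_id`.
#' @export
embed_patches <- function(ps, extractor = stub_extractor(), batch_size = 64L) {
  n <- dim(ps$patches)[1]
  starts <- seq(1L, n, by = batch_size)
  chunks <- lapply(starts, function(s) {
    e <- min(s + batch_size - 1L, n)
    extractor(ps$patches[s:e, , , , drop = FALSE])
  })
  dims <- vapply(chunks, ncol, 1L)
  if (length(unique(dims)) != 1L) stop("extractor output dimension varies across batches")
  raw <- do.call(rbind, chunks)
  attr(raw, "extractor_id") <- attr(extractor, "extractor_id") %||% "custom"
  raw
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' PCA-reduce raw patch features
#'
#' Centers the raw features and keeps the top `d` principal components,
#' with a deterministic sign convention (the largest-magnitude loading of
#' each component is made positive). `d` is clamped to the matrix rank with
#' a warning.
#'
#' @param raw spots x raw_dim feature matrix.
#' @param d target dimension (default 50).
#' @return a `MorphFeatureMatrix`: list with `M` (spots x d), `raw_dim`,
#'   `extractor_id`, `rotation`, `explained_var`.
#' @export
reduce_pca <- function(raw, d = 50L) {
  raw <- as.matrix(raw)
  pc <- stats::prcomp(raw, center = TRUE, scale. = FALSE)
  rank_ <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (d > rank_) {
    warning("d = ", d, " exceeds feature rank ", rank_, "; clamping")
    d <- rank_
  }
  rot <- pc$rotation[, seq_len(d), drop = FALSE]
  flip <- vapply(seq_len(d), function(j) {
    l <- rot[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 1)
  rot <- sweep(rot, 2L, flip, "*")
  M <- sweep(pc$x[, seq_len(d), drop = FALSE], 2L, flip, "*")
  structure(list(M = M, raw_dim = ncol(raw),
                 extractor_id = attr(raw, "extractor_id") %||% "unknown",
                 rotation = rot,
                 explained_var = pc$sdev[seq_len(d)]^2 / sum(pc$sdev^2)),
            class = "MorphFeatureMatrix")
}

#' Full histology feature path
#'
#' `extract_patches` -> `standardize_patches` -> optional augmentation ->
#' `embed_patches` -> `reduce_pca`.
#'
#' @inheritParams extract_patches
#' @inheritParams reduce_pca
#' @param extractor feature extractor, see [embed_patches()].
#' @param augment enable seeded augmentation (default `FALSE`).
#' @param seed seed for augmentation draws.
#' @return a `MorphFeatureMatrix`.
#' @export
histology_features <- function(image, coords, crop = 50L, out_size = 224L,
                               d = 50L, extractor = stub_extractor(),
                               augment = FALSE, seed = 100L) {
  ps <- extract_patches(image, coords, crop = crop, out_size = out_size)
  ps <- augment_patches(ps, seed = seed, enabled = augment)
  ps <- standardize_patches(ps)
  raw <- embed_patches(ps, extractor = extractor)
  reduce_pca(raw, d = d)
}
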