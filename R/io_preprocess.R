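#' Construct a SpatialDataset
#'
#' Container for a spot-by-gene count matrix, per-spot pixel coordinates and
#' an optional RGB histology image. Coordinates are full-resolution pixel
#' units, 0-based, ordered (x = column, y = row); this convention is stored
#' in `meta$coord_convention` to make axis handling explicit.
#'
#' @param counts nonnegative integer matrix, spots in rows, genes in columns.
#' @param coords numeric matrix/data.frame with columns x, y; one row per spot.
#' @param spot_ids,gene_ids character identifiers; default from dimnames.
#' @param image optional RGB array (height x width x 3) with values in
#'   \[0, 255\], or `NULL`.
#' @param in_tissue logical per-spot flag; default all `TRUE`.
#' @param meta free-form list of extra per-dataset metadata (e.g. planted
#'   domain labels under `meta$domain`).
#' @return an object of class `SpatialDataset`.
#' @export
spatial_dataset <- function(counts, coords, spot_ids = rownames(counts),
                            gene_ids = colnames(counts), image = NULL,
                            in_tissue = NULL, meta = list()) {
  counts <- as.matrix(counts)
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  colnames(coords) <- c("x", "y")
  if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(counts)))
  if (is.null(in_tissue)) in_tissue <- rep(TRUE, nrow(counts))
  if (nrow(counts) != nrow(coords) || nrow(counts) != length(spot_ids)) {
    stop("counts, coords and spot_ids must agree on the number of spots")
  }
  if (ncol(counts) != length(gene_ids)) stop("gene_ids length must match gene count")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(!is.finite(coords))) stop("coords must be finite")
  if (length(in_tissue) != nrow(counts)) stop("in_tissue length must match spot count")
  if (!is.null(image)) {
    if (length(dim(image)) != 3L || dim(image)[3] != 3L) stop("image must be height x width x 3")
    oob <- coords[, 1] < 0 | coords[, 1] >= dim(image)[2] |
      coords[, 2] < 0 | coords[, 2] >= dim(image)[1]
    if (any(oob)) warning(sum(oob), " spot(s) fall outside the image bounds")
  }
  rownames(counts) <- spot_ids; colnames(counts) <- gene_ids
  rownames(coords) <- spot_ids
  meta$coord_convention <- "0-based pixel units, x = image column, y = image row"
  structure(list(counts = counts, coords = coords, image = image,
                 spot_ids = spot_ids, gene_ids = gene_ids,
                 in_tissue = as.logical(in_tissue), meta = meta),
            class = "SpatialDataset")
}

#' @export
print.SpatialDataset <- function(x, ...) {
  cat("SpatialDataset:", nrow(x$counts), "spots x", ncol(x$counts), "genes;",
      if (is.null(x$image)) "no image" else paste0("image ", dim(x$image)[1], "x", dim(x$image)[2]),
      "\n")
  invisible(x)
}

#' @export
dim.SpatialDataset <- function(x) dim(x$counts)

subset_dataset <- function(ds, spots = NULL, genes = NULL) {
  if (is.null(spots)) spots <- seq_len(nrow(ds$counts))
  if (is.null(genes)) genes <- seq_len(ncol(ds$counts))
  meta <- ds$meta
  for (nm in names(meta)) {
    if (length(meta[[nm]]) == length(ds$spot_ids) && nm != "coord_convention") {
      meta[[nm]] <- meta[[nm]][spots]
    }
  }
  spatial_dataset(ds$counts[spots, genes, drop = FALSE],
                  ds$coords[spots, , drop = FALSE],
                  spot_ids = ds$spot_ids[spots], gene_ids = ds$gene_ids[genes],
                  image = ds$image, in_tissue = ds$in_tissue[spots], meta = meta)
}

h5ad_bridge_path <- function() {
  p <- system.file("python", "h5ad_bridge.py", package = "stesh")
  if (p == "") p <- file.path("inst", "python", "h5ad_bridge.py")
  p
}

run_h5ad_bridge <- function(args) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "") stop("h5ad support needs a python interpreter with anndata on PATH")
  out <- suppressWarnings(system2(py, c(shQuote(h5ad_bridge_path()), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("h5ad bridge failed:\n", paste(out, collapse = "\n"))
  }
  invisible(out)
}

load_mtx_dir <- function(path) {
  mtx <- file.path(path, "matrix.mtx")
  bc <- file.path(path, "barcodes.tsv")
  ft <- file.path(path, "features.tsv")
  for (f in c(mtx, bc, ft)) if (!file.exists(f)) stop("missing file: ", f)
  m <- Matrix::readMM(mtx)           # genes x spots, 10x convention
  barcodes <- readLines(bc)
  feat <- utils::read.delim(ft, header = FALSE, stringsAsFactors = FALSE)
  genes <- feat[[1]]
  counts <- t(as.matrix(m))
  rownames(counts) <- barcodes
  colnames(counts) <- genes
  cf <- file.path(path, "coords.csv")
  if (!file.exists(cf)) cf <- file.path(path, "tissue_positions.csv")
  if (!file.exists(cf)) stop("missing coordinates: no coords.csv/tissue_positions.csv in ", path)
  pos <- utils::read.csv(cf, stringsAsFactors = FALSE)
  if (!all(c("barcode", "x", "y") %in% names(pos))) {
    stop("coordinate CSV must have columns barcode, x, y (optional in_tissue)")
  }
  missing_bc <- setdiff(barcodes, pos$barcode)
  if (length(missing_bc)) {
    stop("barcodes missing from coordinates: ", paste(utils::head(missing_bc, 5), collapse = ", "))
  }
  pos <- pos[match(barcodes, pos$barcode), ]
  in_tissue <- if ("in_tissue" %in% names(pos)) as.logical(pos$in_tissue) else NULL
  meta <- list()
  lf <- file.path(path, "labels.csv")
  if (file.exists(lf)) {
    lab <- utils::read.csv(lf, stringsAsFactors = FALSE)
    meta$domain <- lab$domain[match(barcodes, lab$barcode)]
  }
  list(counts = counts, coords = as.matrix(pos[, c("x", "y")]),
       in_tissue = in_tissue, meta = meta)
}

#' Load a spatial transcriptomics dataset
#'
#' Reads either a 10x-style MatrixMarket directory (`matrix.mtx` genes x
#' spots, `barcodes.tsv`, `features.tsv`, and a coordinate CSV with columns
#' `barcode,x,y[,in_tissue]`) or an AnnData `.h5ad` file (converted through
#' a bundled Python helper that requires `python` with `anndata` on the
#' PATH). An optional histology image (PNG/TIFF/JPEG) can be attached.
#'
#' @param path path to an `.h5ad` file or an MTX directory.
#' @param image_path optional path to the histology image.
#' @return a `SpatialDataset`.
#' @export
load_dataset <- function(path, image_path = NULL) {
  if (dir.exists(path)) {
    parts <- load_mtx_dir(path)
  } else if (grepl("\\.h5ad$", path)) {
    if (!file.exists(path)) stop("no such file: ", path)
    tmp <- tempfile("h5ad_export_")
    dir.create(tmp)
    on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
    run_h5ad_bridge(c("export", shQuote(path), shQuote(tmp)))
    parts <- load_mtx_dir(tmp)
  } else {
    stop("path must be an .h5ad file or an MTX directory: ", path)
  }
  image <- if (!is.null(image_path)) read_image(image_path) else NULL
  spatial_dataset(parts$counts, parts$coords, image = image,
                  in_tissue = parts$in_tissue, meta = parts$meta)
}

#' Write a dataset as an MTX directory
#'
#' Writes `matrix.mtx` (genes x spots), `barcodes.tsv`, `features.tsv`,
#' `coords.csv` and, when planted labels are present, `labels.csv`.
#'
#' @param ds a `SpatialDataset`.
#' @param dir output directory.
#' @param image_file optional PNG filename (within `dir`) for the image.
#' @return `dir`, invisibly.
#' @export
write_dataset_mtx <- function(ds, dir, image_file = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(ds$counts), sparse = TRUE)
  Matrix::writeMM(methods::as(m, "generalMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(ds$spot_ids, file.path(dir, "barcodes.tsv"))
  utils::write.table(data.frame(id = ds$gene_ids, name = ds$gene_ids, type = "Gene Expression"),
                     file.path(dir, "features.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(barcode = ds$spot_ids, x = ds$coords[, 1],
                              y = ds$coords[, 2], in_tissue = as.integer(ds$in_tissue)),
                   file.path(dir, "coords.csv"), row.names = FALSE)
  if (!is.null(ds$meta$domain)) {
    utils::write.csv(data.frame(barcode = ds$spot_ids, domain = ds$meta$domain),
                     file.path(dir, "labels.csv"), row.names = FALSE)
  }
  if (!is.null(image_file) && !is.null(ds$image)) {
    write_image(ds$image, file.path(dir, image_file))
  }
  invisible(dir)
}

#' Write a dataset as an AnnData h5ad file
#'
#' Round-trips through an MTX directory and the bundled Python helper
#' (requires `python` with `anndata`).
#'
#' @param ds a `SpatialDataset`.
#' @param path output `.h5ad` path.
#' @return `path`, invisibly.
#' @export
write_dataset_h5ad <- function(ds, path) {
  tmp <- tempfile("h5ad_import_")
  write_dataset_mtx(ds, tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  run_h5ad_bridge(c("import", shQuote(tmp), shQuote(path)))
  invisible(path)
}

#' Remove out-of-tissue spots and empty genes
#'
#' Keeps spots flagged `in_tissue`, then drops genes whose total count over
#' the remaining spots is zero.
#'
#' @param ds a `SpatialDataset`.
#' @return filtered `SpatialDataset`.
#' @export
filter_spots <- function(ds) {
  keep <- which(ds$in_tissue)
  if (length(keep) == 0L) stop("no spots remain after tissue filtering")
  ds2 <- subset_dataset(ds, spots = keep)
  gene_keep <- which(colSums(ds2$counts) > 0)
  subset_dataset(ds2, genes = gene_keep)
}

#' Select highly variable genes
#'
#' Ranks genes by a dispersion statistic on library-size-normalized counts:
#' per-gene mean and dispersion (variance/mean) are computed on counts
#' scaled to 1e4 per spot, means are cut into 20 equal-frequency bins, and
#' each dispersion is centered and scaled by its bin's median and MAD (a
#' robust variant of the classic binned-dispersion ranking that tolerates
#' sparsely populated bins). The top `n_top` genes by
#' normalized dispersion are kept; ties break by gene identifier order so
#' the ranking is deterministic.
#'
#' @param ds a `SpatialDataset`.
#' @param n_top number of genes to keep (default 3000; clamped with a
#'   warning when it exceeds the gene count).
#' @return `SpatialDataset` restricted to the selected genes, in their
#'   original column order.
#' @export
select_hvg <- function(ds, n_top = 3000L) {
  G <- ncol(ds$counts)
  if (n_top < 1L) stop("n_top must be >= 1")
  if (n_top > G) {
    warning("n_top = ", n_top, " exceeds gene count ", G, "; keeping all genes")
    n_top <- G
  }
  if (n_top == G) return(ds)
  tot <- rowSums(ds$counts)
  tot[tot == 0] <- 1
  norm <- ds$counts / tot * 1e4
  mu <- colMeans(norm)
  v <- apply(norm, 2L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  nbin <- min(20L, max(1L, sum(mu > 0)))
  bins <- cut(rank(mu, ties.method = "first"), breaks = nbin, labels = FALSE)
  zdisp <- disp
  for (b in unique(bins)) {
    sel <- bins == b
    s <- stats::mad(disp[sel])
    if (!is.finite(s) || s == 0) s <- stats::sd(disp[sel])
    if (!is.finite(s) || s == 0) s <- 1
    zdisp[sel] <- (disp[sel] - stats::median(disp[sel])) / s
  }
  ord <- order(-zdisp, ds$gene_ids)
  keep <- sort(ord[seq_len(n_top)])
  subset_dataset(ds, genes = keep)
}

#' Normalize counts into the model feature matrix
#'
#' Scales each spot's counts by a size factor to a common target of 1e4:
#' `X_ij = count_ij / s_i * 1e4`. With `norm_mode = "per_spot_total"`
#' (default) `s_i` is the spot's total count, so every row of `X` sums to
#' 1e4; with `"median_ratio"` `s_i = total_i / median(total)`, preserving
#' the median library size times 1e4 as overall scale. Spots with zero total
#' are removed with a warning. No log transform is applied unless
#' `log_transform = TRUE` (then `log1p` after scaling).
#'
#' @param ds a `SpatialDataset`.
#' @param norm_mode `"per_spot_total"` or `"median_ratio"`.
#' @param log_transform apply `log1p` after scaling.
#' @return a `FeatureMatrix`: list with `X`, `hvg_names`, `scale_factors`,
#'   `spot_ids` and the dataset the matrix aligns to (`dataset`).
#' @export
normalize_counts <- function(ds, norm_mode = c("per_spot_total", "median_ratio"),
                             log_transform = FALSE) {
  norm_mode <- match.arg(norm_mode)
  tot <- rowSums(ds$counts)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " spot(s) with zero total count removed before normalization")
    ds <- subset_dataset(ds, spots = which(tot > 0))
    tot <- rowSums(ds$counts)
  }
  s <- switch(norm_mode,
              per_spot_total = tot,
              median_ratio = tot / stats::median(tot))
  X <- ds$counts / s * 1e4
  if (log_transform) X <- log1p(X)
  structure(list(X = X, hvg_names = ds$gene_ids, scale_factors = s,
                 spot_ids = ds$spot_ids, dataset = ds,
                 norm_mode = norm_mode, log_transform = log_transform),
            class = "FeatureMatrix")
}

#' Standard preprocessing chain
#'
#' `filter_spots()` then `select_hvg()` then `normalize_counts()`.
#'
#' @inheritParams normalize_counts
#' @inheritParams select_hvg
#' @return a `FeatureMatrix`.
#' @export
preprocess_dataset <- function(ds, n_top = 3000L,
                               norm_mode = "per_spot_total", log_transform = FALSE) {
  ds <- filter_spots(ds)
  ds <- select_hvg(ds, n_top = n_top)
  normalize_counts(ds, norm_mode = norm_mode, log_transform = log_transform)
}
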