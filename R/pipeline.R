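#' Run the full spatial-domain identification pipeline
#'
#' Chains every stage: tissue/gene filtering, highly-variable-gene
#' selection, depth normalization, histology patch features (when an image
#' is present and `cfg$use_image`), graph construction, multi-view
#' autoencoder training, and GMM clustering of the final embedding. When
#' the dataset carries ground-truth labels (`meta$domain`) the clustering
#' is scored with ARI/NMI/FMI.
#'
#' @param ds a `SpatialDataset`.
#' @param n_domains number of domains to cluster into; defaults to the
#'   number of distinct ground-truth labels when present.
#' @param cfg a `TrainConfig` from [stesh_config()].
#' @param extractor patch feature extractor, see [embed_patches()].
#' @return list of class `SteshRun`: `fm`, `morph`, `bundle`, `train`
#'   (`TrainResult`), `domains` (`DomainLabels`), `metrics` (NULL without
#'   ground truth), `truth`.
#' @export
stesh_run <- function(ds, n_domains = NULL, cfg = stesh_config(),
                      extractor = stub_extractor()) {
  fm <- preprocess_dataset(ds, n_top = cfg$n_top, norm_mode = cfg$norm_mode,
                           log_transform = cfg$log_transform)
  kept <- fm$dataset
  morph <- NULL
  if (!is.null(kept$image) && isTRUE(cfg$use_image)) {
    morph <- histology_features(kept$image, kept$coords, crop = cfg$crop,
                                out_size = cfg$out_size, d = cfg$pca_dim,
                                extractor = extractor, seed = cfg$seed)
  }
  bundle <- build_graph_bundle(fm$X, kept$coords, M = morph,
                               k_expr = cfg$k_expr, k_morph = cfg$k_morph,
                               r = cfg$r)
  tr <- train(fm, bundle, cfg)
  truth <- kept$meta$domain
  if (is.null(n_domains)) {
    if (is.null(truth)) stop("n_domains must be given when the dataset has no ground-truth labels")
    n_domains <- length(unique(truth))
  }
  dom <- cluster_embedding(tr$E_final, n_domains, seed = cfg$seed)
  metrics <- if (!is.null(truth)) score_clustering(truth, dom$labels) else NULL
  structure(list(fm = fm, morph = morph, bundle = bundle, train = tr,
                 domains = dom, metrics = metrics, truth = truth),
            class = "SteshRun")
}

#' @export
print.SteshRun <- function(x, ...) {
  cat("SteshRun:", nrow(x$train$E_final), "spots ->", x$domains$n_domains, "domains\n")
  if (!is.null(x$metrics)) {
    cat(sprintf("  ARI %.3f | NMI %.3f | FMI %.3f\n",
                x$metrics$ari, x$metrics$nmi, x$metrics$fmi))
  }
  invisible(x)
}

#' Write pipeline outputs
#'
#' Writes domain labels as CSV (`spot_id, domain`), metrics as JSON (when
#' available), and the training artifacts via [export_train_result()].
#'
#' @param run a `SteshRun`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
export_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(spot_id = run$fm$spot_ids, domain = run$domains$labels),
                   file.path(dir, "domains.csv"), row.names = FALSE)
  if (!is.null(run$metrics)) {
    jsonlite::write_json(run$metrics, file.path(dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  export_train_result(run$train, dir, spot_ids = run$fm$spot_ids)
  invisible(dir)
}
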