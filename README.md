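# stesh

Spatial-domain identification for spatial transcriptomics by integrating
**g**ene expression, **s**patial coordinates and **h**istology. `stesh`
builds three neighbor graphs over the spots of an arrayed tissue section —
spatial (radius), expression (cosine kNN) and morphological (Pearson kNN on
image-patch features) — and learns one fused spot embedding with a
multi-view graph convolutional autoencoder:

* per-view two-layer GCNs (`genes -> 128 -> 64`) plus a collaborative
  branch whose shared weights run on all three graphs,
* attention fusion of the four view embeddings (softmax weights per spot,
  exported every epoch),
* a negative binomial decoder reconstructing expression
  (`L_NB = -mean log f_NB(X | mu, theta)`),
* a cross-graph consistency loss on the collaborative embeddings and a
  neighbor/non-neighbor regularization on the fused embedding,
  combined as `L = alpha*L_NB + beta*L_con + gamma*L_reg`
  (`alpha = 1, beta = 10, gamma = 0.1`),
* full-batch Adam (`lr = 0.001`, 200 epochs), everything driven by one
  seed — identical runs are bitwise identical.

The final embedding is clustered into spatial domains with a Gaussian
mixture model (shared full covariance, via `mclust`), and clusterings are
scored against reference labels with ARI, NMI and FMI. A synthetic-data
module generates fully self-contained fixtures — planted banded or ring
domains, negative binomial counts with controlled fold changes, and a
rendered histology image — so the entire pipeline runs and is tested
offline.

Everything numerical under the model (graph convolutions, attention,
NB likelihood, losses, Adam) runs on a small reverse-mode autodiff core
included in the package; no deep-learning framework is required.

## Quick start

```r
library(stesh)

# a 30x30 lattice with 4 planted banded domains, NB counts, rendered image
ds  <- make_dataset(synthetic_spec())
run <- stesh_run(ds, cfg = stesh_config())
print(run)
#> SteshRun: 900 spots -> 4 domains
#>   ARI 0.923 | NMI 0.931 | FMI 0.942

tail(run$train$loss_history, 1)
#>         L_nb        L_con     L_reg  L_total
#> 200 4.996342 9.873034e-06 0.5691249 5.053353

round(tail(run$train$attention_history, 1), 3)
#>     omega_s omega_f omega_m omega_c
#> 200   0.309   0.316   0.319   0.056
```

`run$metrics` holds the agreement of the recovered domains with the
planted labels (1.0 would be perfect recovery; here the Gaussian mixture
trims one band border), `run$train$loss_history` the per-epoch loss
components, and `run$train$attention_history` the mean attention weight
each view received per epoch (each row sums to 1 — after 200 epochs the
three graph views share the weight almost evenly, with a small
collaborative share).

On real data:

```r
ds  <- load_dataset("outs/filtered_feature_bc_matrix",   # MTX dir + coords.csv
                    image_path = "outs/tissue_image.png")
run <- stesh_run(ds, n_domains = 7, cfg = stesh_config())
export_run(run, "results/")        # domains.csv, embedding.csv, histories
```

A thin CLI wraps the same functions:

```sh
exec/stesh simulate --out fixture/ --seed 100
exec/stesh train --input fixture/ --image fixture/image.png --domains 4 --out run/
```

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "stesh", load_package = "installed")'
```

The suite covers every stage against independent oracles: brute-force
graph constructions, finite-difference gradients for every autodiff op,
scalar-loop attention and loss oracles, closed-form NB values and the
Poisson limit, pair-enumeration clustering metrics, and end-to-end
determinism and planted-domain recovery.

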