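---
title: "Identifying spatial domains with multi-view graph convolutional autoencoders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying spatial domains with multi-view graph convolutional autoencoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Array-based spatial transcriptomics (10x Visium, Stereo-seq) measures a
gene-expression profile at each of thousands of spatially arranged capture
spots, usually alongside an H&E-stained photograph of the same tissue
section. A *spatial domain* is a contiguous region of tissue — a cortical
layer, a tumor compartment — whose spots share both an expression profile
and a histological appearance. Clustering expression alone fragments such
regions; clustering expression plus coordinates ignores what the image
shows. `stesh` integrates all three signals: it learns one low-dimensional
embedding per spot from three neighbor graphs (spatial, expression,
morphological) and clusters that embedding into domains.

## The model

**Graphs.** Let `X` be the spot-by-gene matrix of depth-normalized
expression over the highly variable genes. Three binary adjacencies are
built over the same spots:

* spatial: `A_s[i,j] = 1` iff the Euclidean distance between spot centers
  is strictly below a radius `r` (default 1.3 times the minimum nonzero
  spot distance, which captures the six hexagonal Visium neighbors);
* expression: cosine similarity of rows of `X`, each spot keeping its `k`
  most similar spots (`k = 10`);
* morphological: Pearson correlation of per-spot image-patch features
  (50 px crops embedded by a feature extractor and PCA-reduced to 50
  dimensions), again top-`k`.

kNN relations are directed; we symmetrize by logical OR so that the
symmetric normalization `Ã = D^(-1/2) A D^(-1/2)` is well defined (the
directed variant remains available). Self-loops are enforced uniformly:
the spatial graph has them by construction (distance 0), and for kNN
graphs self is excluded from the ranking and the diagonal set afterwards.

**Encoder.** Each view runs a two-layer graph convolution
`E = Ã ReLU(Ã X W1) W2` with its own weights (the second layer is linear
so latent coordinates can be signed). A fourth, *collaborative* branch
applies one shared weight set to all three graphs, producing `E_cs`,
`E_cf`, `E_cm` whose average is the collaborative embedding `E_c`. Giving
the collaborative branch its own shared weights (rather than reusing the
view weights) is what makes the cross-graph consistency constraint
meaningful: the three collaborative embeddings are produced by the same
function and differ only through the graphs. Layer widths are
`genes -> 128 -> 64`.

**Attention fusion.** Each spot's four view embeddings are scored by a
two-layer projection (`16` hidden units, Tanh, bias-free second layer),
softmax-normalized into weights that are nonnegative and sum to one, and
combined as a weighted sum followed by a final linear layer. Mean
per-view weights are exported every epoch.

**Decoder and losses.** A negative binomial decoder (linear layer,
batch normalization, ReLU, then separate `mu` and `theta` heads through
`softplus + 1e-4`, with `theta` clamped to `[1e-4, 1e4]`) reconstructs the
model input; the reconstruction loss is the mean NB negative
log-likelihood evaluated in log-gamma space. Two structural terms are
added: a consistency loss — the mean squared difference between the
spot-spot similarity matrices of the row-normalized collaborative
embeddings, summed over view pairs — and a regularization loss that pushes
the cosine similarity of the final embedding to be high between
spatial/morphological graph neighbors and low between sampled
non-neighbors, with one negative drawn per positive. The total is
`L = alpha*L_nb + beta*L_con + gamma*L_reg` with `alpha = 1`, `beta = 10`,
`gamma = 0.1`.

**Training and clustering.** Full-batch Adam (`lr = 0.001`, 200 epochs, no
scheduler, no early stopping), Glorot-uniform initialization, everything
seeded from one integer (default 100): two runs with the same data and
config are bitwise identical. The final embedding is clustered by a
Gaussian mixture with shared full covariance (mclust model `"EEE"`), and
agreement with reference labels is scored by ARI, NMI (arithmetic-mean
normalization) and FMI.

## Worked example

```{r, eval = FALSE}
library(stesh)

ds <- make_dataset(synthetic_spec())        # 30x30 lattice, 4 banded domains
run <- stesh_run(ds, cfg = stesh_config())  # preprocess, graphs, train, cluster
print(run)
run$metrics                                  # ARI / NMI / FMI vs planted labels
head(run$train$attention_history)            # per-epoch mean view weights
```

## Design choices where the design was open

* **Depth normalization.** The target is `X_ij = count_ij / s_i * 1e4`.
  The package's default size factor is the spot's total count, the only
  reading under which every spot is actually brought to a common depth;
  `norm_mode = "median_ratio"` (`s_i = total_i / median(total)`) is
  provided for parity experiments. No log transform is applied by default;
  `log_transform = TRUE` adds `log1p` after scaling, and the NB
  reconstruction always targets the model input matrix (a
  `nb_target`-style switch would target raw counts; we reconstruct what
  the encoder sees).
* **HVG statistic.** Genes are ranked by dispersion (variance/mean of
  counts scaled to 1e4 per spot) normalized within 20 equal-frequency mean
  bins by the bin median and MAD. The robust centering tolerates sparsely
  populated bins; ties break by gene identifier so the selection is
  deterministic.
* **Consistency loss operand.** The loss is defined on similarity
  (covariance-like) matrices of the row-normalized collaborative
  embeddings by default — this makes it invariant to per-spot rescaling
  and compares relational structure rather than coordinates; the literal
  embedding-difference form is available via `mode = "embedding"`.
* **Negative sampling.** Per node, as many negatives as positives, drawn
  uniformly from non-neighbors each epoch from the seeded stream; the full
  complement is available for small-n exactness (and is what the oracle
  tests use). Losses are averaged (not summed) over their pair sets so the
  loss weights keep a dataset-size-independent meaning.
* **Feature extractor.** The patch embedder is pluggable. The built-in
  default is a deterministic histogram-plus-downsampled-pixels embedder
  (240 dimensions) that needs no pretrained weights and keeps the whole
  pipeline offline-reproducible; any function mapping a patch batch to
  fixed-length vectors (e.g. a pretrained ResNet50 wrapper) can be
  substituted. Patch augmentation (seven seeded operations: autocontrast,
  Gaussian blur, affine translation, horizontal/vertical flips, 90-degree
  rotation, color jitter) is off by default at inference.
* **Clustering backend.** The GMM is fit by `mclust` (model `"EEE"`,
  shared full covariance), matching the method's R clustering convention;
  a degenerate fit falls back to one seeded k-means restart.
* **Adam internals.** The optimizer's momentum constants are the standard
  `beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`; they are recorded in the
  exported provenance.

## The synthetic generator

`synthetic_spec()` defines the study conditions the test-suite fixtures
use: a 30x30 lattice whose spots are carved into 4 contiguous horizontal
bands (mimicking cortical laminae; concentric rings available), 300 genes
with a log-normal baseline, 20% of genes per domain up-regulated by
`exp(1.5)`, counts drawn from NB with dispersion 10 at a mean library size
of 5000, and a rendered image (10 px per spot) whose domain color/texture
signal is scaled by a contrast parameter (0.7 by default; 0 yields a
perfectly uniform image). The generator mirrors the decoder's NB
parameterization exactly, so parameter-recovery questions are well posed.

What it does *not* emulate: within-domain expression gradients, irregular
domain shapes, realistic H&E stain variation, platform artifacts
(ambient RNA, doublets, segmentation errors). Passing the planted-domain
tests therefore demonstrates the machinery is correct and the integration
works on clean signal, not that real-tissue accuracy matches any
published benchmark.

## Numerical choices

* Softplus is evaluated as `max(x, 0) + log1p(exp(-abs(x)))`; the NB
  likelihood uses log-gamma throughout; `log sigma(x)` is `-softplus(-x)`.
* Batch normalization uses full-batch statistics, so training and
  inference coincide for whole-graph training (deterministic export).
* PCA components carry a fixed sign convention (largest-magnitude loading
  positive); requested dimensions clamp to the matrix rank with a warning.
* Top-k neighbor ties break toward the smaller spot index; zero rows in
  similarity inputs are guarded (similarity 0, with a warning).
* Non-finite losses abort training with the epoch and component named.

## Problem sizes used by the test suite

Unit tests run on 10x10 lattices (100 spots, 60 genes) in seconds. The
planted-domain recovery test and the acceptance script train the full
900-spot fixture for 200 epochs; the ablation comparison (image-free,
`beta = 0`, `gamma = 0` against the full model, 5 seeds each) and the
seed-stability sweep use 50 epochs — by then the loss has completed most
of its descent on this fixture, and those comparisons are relative, so the
shorter runs measure the same effects at a fraction of the cost.

## Known limitations

* Full-batch training keeps the whole `n x n` similarity structure in
  memory; the intended scale is arrayed tissue sections (up to a few tens
  of thousands of spots), not dissociated atlases.
* The built-in patch embedder captures color and coarse intensity layout,
  not the nuclear texture a pretrained CNN sees; on real H&E images a
  pretrained backbone should be plugged in.
* The number of domains is supplied by the user (as when benchmarking
  against an annotation); no model selection over `G` is attempted.
* h5ad I/O shells out to a bundled Python helper (`anndata` required);
  the MTX directory path is pure R.
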