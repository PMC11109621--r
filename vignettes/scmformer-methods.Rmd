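---
title: "scmformer: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scmformer: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, what the synthetic generator
does and does not emulate, the numerical choices, and the places where
the design was genuinely open and we had to decide. It states no
empirical result that the test suite does not itself compute.

## 1. The model

### Cells embedding

All modalities are first brought to a common width `D` (`aligned_dim`)
by per-modality PCA (small panels are zero-padded instead, see §3). Each
cell's length-`D` vector is split row-major into `n_sub = D/s`
contiguous sub-vectors of length `s`; these are the attention tokens.
`D %% s == 0` is enforced up front.

Positional information (the token's index) and categorical information
(which modality the token belongs to) are injected as **learned additive
embeddings of width `s`**. The source description says the codes are
"appended" to each sub-vector, but the attention projection has shape
`s × 3s`, which requires length-`s` tokens; appending a scalar would
break every subsequent shape. Token-type-style additive embeddings
preserve the stated dimensions while carrying the same information. This
is a deliberate, documented interpretation, as is the choice of a
*learned* (rather than sinusoidal) positional table.

For joint integration the modalities are concatenated along the token
axis — a cell contributes `D/s` RNA tokens followed by `D/s` protein
tokens, with distinct modality codes and global positions — and a single
decoder processes the joint sequence. This resolves an ambiguity in the
source (the fusion loss is written over latents of width "s|2"): we pool
one width-`s` latent per modality from the jointly encoded sequence.

### scm-attention

Per head (`s` must be divisible by the head count `H`):

* `Q, K, V = ReLU(split(X W_qkv + b))` — joint projection `s × 3s`,
  ReLU applied after the split;
* scores `Q K^T / sqrt(s)` — scaled by `sqrt(s)` as printed in the
  source equations, not by the per-head width;
* a causal mask removes all positions `j > i`. The source says masked
  scores are "set to infinity", which is only meaningful under a
  softmax; with ReLU in place of softmax, `+Inf` would propagate. We set
  masked scores to `-Inf` *before* the ReLU — equivalently, masked
  attention weights are exactly zero — which preserves the stated
  autoregressive contract (the forward pass at position `p` is
  bit-for-bit independent of inputs at positions `> p`; the test suite
  asserts this with `expect_identical`);
* attention weights are `ReLU(scores)` — no softmax anywhere — and the
  head output is `ReLU(scores) V`;
* heads are concatenated and passed through a learned `s × s` merge
  matrix (the concatenation in the source implies one; an
  `identity_merge` option freezes it to the identity).

### Decoder layer, pooling, heads

Pre-norm residuals, exactly as the source equations are written:

    X1 = X + Dropout(Merge(MultiHead(LayerNorm1(X))))
    X2 = X1 + Dropout(ReLU(LayerNorm2(X1) W1 + b1)) W2 + b2

with feed-forward inner width `2s`. Default depth is one decoder layer
(the source's figures show a single block; depth is configurable).
Decoder outputs are average-pooled over each modality's token positions
into `X_average ∈ R^{cells×s}`, and one linear head per target modality
maps the latent to feature space with no activation.

### Objectives

* reconstruction: `MSE(X_rec,m, X_m)` per modality, against the
  *reduced* (post-PCA) input — the sum over modalities enters the total
  (the source does not say sum or mean; sum implemented);
* fusion: MSE between the per-modality latents; for three modalities the
  mean over all unordered pairs, handling triple-omics in one objective;
* integration total: `λ · Σ rec + comb`, `λ ≥ 0` (default 70, inside the
  published optimum range 40–100);
* generation: plain MSE between the head's prediction and the measured
  target on its normalized scale. Inference is a single pass (source
  tokens → pooled latent → target head), not token-by-token
  autoregression: the supplementary procedure is not described in the
  main source and the pooled-latent head structure supports single-pass
  directly. The causal mask is retained.

## 2. Optimisation, and why the learning-rate default deviates

Adam, fixed learning rate, no schedule, seeded mini-batches drawing the
same cell indices across modalities. All randomness (initialisation,
batch order, dropout) derives from `scm_config(seed=)`; repeated runs
are bitwise identical, and results were observed to be invariant to BLAS
thread count on the reference platform.

The published per-task learning rate is 1e-4, with a printed robustness
interval of 1e-5 to 5e-3 ("little effect"). That default presumes tens
of thousands of cells: with 600 cells, batch 32 and 20 epochs there are
only ~380 Adam updates, and since Adam's per-step parameter displacement
is bounded by roughly the learning rate, total weight motion is capped
near `380 × 1e-4 ≈ 0.04` — provably too small to train from random
initialisation (empirically the alignment error stays at the random
baseline). The package default is therefore `lr = 3e-3`, inside the
published robustness interval; users reproducing large-data settings can
set 1e-4 explicitly.

For the same reason `train_generation()` defaults to 300 epochs: its
objective has a single MSE term (the integration loss has `λ`-weighted
reconstruction terms per modality plus fusion), converges more slowly,
and at desk scale 300 epochs still run in about a minute. The published
analysis reports epoch count as having minimal impact.

Weight initialisation (unspecified in the source): He/Kaiming for
projections feeding a ReLU (`W_qkv`, feed-forward `W1`), Xavier for the
merge matrix and linear heads, `N(0, 0.02²)` embedding tables, unit
LayerNorm gains. The backward pass is hand-derived; the test suite
checks it against central finite differences across every weight array.

## 3. Preprocessing

* **RNA (and ATAC under the RNA recipe)**: per-cell scaling to
  `target_sum` (default 1e4) then `log1p`. Zero-count cells are left as
  zero rows with a warning.
* **Protein (ADT)**: centered log-ratio per cell,
  `y_j = log((x_j + c)/geomean(x + c))` with pseudocount `c = 1` — the
  standard count-compatible CLR variant; the source names CLR but not
  its zero handling.
* **ATAC default**: TF-IDF weighting then log scaling (standard practice
  for peak matrices; the source does not specify), toggleable to the RNA
  recipe.
* **HVG selection**: dispersion (variance/mean) z-scored within
  equal-frequency mean bins, top `n_hvg` kept in original order — the
  source gives the HVG count but not the selector; this is the
  classic binned-dispersion flavour.
* **Dimension alignment**: per-modality PCA on centered data to exactly
  `aligned_dim` columns; a modality with *fewer* features than
  `aligned_dim` (e.g. a 36- or 40-plex protein panel) is zero-padded
  instead, keeping the PCA honest. Whether the source reduces both
  modalities or only the wider one is not stated; both are reduced.
* **Cross-modality scale** (`scale_total_var`, package addition, default
  on): after reduction each modality is rescaled by a single global
  factor to unit mean per-entry variance. Without it the λ-weighted
  reconstruction losses and the attention inputs are dominated by
  whichever modality happens to have larger raw variance; one global
  factor per modality preserves the relative variance profile of the
  principal components while making losses comparable. Toggleable for
  users who want raw PCA scores.

For generation, `fit_preprocessor()` records the recipe, the selected
HVG set and the PCA basis on the training cells and
`apply_preprocessor()` replays them on queries — held-out cells are
never allowed to influence the basis.

## 4. The synthetic world

`simulate_paired()` draws, per cell, a shared latent state (one of
`n_types` Gaussian centroids plus within-type jitter of sd 0.3) observed
through two channels:

* RNA: log-linear rates `exp(base_g + latent·loadings + cell-size
  offset + ε)`, Poisson counts, Bernoulli dropout (default rate 0.2,
  extra log-rate noise sd 0.2);
* protein: log-linear abundance `exp(base_p + latent·loadings)` with
  additive Gaussian noise (sd 2 on the count scale, i.e. ~10% of the
  typical abundance `e^3 ≈ 20`), rounded and clipped at zero;
* optional per-batch mean shifts on the log scale.

Defaults (600 cells, 3 types, 400 genes, 40 proteins, latent dimension
10) describe a small CITE-seq-like panel that trains in seconds on one
CPU. The noise levels were fixed once at values giving realistic count
magnitudes (per-cell RNA totals ~10³, ADT counts ~10¹–10²) and were not
revisited afterwards. What the generator deliberately does **not**
emulate: ambient/background ADT mixture distributions, empty droplets
and doublets, peak-matrix sparsity structure, batch-specific library
chemistry. A green recovery test therefore establishes that the
implementation optimises its objectives and that the architecture can
exploit a shared-latent pairing — not that it matches published
benchmarks on real tissues.

`simulate_unpaired_query()` draws new cells from the same world (same
centroids and loadings) for transfer/generation testing, with the
held-out counterpart returned as ground truth; `count_noise = FALSE`
switches off Poisson/rounding noise so the counterpart is exactly
recoverable through the known log-linear map, which the tests use as a
construction oracle.

## 5. Metrics

* **FOSCTTM**: both directions compare against the true-match distance
  `d(x_i, y_i)`; the printed definition of one direction
  (`d(x_j, y_i) < d(x_i, y_j)`) is internally inconsistent with the
  metric's stated meaning and with the other printed direction, so the
  standard form is implemented (deviation logged). Strict inequality, so
  ties do not count and identical embeddings score exactly 0. Euclidean
  throughout.
* **Label transfer**: brute-force exact kNN (no approximate search at
  desk scale), majority vote, ties broken by smallest cumulative
  neighbour distance then lexicographic label order. `k = 5` by default
  — the source never prints its `k`; exposed as a flag.
* **macro-F1**: unweighted mean over classes present in the *true*
  labels; a class never predicted contributes 0. The source does not
  state its convention.
* **Generation quality**: Pearson/Spearman per feature across cells
  (constant features reported as 0 with a flag), MSE/RMSE over all
  entries.

## 6. Numerical choices and degenerate inputs

* LayerNorm uses population variance with `eps = 1e-5`.
* Masked attention entries are exact zeros after ReLU, so causality
  holds bitwise, not just approximately.
* Dropout (default 0.1) applies to the attention output and the
  feed-forward inner activation, training only; inference is
  deterministic.
* Training aborts with the epoch/batch index on a non-finite loss.
* Zero-count cells normalize to zero rows (warning); an all-zero
  generation query returns the model's finite intercept response.
* MTX orientation is disambiguated against sidecar lengths; a square
  matrix with equal-length sidecars is refused as ambiguous.
* Model archives are JSON with C99 hex-float literals, so
  `load_model(save_model(m))` restores weights bit-for-bit; shape
  mismatches against the stored config are errors.
* The held-out variance in the generation recovery criterion is computed
  over all target entries (the MSE of the global constant predictor),
  the unit-consistent comparison for an MSE over all entries; the
  alternative (mean of per-feature variances) is stricter and noted here
  for transparency.

## 7. Known limitations

* One decoder layer and a 16-wide latent by default: at desk scale the
  generation quality plateaus slightly above the level of a rank-16
  linear regression ceiling; the architecture's pooled causal latent
  trades some attainable accuracy for its multimodal structure.
* No imbalanced-cell-count extension, no optimal-transport post-hoc
  alignment, no multi-batch atlas workflow, no pretraining: out of
  scope by design.
* ATAC enters as a precomputed peak × cell matrix; no fragment/BAM
  processing.
* The H5AD path shells out to Python's `anndata`; without a Python
  environment the MTX/CSV paths are the supported formats.
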