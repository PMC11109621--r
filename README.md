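# scmformer

Multi-task transformer integration and cross-modality generation for
paired single-cell multimodal data, in R.

## The problem

Protocols such as CITE-seq, REAP-seq, ASAP-seq and DOGMA-seq measure two
or three omics layers — RNA, surface protein (ADT), chromatin
accessibility — in the *same* single cells. Two questions follow:

1. **Integration** — embed each modality into a shared latent space so
   that the two views of the same cell land next to each other (and
   cell-type labels transfer across modalities);
2. **Generation** — given only one measured modality (say RNA), predict
   the unmeasured one (say the protein panel).

`scmformer` implements a transformer-decoder approach to both tasks,
together with the matching evaluation metrics and a seeded synthetic
generator of paired data, so the entire system is testable on a laptop
with no downloads.

## The model

Each cell's preprocessed expression vector (all modalities PCA-aligned to
a common width *D*) is partitioned into *n_sub = D/s* contiguous
**sub-vectors** of length *s* — the attention tokens — with learned
additive positional and modality embeddings. Tokens pass through a
decoder layer with pre-norm residuals:

    X1 = X + Merge(MultiHead(LayerNorm(X)))
    X2 = X1 + ReLU(LayerNorm(X1) W1 + b1) W2 + b2

whose attention is the **scm-attention** variant: ReLU everywhere, no
softmax, and a causal mask so position *p* only sees positions *≤ p*:

    Q, K, V = ReLU(split(X W + b)),   W ∈ R^{s×3s}
    head    = ReLU(Mask(Q K^T / sqrt(s))) V

Per modality, decoder outputs are average-pooled into a latent
`X_average ∈ R^{cells×s}` and a linear head reconstructs the input
(`X_rec = X_average W + b`). Training is multi-task:

    Loss_integration = λ · Σ_m MSE(X_rec,m , X_m)  +  MSE(X_average,mod1 , X_average,mod2)

(fusion term averaged over all unordered pairs for triple-omics), and for
generation simply `MSE(prediction, measured target)`. Optimisation is
Adam at a fixed learning rate with seeded mini-batches; everything is
bitwise reproducible given the seed.

Evaluation: **FOSCTTM** (fraction of samples closer than the true match;
0 = perfect, 0.5 = random), kNN cross-modality label transfer
(accuracy, macro-F1), and per-feature Pearson/Spearman + MSE/RMSE for
generated profiles.

## Worked example

```r
library(scmformer)

# a seeded paired CITE-seq-like world: 600 cells, 3 types, 400 genes, 40 proteins
sim <- simulate_paired(sim_config(seed = 0))
sim$dataset
#> <paired_dataset> 2 modalities (rna, protein), 600 cells, pairing=by_order

# normalize (library-size+log RNA, CLR protein), align both to 128 dims by PCA
prep <- preprocess_paired(sim$dataset,
                          preprocess_config(n_hvg = 400, aligned_dim = 128))

# multi-task training: lambda * reconstruction + latent fusion
model <- train_integration(prep$reduced, scm_config(seed = 0))
tail(model$trace, 3)
#>    epoch     loss       rec      comb
#> 18    18 57.03282 0.8056512 0.6372355
#> 19    19 56.70327 0.8011491 0.6228315
#> 20    20 56.44393 0.7977298 0.6028472

lat <- extract_latents(model, prep$reduced)
metrics_report(lat$rna, lat$protein, labels = sim$dataset$labels)
#> <metrics_report>
#>   foscttm   0.1222
#>   accuracy  0.9967
#>   macro_f1  0.9966
```

The trace shows both loss components falling; after 20 epochs the paired
cells are well aligned (FOSCTTM 0.12 against a 0.5 random baseline) and
protein-side cells inherit the correct type from their RNA neighbours
99.7% of the time.

For generation, fit the preprocessing on training cells and replay it on
queries:

```r
pp    <- fit_preprocessor(rna_train, preprocess_config())
model <- train_generation(apply_preprocessor(pp, rna_train),
                          normalize_protein(adt_train))
pred  <- generate(model, apply_preprocessor(pp, rna_query))
```

## Command line

```sh
scmformer simulate  --preset small --seed 0 --out sim/
scmformer integrate --rna sim/rna --protein sim/protein --labels sim/labels.csv \
                    --sub-len 16 --heads 4 --lambda 70 --epochs 20 --seed 0 --out run/
scmformer generate  --train-rna rna.csv --train-protein adt.csv \
                    --query-rna query.csv --out pred/
scmformer evaluate  --latents-a run/latent_rna.csv --latents-b run/latent_protein.csv \
                    --labels sim/labels.csv --out report.json
```

Every run writes a `manifest.json` (effective config, seed, input MD5
hashes, package version) before compute starts, plus loss traces,
latents (CSV, and H5AD when Python/anndata is available) and a metrics
report.

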