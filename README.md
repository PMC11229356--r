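# scMosaicVAE

Simultaneous **horizontal** (batch-effect removal) and **vertical**
(cross-modality) integration of paired single-cell multimodal data
(RNA+ATAC, RNA+ADT), and **mosaic** integration of paired with unimodal
data.  The package is aimed at analysts who have cell-by-feature count
matrices from Multiome- or CITE-seq-style assays across several samples,
sites or conditions, and who want one batch-corrected joint embedding of
all cells.

## The model

A variational autoencoder with:

* a **logistic-normal latent** `z_n` on the probability simplex
  (k = 20 by default), built from modality-specific encoder branches whose
  hidden representations are concatenated ("early-stage integration");
* **modality-specific likelihoods** on raw-scale data — negative binomial
  for RNA counts, `log P(x) = lgamma(x+θ) − lgamma(θ) − lgamma(x+1) +
  θ log(θ/(θ+μ)) + x log(μ/(θ+μ))` with mean `μ = l_n · softmax(logits)`,
  a **negative multinomial** over a cell's whole binarized accessibility
  profile (feature probabilities plus a residual probability, shared
  overdispersion `r`), and the NB form on CLR-transformed antibody tags;
* **cell- and modality-specific size factors** `l_n`, `d_n` with
  batch-indexed log-normal priors fixed from the data;
* **batch conditioning** via per-batch size-factor priors and dispersions,
  a conditional encoder and/or decoder (one-hot batch appended), and
* a **batch-adversarial term**: a classifier predicts the batch from `z_n`
  through a gradient reversal layer; its cross-entropy joins the loss
  scaled by a tunable `α`, so
  `loss = loss_rna + loss_atac/adt + KL_z + KL_l + KL_d + α · loss_adv`.

All published ablation variants are presets (`variantConfig()`): `vae`,
`batchvae`, `cevae`, `cdvae`, `cvae`, `avae`, `bavae` (the default:
conditional decoder + adversary).  Mosaic cells with one modality measured
are handled by zeroing the missing branch's input and all loss terms that
refer to it.  The optimisation (mini-batch 128, Adam, lr 1e-3, weight decay
1e-6, 95/5 split, early stopping with patience 10, best-model restoration)
is hand-implemented with an analytic backward pass; no deep-learning
framework is required.

A synthetic-data module (`simulateMultimodal()`, `syntheticPreset()`)
generates multimodal datasets with known cell types, nested batch effects
and library sizes, and integration metrics (`ilisi()`, `nmiScore()`,
`aswLabel()`, `aswBatch()`, `clusterForNmi()`) score mixing and
bio-conservation.  See the methods vignette
(`vignettes/multimodal-integration.Rmd`) for the full model account.

## Worked example

```r
library(scMosaicVAE)
sim <- syntheticPreset("paired", seed = 1, nCells = 600)
ds <- sim$dataset
ds
#> MultimodalDataset with 600 cells
#>   rna: 200 features (600 cells measured)
#>   atac: 500 features (600 cells measured)
#>   batches: b1, b2
#>   cellData: cell_type

model <- fitModel(ds, variantConfig("bavae", alpha = 1, seed = 0),
                  maxEpochs = 20)
z <- embedCells(model, ds)          # 600 x 20, rows on the simplex
round(head(z[, 1:5], 3), 3)
#>       factor1 factor2 factor3 factor4 factor5
#> cell1   0.034   0.034   0.070   0.053   0.060
#> cell2   0.061   0.071   0.037   0.061   0.031
#> cell3   0.037   0.068   0.057   0.040   0.057

ilisi(z, batchCodes(ds))            # batch mixing in [0,1]; higher = better
#> 0.509
attr(clusterForNmi(z, cellData(ds)$cell_type, seed = 0), "nmi")
#> 0.943                             # cell types preserved in the embedding
cor(sizeFactors(model, ds)[, "rna"], sim$truth$log_lib_rna)
#> 0.811                             # inferred log size factors vs truth
```

A batch iLISI of 0.51 means the two batches are about half-way to perfectly
interleaved in embedding neighbourhoods (the uncorrected `vae` variant
scores ≈ 0 on the same data), while an NMI of 0.94 says Leiden clusters of
the embedding almost exactly reproduce the simulated cell types.

## Command line

A thin CLI over the same functions ships in `inst/scripts/scmvae`:

```sh
scmvae simulate --preset paired --seed 0 --out data/
scmvae train    --input data/ --variant bavae --alpha 1 --seed 0 --out model.rds
scmvae embed    --input data/ --checkpoint model.rds --out embedding.tsv
scmvae evaluate --embedding embedding.tsv --input data/ \
                --ilisi-vars batch --nmi-var cell_type --out metrics.tsv
```

Every subcommand writes a JSON run manifest next to its output; a YAML file
passed via `--config` is merged under explicit flags.

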