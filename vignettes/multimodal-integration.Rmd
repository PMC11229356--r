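---
title: "Multimodal and mosaic single-cell integration with scMosaicVAE"
author: "scMosaicVAE maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal and mosaic single-cell integration with scMosaicVAE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scMosaicVAE)
```

# The integration problem

Paired multimodal single-cell assays measure two molecular layers in the
same cells: gene expression together with chromatin accessibility
(Multiome-style) or with cell-surface protein abundance via antibody-derived
tags (CITE-seq-style).  Analysing such data requires solving two integration
problems at once: *vertical* integration (combining modalities with very
different dimensionality and noise into one representation) and *horizontal*
integration (removing technical batch effects across samples, sites or
replicates while keeping biology).  A third, *mosaic*, setting adds samples
in which only one modality was measured at all.

scMosaicVAE implements a variational autoencoder that addresses all three
settings simultaneously and returns a batch-corrected joint low-dimensional
embedding of the cells.

# The model

## Observation models

Each modality keeps its own likelihood, evaluated on the raw-scale data:

* **RNA**: raw counts \(x_{ng}\) are negative binomial with mean
  \(\mu_{ng} = l_n \, w_{ng}\), where \(w_{n\cdot}\) is a softmax over
  decoder feature logits (so \(\sum_g w_{ng} = 1\)) and \(l_n > 0\) is a
  cell-specific size factor capturing sequencing depth.  The dispersion
  \(\theta_{sg}\) is a free parameter per gene and (optionally) per batch
  \(s\).
* **ATAC**: the binarized accessibility profile of a cell is modelled
  *jointly* with a negative multinomial: feature probabilities
  \((p_1,\dots,p_G, p_0)\) come from a softmax over the decoder's feature
  logits plus one residual logit, with a per-batch overdispersion \(r_s\).
  The log-likelihood of a profile \(x\) is
  \(\log\Gamma(r+\sum_i x_i) - \log\Gamma(r) - \sum_i \log\Gamma(x_i+1)
  + r\log p_0 + \sum_i x_i \log p_i\).
  The cell-specific accessibility size factor \(d_n\) enters the decoder as
  an extra node appended to the penultimate layer.  We feed \(\log d_n\)
  rather than \(d_n\): the magnitude of a raw library size is unbounded and
  would dominate a layer whose other activations are normalized.
* **ADT**: antibody-tag inputs are CLR-transformed across features
  (`clrTransform()`).  They are scored with the same negative-binomial form
  as RNA using the size factor \(d_n\).  Because CLR values are real-valued,
  the likelihood is evaluated as a continuous log-Gamma relaxation of the NB
  probability mass function after shifting each cell's values to be
  non-negative by its row minimum (`shiftNonNegative()`).  This convention
  is isolated in one function; it is a pragmatic pairing of a count
  likelihood with compositional inputs, not a calibrated count model.

## Latent variables

The per-cell latent \(z_n\) is logistic-normal: the encoder outputs a
Gaussian mean and variance in \(\mathbb{R}^k\) (default \(k = 20\)), a
reparameterized sample is pushed through a softmax, and the embedding rows
therefore live on the probability simplex.  This makes latent loadings
interpretable as compositions.  Size factors \(l_n, d_n\) are log-normal
with *batch-indexed priors* fixed from the data: per batch, the mean and
variance of the per-cell log library size.  (The variance could also be read
"literally" as the spread of the per-batch means; `priorVariance =
"literal"` exposes that reading.  The per-cell reading is the default
because a per-batch scalar has no within-batch variance and the per-cell
convention matches the scVI model family this architecture descends from.)

The KL regularizers are closed-form diagonal-Gaussian divergences
(`klDiagGaussian()`): standard-normal prior for the pre-softmax latent
coordinates, batch-indexed log-normal priors for the size factors.

## Encoder, decoder, and conditioning

Each modality has its own input layer and one hidden layer (width 128 by
default); the two hidden representations are concatenated to form the latent
posterior ("early-stage integration"), and each also feeds a small branch
producing its size-factor posterior.  All hidden layers use layer
normalization and ReLU; dropout (default 0.1) is applied in the encoder
only.  Decoders have two hidden layers per modality and no dropout.  For
mosaic cells the unmeasured modality's encoder input is all-zero, and every
loss term referring to that modality (reconstruction and its size-factor KL)
is exactly zero for that cell.

Batch handling is controlled by independent switches that reproduce the
published ablation series (`variantConfig()`): batch-specific size-factor
priors and dispersions (`batchvae`), a conditional encoder (`cevae`), a
conditional decoder (`cdvae`, both: `cvae`), a batch-adversarial term
(`avae`), and the default combination of conditional decoder plus adversary
(`bavae`).  The plain `vae` disables all of it.  With a conditional decoder
the one-hot batch is appended to the decoder input, letting reconstruction
absorb batch effects so the embedding does not have to encode them.

## Adversarial batch removal

A batch classifier (one hidden layer of 32 nodes) receives a sample of
\(z_n\) through a **gradient reversal layer**: forward it is the identity;
backward it negates the gradient (constant \(-1\)).  The classifier's
cross-entropy joins the total loss scaled by \(\alpha\):

\[
\mathrm{loss} = \mathrm{loss}_{rna} + \mathrm{loss}_{atac/adt}
 + KL_z + KL_l + KL_d + \alpha \cdot \mathrm{loss}_{adv}.
\]

One joint optimizer minimises this total; through the reversal the encoder
*ascends* the classifier loss, removing batch-predictive structure from the
latent, and \(\alpha\) is the single knob controlling batch-mixing strength.

**Two-timescale refinement.**  With a single joint Adam step per mini-batch
the classifier cannot track the moving latent: empirically its cross-entropy
stays at or above \(\log B\) while the latent remains perfectly
batch-separable, and the reversed gradient then rewards *confidently wrong*
predictions instead of genuine mixing (at large \(\alpha\) mixing actually
degrades).  We therefore keep the discriminator near its best response by
adding a few cheap classifier-only update steps per mini-batch (`advSteps`,
default 10) at a faster learning rate (`advLr`, default 1e-2), computed on
the mini-batch's fixed latent sample.  This is the standard two-timescale
prescription for adversarial training; with it, increasing \(\alpha\)
monotonically strengthens batch mixing as published.  The gradient-reversal
semantics of the joint step are unchanged (and are verified against finite
differences in the test suite).

## Training schedule

`fitModel()` uses mini-batches of 128 cells, Adam with learning rate 1e-3
and weight decay 1e-6, a uniform random 95/5 train/validation split, early
stopping with patience 10 on the validation total, and restoration of the
best-validation parameters.  A safety cap (`maxEpochs`, default 500) bounds
runtime.  All randomness (split, initialization, mini-batch order,
reparameterization noise, dropout) derives from the configuration seed, so
runs are bit-reproducible on one platform.  The deterministic embedding is
`softmax` of the latent posterior mean — no sampling at evaluation time.

Numerical conventions: probabilities are clamped at 1e-8 before logs;
posterior log-variances are clamped to \(\pm 10\) and sampled log size
factors to \(\pm 20\); dispersions are stored as unconstrained logs
initialised at zero.  One genuine non-smoothness is worth knowing about:
cells whose input row is entirely zero meet layer norm and ReLU exactly at
their kinks when all biases are zero (the initialisation point), so gradient
checks are performed at perturbed parameters; training leaves the kink after
the first update.

# The synthetic study conditions

`simulateMultimodal()` generates data with known ground truth matching the
model's assumptions: discrete cell types with shared programs across
modalities (per-type log-fold feature programs, sd 1 by default — a strong,
recoverable type signal), nested batch effects (per-batch multiplicative
log-fold feature biases, sd 1 — a strong batch effect — plus per-batch
library-size shifts of \(\pm 0.4\) on the log scale), NB counts for RNA
(dispersion 10, median library ~2000), Bernoulli-thinned binary ATAC
(baseline density 0.1), and NB counts CLR-transformed for ADT.  The presets
define the study designs used throughout the tests:

* `paired` — 2000 cells, 3 types, 2 batches, fully paired RNA+ATAC: the
  default benchmark for the ablation series.
* `treatment-control` — 1000 cells, RNA+ADT, a 2-replicate x 2-condition
  design; technical biases follow the *replicate* while a marker block
  (10% of genes up, 10% down, plus an ADT block) responds to stimulation
  only.  This makes the choice of batch variable consequential: removing
  "sample" scrubs the treatment effect, removing "replicate" keeps it.
* `mosaic-full` / `mosaic-a` / `mosaic-b` — four sites of which only one
  stays paired; the others keep a single modality, optionally with the
  binarized ATAC values subsampled to 10% per cell
  (`subsampleFeatureValues()`), emulating low-quality assays.

What these fixtures do *not* emulate: peak-to-gene linkage, doublets,
ambient contamination, zero-inflation beyond the NB, or cell-type
proportions shifting across batches.  Passing tests therefore demonstrate
the mechanics of the model under its own assumptions, not performance on
any real dataset.

Problem sizes in the test suite are chosen to keep a full run comfortable on
one CPU: the paired-benchmark fits use 30 training epochs, the
treatment-control design 50 and the mosaic scenario 60 (their structure
crystallises more slowly), with 1–3 seeds per comparison.

# Metrics

* `ilisi()` — perplexity-weighted local inverse Simpson index of a label in
  embedding neighbourhoods (default 90 neighbours, perplexity 30), rescaled
  to [0, 1]; higher = better mixed.  This is a self-contained implementation
  of the LISI family; it is not bound to any external package's graph
  variant, and is validated against an independent enumeration oracle in the
  tests.
* `nmiScore()` — mutual information normalized by the arithmetic mean of
  the label entropies; `clusterForNmi()` provides the standard
  kNN-graph + Leiden sweep over resolutions, keeping the labeling that
  maximizes NMI against the reference.
* `aswLabel()` / `aswBatch()` — silhouette-based bio-conservation and
  within-cell-type batch-mixing scores, both mapped to [0, 1]; groups
  containing a single batch are scored as perfectly mixed and flagged.
  Distances are Euclidean on the embedding.
* Donor- or subset-restricted variants are obtained by subsetting first and
  scoring after (`metricReport(subset = ...)`); there is no special code
  path.

# Design choices made where the design was open

* **CLR pseudocount**: 1 by default, configurable; standard practice for
  ADT counts.
* **Subsampling granularity**: "retain a fraction of feature values per
  cell" is implemented as per-cell thinning of that cell's nonzero entries,
  rounding to the nearest integer.
* **Batch category ordering**: sorted lexicographically at dataset
  construction and persisted in the container, so one-hot encodings are
  reproducible.
* **Hidden widths**: 128 throughout by default, a typical choice for this
  model family at \(k = 20\); all widths are configurable.
* **Encoder inputs**: `log1p` counts for RNA, binary ATAC, CLR ADT — the
  convention of the scVI lineage.
* **Size-factor posterior offset**: the batch prior mean is added to the
  size-factor posterior-mean head as a fixed offset.  This is a pure
  reparameterisation (the KL is unchanged in form) that starts the sampler
  at the right scale and avoids an early race between size factors and
  feature logits.
* **Container format**: a plain-text directory of MatrixMarket matrices,
  TSV metadata and a JSON manifest — readable by any toolchain and
  diff-friendly; `readDataset()`/`writeDataset()` round-trip exactly.
* **Mosaic loss bookkeeping**: reconstruction terms are means over the
  cells that measured the modality (not over all cells), and masked cells
  contribute exactly zero to the matching KL.

# Known limitations

* The adversarial game is a minimax optimisation; very large \(\alpha\)
  (beyond ~50 under the default conditions) trades bio-conservation for
  mixing, and the two-timescale classifier refresh is a heuristic
  stabiliser, not a convergence guarantee.
* The ADT likelihood on CLR values is a relaxation (see above); absolute
  ADT loss values are not comparable across preprocessing choices.
* Trimodal decoders (RNA+ATAC+ADT in one model) are out of scope; a model
  uses one or two modalities.
* Imputation / modality translation is explicitly not the package's task:
  the output is the joint embedding, not reconstructed data.
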