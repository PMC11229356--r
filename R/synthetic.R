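#' Specification for a synthetic multimodal dataset
#'
#' Defines the ground-truth generative conditions for a simulated multimodal
#' experiment: discrete cell types sharing programs across modalities,
#' nested batch effects (multiplicative per-feature biases plus per-batch
#' library-size shifts), NB-distributed RNA counts, Bernoulli-thinned binary
#' ATAC profiles, NB-distributed ADT counts, optional treatment-control
#' design with replicate structure, and optional mosaic masking of whole
#' modalities per batch.
#'
#' @param nCells number of cells (default 2000)
#' @param nTypes number of cell types (default 3)
#' @param nBatches number of batches; ignored when `design` is given
#' @param nRna,nAtac,nAdt features per modality (defaults 200/500/30)
#' @param modalities which modalities to simulate
#' @param typeStrength sd of the per-type log-fold feature programs
#'   (default 1, a strong type signal)
#' @param batchStrength sd of the per-batch multiplicative log-fold feature
#'   biases (default 1, a strong batch effect)
#' @param libMeanlog base mean of per-cell log library size for rna
#'   (default log(2000))
#' @param libSdlog sd of per-cell log library size (default 0.3)
#' @param libBatchShift per-batch additive shifts of `libMeanlog`; defaults
#'   to an equally spaced spread over `[-0.4, 0.4]`
#' @param adtLibMeanlog base mean log library size for adt (default log(500))
#' @param atacDensity baseline accessibility probability (default 0.1)
#' @param nbDispersion NB size parameter for rna/adt counts (default 10)
#' @param design optional data.frame with one row per batch (rownames =
#'   batch/sample names) and columns `replicate` and `condition`; batch
#'   biases are then keyed by replicate (technical) while `condition`
#'   effects are biological
#' @param conditionEffect log-fold effect applied to a marker block of
#'   features in the "stimulated" condition (a block up-regulated, a second
#'   block depleted); 0 disables
#' @param mosaicPlan named list batch -> modality to drop (see
#'   [makeMosaic()])
#' @param seed integer seed; fully determines the output
#' @return a validated spec (list of class `SyntheticSpec`)
#' @export
syntheticSpec <- function(nCells = 2000L, nTypes = 3L, nBatches = 2L,
                          nRna = 200L, nAtac = 500L, nAdt = 30L,
                          modalities = c("rna", "atac"),
                          typeStrength = 1, batchStrength = 1,
                          libMeanlog = log(2000), libSdlog = 0.3,
                          libBatchShift = NULL,
                          adtLibMeanlog = log(500), atacDensity = 0.1,
                          nbDispersion = 10, design = NULL,
                          conditionEffect = 0, mosaicPlan = NULL, seed = 0L) {
  if (!is.null(design)) nBatches <- nrow(design)
  if (nTypes > nCells) stop("syntheticSpec: more types than cells")
  if (atacDensity <= 0 || atacDensity >= 1)
    stop("syntheticSpec: atacDensity must be in (0,1)")
  if (is.null(libBatchShift))
    libBatchShift <- if (nBatches > 1)
      seq(-0.4, 0.4, length.out = nBatches) else 0
  spec <- list(nCells = as.integer(nCells), nTypes = as.integer(nTypes),
               nBatches = as.integer(nBatches), nRna = as.integer(nRna),
               nAtac = as.integer(nAtac), nAdt = as.integer(nAdt),
               modalities = modalities, typeStrength = typeStrength,
               batchStrength = batchStrength, libMeanlog = libMeanlog,
               libSdlog = libSdlog, libBatchShift = libBatchShift,
               adtLibMeanlog = adtLibMeanlog, atacDensity = atacDensity,
               nbDispersion = nbDispersion, design = design,
               conditionEffect = conditionEffect, mosaicPlan = mosaicPlan,
               seed = as.integer(seed))
  class(spec) <- "SyntheticSpec"
  spec
}

#' Simulate a multimodal dataset with known ground truth
#'
#' RNA counts are negative-binomial with mean `libsize * softmax(type
#' program + batch bias)`; ATAC is Bernoulli with logit `baseline + type
#' program + batch bias`, binarized; ADT is negative-binomial on a small
#' panel, CLR-transformed via [clrTransform()] before entering the dataset
#' (exercising the standard input path).  Condition effects, when a design
#' is given, apply to a dedicated marker block only, so batch-variable
#' choices (replicate vs sample) have distinguishable consequences.
#' Deterministic per seed.
#'
#' @param spec a [syntheticSpec()]
#' @return list with `dataset` (a [MultimodalDataset-class]; cell type and
#'   any replicate/condition labels in `cellData`) and `truth` (data.frame
#'   of per-cell ground truth incl. true log library sizes)
#' @export
simulateMultimodal <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  restore <- localRNG(spec$seed)
  on.exit(restore())
  n <- spec$nCells
  B <- spec$nBatches
  batchNames <- if (!is.null(spec$design)) rownames(spec$design)
                else paste0("b", seq_len(B))
  type <- sample.int(spec$nTypes, n, replace = TRUE)
  batch <- sample.int(B, n, replace = TRUE)
  repl <- if (!is.null(spec$design)) spec$design$replicate[batch] else NULL
  cond <- if (!is.null(spec$design)) spec$design$condition[batch] else NULL
  # technical biases are keyed by replicate when a design is present
  biasKey <- if (!is.null(repl)) match(repl, unique(spec$design$replicate))
             else batch
  nBias <- max(biasKey)
  stim <- if (!is.null(cond)) cond == "Stim" else rep(FALSE, n)

  mods <- list(); truth <- data.frame(cell = paste0("cell", seq_len(n)),
                                      cell_type = paste0("t", type),
                                      batch = batchNames[batch])
  condBlock <- function(G) {
    nb <- max(1L, round(0.1 * G))
    list(up = seq_len(nb), down = nb + seq_len(nb))
  }

  if ("rna" %in% spec$modalities) {
    prog <- matrix(rnorm(spec$nTypes * spec$nRna, sd = spec$typeStrength),
                   spec$nTypes, spec$nRna)
    bias <- matrix(rnorm(nBias * spec$nRna, sd = spec$batchStrength),
                   nBias, spec$nRna)
    logit <- prog[type, , drop = FALSE] + bias[biasKey, , drop = FALSE]
    if (spec$conditionEffect > 0) {
      blk <- condBlock(spec$nRna)
      logit[stim, blk$up] <- logit[stim, blk$up] + spec$conditionEffect
      logit[stim, blk$down] <- logit[stim, blk$down] - spec$conditionEffect
    }
    pr <- softmaxRows(logit)
    lib <- exp(rnorm(n, spec$libMeanlog + spec$libBatchShift[batch],
                     spec$libSdlog))
    mu <- pr * lib
    x <- matrix(rnbinom(n * spec$nRna, mu = mu, size = spec$nbDispersion),
                n, spec$nRna)
    colnames(x) <- paste0("gene", seq_len(spec$nRna))
    mods$rna <- x
    truth$log_lib_rna <- log(lib)
  }
  if ("atac" %in% spec$modalities) {
    prog <- matrix(rnorm(spec$nTypes * spec$nAtac, sd = spec$typeStrength),
                   spec$nTypes, spec$nAtac)
    bias <- matrix(rnorm(nBias * spec$nAtac, sd = spec$batchStrength),
                   nBias, spec$nAtac)
    logit <- qlogis(spec$atacDensity) + prog[type, , drop = FALSE] +
      bias[biasKey, , drop = FALSE]
    if (spec$conditionEffect > 0) {
      blk <- condBlock(spec$nAtac)
      logit[stim, blk$up] <- logit[stim, blk$up] + spec$conditionEffect
      logit[stim, blk$down] <- logit[stim, blk$down] - spec$conditionEffect
    }
    # per-batch library shift realised as an additive logit offset
    logit <- logit + spec$libBatchShift[batch]
    p <- plogis(logit)
    x <- matrix(rbinom(n * spec$nAtac, 1L, p), n, spec$nAtac)
    colnames(x) <- paste0("peak", seq_len(spec$nAtac))
    mods$atac <- x
    truth$log_lib_atac <- log(pmax(rowSums(x), 1))
  }
  if ("adt" %in% spec$modalities) {
    prog <- matrix(rnorm(spec$nTypes * spec$nAdt, sd = spec$typeStrength),
                   spec$nTypes, spec$nAdt)
    bias <- matrix(rnorm(nBias * spec$nAdt, sd = spec$batchStrength / 2),
                   nBias, spec$nAdt)
    logit <- prog[type, , drop = FALSE] + bias[biasKey, , drop = FALSE]
    if (spec$conditionEffect > 0) {
      nb <- max(1L, round(0.15 * spec$nAdt))
      logit[stim, seq_len(nb)] <- logit[stim, seq_len(nb)] +
        spec$conditionEffect
    }
    pr <- softmaxRows(logit)
    lib <- exp(rnorm(n, spec$adtLibMeanlog + spec$libBatchShift[batch] / 2,
                     spec$libSdlog))
    counts <- matrix(rnbinom(n * spec$nAdt, mu = pr * lib,
                             size = spec$nbDispersion), n, spec$nAdt)
    colnames(counts) <- paste0("adt", seq_len(spec$nAdt))
    mods$adt <- clrTransform(counts)
    truth$log_lib_adt <- log(pmax(rowSums(counts), 1))
  }

  cd <- data.frame(cell_type = truth$cell_type, row.names = truth$cell)
  if (!is.null(spec$design)) {
    cd$replicate <- repl
    cd$condition <- cond
    cd$sample <- batchNames[batch]
  }
  ds <- MultimodalDataset(mods, batch = batchNames[batch],
                          cells = truth$cell, colData = cd)
  if (!is.null(spec$mosaicPlan)) ds <- makeMosaic(ds, spec$mosaicPlan)
  list(dataset = ds, truth = truth)
}

#' Study-design presets for the synthetic generator
#'
#' * `paired` — 2000 cells, 3 types, 2 batches, strong batch effect,
#'   rna+atac fully paired (the default integration benchmark).
#' * `treatment-control` — 1000 cells, rna+adt, four samples from a 2
#'   replicate x 2 condition design (Rep1/Rep2 x Ctrl/Stim); technical
#'   biases follow the replicate, a marker block responds to stimulation.
#' * `mosaic-full` — 1600 cells, 3 types, four sites; sites s1/s3 keep only
#'   atac, s2 keeps only rna, s4 stays paired.
#' * `mosaic-a` / `mosaic-b` — as `mosaic-full`, with the binarized atac
#'   feature values additionally subsampled to 10% per cell for the
#'   unimodal atac sites (`a`) or the paired site (`b`).
#'
#' @param preset preset name
#' @param seed integer seed
#' @param nCells optional override of the preset's cell count (e.g. for
#'   quick smoke runs)
#' @return list with `dataset` and `truth` as in [simulateMultimodal()]
#' @export
syntheticPreset <- function(preset = c("paired", "treatment-control",
                                       "mosaic-full", "mosaic-a", "mosaic-b"),
                            seed = 0L, nCells = NULL) {
  preset <- match.arg(preset)
  if (preset == "paired") {
    return(simulateMultimodal(syntheticSpec(
      nCells = if (is.null(nCells)) 2000L else nCells, seed = seed)))
  }
  if (preset == "treatment-control") {
    design <- data.frame(
      replicate = c("Rep1", "Rep1", "Rep2", "Rep2"),
      condition = c("Ctrl", "Stim", "Ctrl", "Stim"),
      row.names = c("Rep1_Ctrl", "Rep1_Stim", "Rep2_Ctrl", "Rep2_Stim"))
    return(simulateMultimodal(syntheticSpec(
      nCells = if (is.null(nCells)) 1000L else nCells,
      nRna = 150L, nAdt = 30L,
      modalities = c("rna", "adt"), design = design,
      conditionEffect = 2, seed = seed)))
  }
  # mosaic scenarios: four sites, paired rna+atac at s4 only
  plan <- list(s1 = "rna", s2 = "atac", s3 = "rna")
  sim <- simulateMultimodal(syntheticSpec(
    nCells = if (is.null(nCells)) 1600L else nCells,
    nBatches = 4L, modalities = c("rna", "atac"),
    seed = seed))
  # rename batches to sites and apply the drop plan
  lv <- levels(batchCodes(sim$dataset))
  siteNames <- paste0("s", seq_along(lv))
  sim$dataset@batchCodes <- factor(
    siteNames[match(as.character(batchCodes(sim$dataset)), lv)],
    levels = siteNames)
  sim$truth$batch <- as.character(batchCodes(sim$dataset))
  ds <- makeMosaic(sim$dataset, plan)
  if (preset %in% c("mosaic-a", "mosaic-b")) {
    target <- if (preset == "mosaic-a") c("s1", "s3") else "s4"
    idx <- as.character(batchCodes(ds)) %in% target &
      modalityMask(ds)[, "atac"]
    atac <- ds@modalities$atac
    atac[idx, ] <- subsampleFeatureValues(atac[idx, , drop = FALSE], 0.1,
                                          seed = seed + 1L)
    ds@modalities$atac <- atac
  }
  sim$dataset <- ds
  sim
}

#' Swap the batch variable of a dataset
#'
#' Returns a dataset whose batch codes are taken from a `cellData` column
#' (e.g. `"replicate"` instead of `"sample"`), with the level ordering
#' frozen lexicographically.  This is how "which variable should the model
#' remove" is selected.
#'
#' @param dataset a [MultimodalDataset-class]
#' @param var column name in `cellData(dataset)`
#' @return a [MultimodalDataset-class]
#' @export
withBatchVariable <- function(dataset, var) {
  cd <- cellData(dataset)
  if (!var %in% colnames(cd))
    stop("withBatchVariable: no cellData column '", var, "'")
  v <- as.character(cd[[var]])
  dataset@batchCodes <- factor(v, levels = sort(unique(v)))
  validObject(dataset)
  dataset
}
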