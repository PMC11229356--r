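#' Deterministic train/validation split
#'
#' Uniform random (non-stratified) split of cells into disjoint, exhaustive
#' train and validation index sets; deterministic given `seed`.
#'
#' @param dataset a [MultimodalDataset-class] or an integer cell count
#' @param fraction training fraction (default 0.95)
#' @param seed integer seed
#' @return list with integer vectors `train` and `val`
#' @export
splitTrainVal <- function(dataset, fraction = 0.95, seed = 0L) {
  n <- if (is(dataset, "MultimodalDataset")) nCells(dataset)
       else as.integer(dataset)
  if (n < 20L) stop("splitTrainVal: need at least 20 cells")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("splitTrainVal: fraction must be in (0, 1)")
  restore <- localRNG(seed)
  on.exit(restore())
  ntrain <- round(fraction * n)
  train <- sort(sample.int(n, ntrain))
  list(train = train, val = setdiff(seq_len(n), train))
}

sliceData <- function(pd, idx) {
  list(xin = lapply(pd$xin, function(x) x[idx, , drop = FALSE]),
       xtgt = lapply(pd$xtgt, function(x) x[idx, , drop = FALSE]),
       S = pd$S[idx, , drop = FALSE], bidx = pd$bidx[idx],
       mask = pd$mask[idx, , drop = FALSE], n = length(idx))
}

termsToRow <- function(terms, prefix) {
  out <- as.data.frame(terms[c("loss_rna", "loss_atac", "loss_adt", "kl_z",
                               "kl_l", "kl_d", "loss_adv", "total")])
  names(out) <- paste0(prefix, "_", names(out))
  out
}

#' Fit the multimodal VAE
#'
#' Mini-batch Adam optimisation (batch size 128, learning rate 1e-3, weight
#' decay 1e-6) of the total loss on a 95/5 train/validation split, with
#' early stopping after `patience` epochs without validation improvement and
#' restoration of the best-validation parameters.  Fully reproducible given
#' the configuration seed.  Cells with unmeasured modalities (mosaic
#' integration) contribute zero to the corresponding reconstruction and
#' size-factor KL terms.
#'
#' @param dataset a validated [MultimodalDataset-class]
#' @param config a [ModelConfig-class] (see [modelConfig()],
#'   [variantConfig()])
#' @param maxEpochs safety cap on epochs (default 500; the schedule relies
#'   on early stopping)
#' @param patience early-stopping patience in epochs (default 10)
#' @param batchSize mini-batch size (default 128)
#' @param lr,weightDecay Adam learning rate and weight decay
#' @param trainFraction fraction of cells in the training split (default
#'   0.95; the remainder is the validation set)
#' @param advSteps extra classifier-only update steps per mini-batch
#'   (default 10).  The batch classifier must track the moving latent
#'   closely for the reversed gradient to reward genuine mixing rather than
#'   confidently-wrong predictions; these cheap discriminator refreshes keep
#'   it near its best response (a two-timescale scheme).
#' @param advLr learning rate of the classifier refresh steps (default
#'   1e-2, faster than the joint step).
#' @param verbose print per-epoch validation totals
#' @return a trained [MultimodalVAE-class]
#' @export
fitModel <- function(dataset, config, maxEpochs = 500L, patience = 10L,
                     batchSize = 128L, lr = 1e-3, weightDecay = 1e-6,
                     trainFraction = 0.95, advSteps = 10L, advLr = 1e-2,
                     verbose = FALSE) {
  validObject(dataset)
  validObject(config)
  restore <- localRNG(config@seed)
  on.exit(restore())
  seeds <- sample.int(.Machine$integer.max - 1L, 3L)

  batchLevels <- levels(batchCodes(dataset))
  pd <- prepModelData(dataset, config, batchLevels)
  priors <- computeSizeFactorPriors(dataset, config, batchLevels)
  featureNames <- lapply(dataset@modalities[config@modalitySet], colnames)
  dims <- modelDims(config, featureNames, length(batchLevels))

  idx <- splitTrainVal(nCells(dataset), trainFraction, seeds[1])
  trainD <- sliceData(pd, idx$train)
  valD <- sliceData(pd, idx$val)

  set.seed(seeds[2])
  params <- initVaeParams(config, dims)
  opt <- adamInit(params)

  set.seed(seeds[3])
  best <- list(total = Inf, params = params, epoch = 0L)
  waited <- 0L
  history <- NULL
  nTrain <- trainD$n

  for (epoch in seq_len(maxEpochs)) {
    ord <- sample.int(nTrain)
    starts <- seq(1L, nTrain, by = batchSize)
    acc <- NULL; accW <- 0
    for (s in starts) {
      take <- ord[s:min(s + batchSize - 1L, nTrain)]
      mb <- sliceData(trainD, take)
      noise <- drawNoise(mb$n, dims, config, train = TRUE)
      fw <- vaeForward(params, mb, config, dims, priors, noise, train = TRUE)
      if (!is.finite(fw$terms$total)) {
        bad <- names(which(!vapply(fw$terms, is.finite, logical(1))))
        stop("non-finite loss at epoch ", epoch, "; offending term(s): ",
             paste(bad, collapse = ", "))
      }
      gr <- vaeBackward(params, mb, config, dims, priors, noise, fw)
      upd <- adamStep(params, gr, opt, lr = lr, weight_decay = weightDecay)
      params <- upd$params; opt <- upd$state
      if (config@adversary && advSteps > 0L) {
        zfix <- fw$cache$z
        for (s in seq_len(advSteps)) {
          ag <- advClassifierGrads(params, zfix, mb$bidx)
          upd <- adamStep(params, ag$grads, opt, lr = advLr,
                          weight_decay = weightDecay)
          params <- upd$params; opt <- upd$state
        }
      }
      w <- mb$n
      tv <- unlist(fw$terms[c("loss_rna", "loss_atac", "loss_adt", "kl_z",
                              "kl_l", "kl_d", "loss_adv", "total")])
      acc <- if (is.null(acc)) tv * w else acc + tv * w
      accW <- accW + w
    }
    trainTerms <- as.list(acc / accW)
    valNoise <- drawNoise(valD$n, dims, config, train = FALSE)
    valFw <- vaeForward(params, valD, config, dims, priors, valNoise,
                        train = FALSE, keep_cache = FALSE)
    vt <- valFw$terms$total
    history <- rbind(history,
                     cbind(data.frame(epoch = epoch),
                           termsToRow(trainTerms, "train"),
                           termsToRow(valFw$terms, "val")))
    if (verbose)
      message(sprintf("epoch %d: train %.4f  val %.4f", epoch,
                      trainTerms$total, vt))
    if (vt < best$total) {
      best <- list(total = vt, params = params, epoch = epoch)
      waited <- 0L
    } else {
      waited <- waited + 1L
      if (waited >= patience) break
    }
  }

  new("MultimodalVAE", config = config, params = best$params,
      priors = priors, batchLevels = batchLevels,
      featureNames = featureNames, history = history,
      bestEpoch = as.integer(best$epoch))
}

checkFeatures <- function(model, dataset) {
  for (m in model@config@modalitySet) {
    have <- colnames(modality(dataset, m))
    want <- model@featureNames[[m]]
    if (!identical(have, want)) {
      missing <- setdiff(want, have)
      stop("feature mismatch for modality '", m, "'",
           if (length(missing)) paste0("; missing: ",
             paste(utils::head(missing, 10), collapse = ", ")) else
             "; feature order differs")
    }
  }
}

#' @describeIn embedCells Deterministic per-cell embedding: softmax of the
#'   latent posterior mean, computed with unmeasured modality inputs zeroed
#'   and no sampling.  Rows lie on the probability simplex.
#' @param dataset a [MultimodalDataset-class] with the training features
#' @export
setMethod("embedCells", "MultimodalVAE", function(object, dataset, ...) {
  validObject(dataset)
  checkFeatures(object, dataset)
  pd <- prepModelData(dataset, object@config, object@batchLevels)
  dims <- modelDims(object@config, object@featureNames,
                    length(object@batchLevels))
  out <- vaeEmbedForward(object@params, pd, object@config, dims, object@priors)
  z <- out$z
  rownames(z) <- dataset@cells
  colnames(z) <- paste0("factor", seq_len(ncol(z)))
  z
})

#' @describeIn sizeFactors Posterior-mean log size factors per cell, one
#'   column per modality (`l` for rna, `d` for atac/adt), natural log scale.
#' @param dataset a [MultimodalDataset-class]
#' @export
setMethod("sizeFactors", "MultimodalVAE", function(object, dataset, ...) {
  validObject(dataset)
  checkFeatures(object, dataset)
  pd <- prepModelData(dataset, object@config, object@batchLevels)
  dims <- modelDims(object@config, object@featureNames,
                    length(object@batchLevels))
  out <- vaeEmbedForward(object@params, pd, object@config, dims, object@priors)
  res <- do.call(cbind, out$log_sf_mean)
  colnames(res) <- names(out$log_sf_mean)
  rownames(res) <- dataset@cells
  res
})

setMethod("show", "MultimodalVAE", function(object) {
  cfg <- object@config
  cat("MultimodalVAE (", paste(cfg@modalitySet, collapse = "+"), ")\n", sep = "")
  cat("  latent dim:", cfg@latentDim,
      " conditional enc/dec:", cfg@conditionalEncoder, "/",
      cfg@conditionalDecoder, "\n")
  cat("  adversary:", cfg@adversary,
      if (cfg@adversary) paste0(" (alpha = ", cfg@alpha, ")") else "", "\n")
  cat("  batches:", paste(object@batchLevels, collapse = ", "), "\n")
  cat("  trained epochs:", nrow(object@history),
      " best epoch:", object@bestEpoch, "\n")
})

#' Save / load a trained model checkpoint
#'
#' A checkpoint is a single file holding the configuration, all parameters,
#' the size-factor prior tables, the frozen batch ordering and feature
#' names, with a versioned schema.
#'
#' @param model a [MultimodalVAE-class]
#' @param path file path
#' @return `loadCheckpoint` returns the [MultimodalVAE-class]
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "MultimodalVAE"))
  saveRDS(list(schema = "scMosaicVAE-checkpoint-v1", model = model), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "scMosaicVAE-checkpoint-v1"))
    stop("not a scMosaicVAE checkpoint: ", path)
  obj$model
}
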