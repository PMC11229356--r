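#' @import methods
#' @importFrom stats rnorm runif rbinom rnbinom var sd cor dist setNames
#'   plogis qlogis dnbinom dmultinom
NULL

MODALITY_NAMES <- c("rna", "atac", "adt")

#' Container for paired (and mosaic) multimodal single-cell data
#'
#' Holds aligned cell-by-feature matrices for up to three modalities
#' (`rna`: raw integer counts, `atac`: binarized counts, `adt`: CLR-scale
#' values), a per-cell categorical batch variable with a frozen level
#' ordering (so one-hot encodings are reproducible), and a per-cell,
#' per-modality logical mask marking which modalities were actually measured
#' (the mosaic case).  Unmeasured modalities are stored as all-zero rows.
#'
#' @slot cells character vector of cell identifiers (unique, ordered).
#' @slot modalities named list of numeric matrices, one per modality; all
#'   share the same rows (cells).
#' @slot batchCodes factor of length `nCells` with a fixed level ordering.
#' @slot modalityMask logical matrix, cells x modalities; `TRUE` = measured.
#' @slot colData data.frame of additional per-cell annotations (cell type,
#'   replicate, condition, ...); may have zero columns.
#'
#' @export
setClass("MultimodalDataset",
  representation(
    cells = "character",
    modalities = "list",
    batchCodes = "factor",
    modalityMask = "matrix",
    colData = "data.frame"
  )
)

setValidity("MultimodalDataset", function(object) {
  msg <- character()
  n <- length(object@cells)
  mods <- object@modalities
  if (length(mods) == 0L) msg <- c(msg, "at least one modality is required")
  if (!all(names(mods) %in% MODALITY_NAMES))
    msg <- c(msg, sprintf("modality names must be among: %s",
                          paste(MODALITY_NAMES, collapse = ", ")))
  for (m in names(mods)) {
    if (nrow(mods[[m]]) != n)
      msg <- c(msg, sprintf("modality '%s' has %d rows but there are %d cells",
                            m, nrow(mods[[m]]), n))
    if (is.null(colnames(mods[[m]])))
      msg <- c(msg, sprintf("modality '%s' lacks feature names", m))
  }
  if (length(object@batchCodes) != n)
    msg <- c(msg, "batchCodes length does not match number of cells")
  if (anyNA(object@batchCodes))
    msg <- c(msg, "batchCodes must not contain NA")
  mk <- object@modalityMask
  if (!is.logical(mk) || nrow(mk) != n ||
      !identical(colnames(mk), names(mods)))
    msg <- c(msg, "modalityMask must be a logical cells x modalities matrix")
  else if (any(rowSums(mk) == 0L))
    msg <- c(msg, "every cell must have at least one measured modality")
  if ("rna" %in% names(mods)) {
    x <- mods[["rna"]]
    if (any(x < 0) || any(x != round(x)))
      msg <- c(msg, "rna entries must be non-negative integers")
  }
  if ("atac" %in% names(mods)) {
    x <- mods[["atac"]]
    if (!all(x %in% c(0, 1)))
      msg <- c(msg, "atac entries must be binary (0/1)")
  }
  if ("adt" %in% names(mods) && any(!is.finite(mods[["adt"]])))
    msg <- c(msg, "adt entries must be finite")
  if (nrow(object@colData) != 0L && nrow(object@colData) != n)
    msg <- c(msg, "colData rows do not match number of cells")
  if (length(msg)) msg else TRUE
})

#' Model configuration for the multimodal VAE
#'
#' All architectural switches of the model.  The published ablation variants
#' are pure preset expansions of this configuration; see [variantConfig()].
#'
#' @slot latentDim integer, dimension k of the logistic-normal latent space.
#' @slot encoderHidden,decoderHidden integer hidden widths (the decoder uses
#'   two hidden layers of `decoderHidden` nodes each).
#' @slot conditionalEncoder,conditionalDecoder logical; append the one-hot
#'   batch to the encoder input layers / to the decoder input.
#' @slot adversary logical; train a batch classifier through a gradient
#'   reversal layer.
#' @slot alpha non-negative scaling of the adversarial loss term.
#' @slot batchSpecificSizeFactors,batchSpecificDispersion logical; per-batch
#'   size-factor priors and per-batch dispersion parameters.
#' @slot dropout encoder dropout rate (decoders and classifier use none).
#' @slot adversaryHidden width of the classifier's single hidden layer.
#' @slot modalitySet character subset of c("rna","atac","adt") the model uses.
#' @slot priorVariance "per_cell" (variance of per-cell log library sizes per
#'   batch) or "literal" (variance across the per-batch means).
#' @slot seed integer master seed.
#' @export
setClass("ModelConfig",
  representation(
    latentDim = "integer",
    encoderHidden = "integer",
    decoderHidden = "integer",
    conditionalEncoder = "logical",
    conditionalDecoder = "logical",
    adversary = "logical",
    alpha = "numeric",
    batchSpecificSizeFactors = "logical",
    batchSpecificDispersion = "logical",
    dropout = "numeric",
    adversaryHidden = "integer",
    modalitySet = "character",
    priorVariance = "character",
    seed = "integer"
  ),
  prototype(
    latentDim = 20L,
    encoderHidden = 128L,
    decoderHidden = 128L,
    conditionalEncoder = FALSE,
    conditionalDecoder = FALSE,
    adversary = FALSE,
    alpha = 1,
    batchSpecificSizeFactors = TRUE,
    batchSpecificDispersion = TRUE,
    dropout = 0.1,
    adversaryHidden = 32L,
    modalitySet = c("rna", "atac"),
    priorVariance = "per_cell",
    seed = 0L
  )
)

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (object@latentDim < 2L) msg <- c(msg, "latentDim must be >= 2")
  if (object@alpha < 0) msg <- c(msg, "alpha must be non-negative")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0, 1)")
  if (!all(object@modalitySet %in% MODALITY_NAMES) ||
      length(object@modalitySet) < 1L || length(object@modalitySet) > 2L)
    msg <- c(msg, "modalitySet must be one or two of rna/atac/adt")
  if (!object@priorVariance %in% c("per_cell", "literal"))
    msg <- c(msg, "priorVariance must be 'per_cell' or 'literal'")
  if (length(msg)) msg else TRUE
})

#' A trained multimodal VAE
#'
#' Returned by [fitModel()].  Stores the configuration, all learned
#' parameters, the fixed size-factor priors, the frozen batch level ordering
#' and the per-modality feature names used at training time, plus the
#' training history (per-epoch loss breakdowns).
#'
#' @slot config a [ModelConfig-class].
#' @slot params named list of parameter matrices/vectors.
#' @slot priors named list of per-modality size-factor priors (mu, var per
#'   batch).
#' @slot batchLevels character, frozen batch category ordering.
#' @slot featureNames named list of per-modality feature names.
#' @slot history data.frame with one row per epoch (train/validation loss
#'   breakdowns).
#' @slot bestEpoch integer epoch whose validation total was minimal.
#' @export
setClass("MultimodalVAE",
  representation(
    config = "ModelConfig",
    params = "list",
    priors = "list",
    batchLevels = "character",
    featureNames = "list",
    history = "data.frame",
    bestEpoch = "integer"
  )
)
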