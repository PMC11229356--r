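#' Create a model configuration
#'
#' Convenience constructor for [ModelConfig-class] with the package defaults
#' (latent dimension 20, hidden width 128, encoder dropout 0.1, classifier
#' hidden width 32).
#'
#' @param latentDim latent dimension k (>= 2)
#' @param encoderHidden,decoderHidden hidden widths
#' @param conditionalEncoder,conditionalDecoder append the one-hot batch to
#'   the encoder inputs / decoder input
#' @param adversary train the batch classifier through gradient reversal
#' @param alpha non-negative adversarial loss scaling
#' @param batchSpecificSizeFactors,batchSpecificDispersion per-batch
#'   size-factor priors / dispersion parameters
#' @param dropout encoder dropout rate
#' @param adversaryHidden classifier hidden width
#' @param modalitySet modalities the model uses; one of
#'   `c("rna","atac")`, `c("rna","adt")`, `"rna"`, `"atac"`, `"adt"`
#' @param priorVariance `"per_cell"` or `"literal"` (see
#'   [ModelConfig-class])
#' @param seed integer master seed
#' @return a validated [ModelConfig-class]
#' @export
modelConfig <- function(latentDim = 20L, encoderHidden = 128L,
                        decoderHidden = 128L, conditionalEncoder = FALSE,
                        conditionalDecoder = FALSE, adversary = FALSE,
                        alpha = 1, batchSpecificSizeFactors = TRUE,
                        batchSpecificDispersion = TRUE, dropout = 0.1,
                        adversaryHidden = 32L,
                        modalitySet = c("rna", "atac"),
                        priorVariance = "per_cell", seed = 0L) {
  if (length(modalitySet) == 2L && !"rna" %in% modalitySet)
    stop("two-modality models must pair rna with atac or adt")
  cfg <- new("ModelConfig", latentDim = as.integer(latentDim),
             encoderHidden = as.integer(encoderHidden),
             decoderHidden = as.integer(decoderHidden),
             conditionalEncoder = conditionalEncoder,
             conditionalDecoder = conditionalDecoder,
             adversary = adversary, alpha = alpha,
             batchSpecificSizeFactors = batchSpecificSizeFactors,
             batchSpecificDispersion = batchSpecificDispersion,
             dropout = dropout, adversaryHidden = as.integer(adversaryHidden),
             modalitySet = modalitySet, priorVariance = priorVariance,
             seed = as.integer(seed))
  validObject(cfg)
  cfg
}

#' Expand a published ablation-variant name into a configuration
#'
#' Pure mapping from variant name to configuration flags.  All variants have
#' batch-specific size factors and dispersion parameters except the plain
#' `vae` (no batch correction at all):
#'
#' * `vae` — no batch machinery at all
#' * `batchvae` — batch-specific size-factor priors and dispersions only
#' * `cevae` — conditional encoder only
#' * `cdvae` — conditional decoder only
#' * `cvae` — conditional encoder and decoder
#' * `avae` — batch-adversarial term only (scaling `alpha`)
#' * `bavae` — conditional decoder + batch-adversarial term (the default
#'   architecture)
#'
#' @param variant one of the names above (case-insensitive)
#' @param alpha adversarial scaling (used by `avae`/`bavae`)
#' @param ... further arguments forwarded to [modelConfig()]
#' @return a [ModelConfig-class]
#' @examples
#' variantConfig("bavae", alpha = 50)
#' @export
variantConfig <- function(variant, alpha = 1, ...) {
  variant <- match.arg(tolower(variant),
                       c("vae", "batchvae", "cevae", "cdvae", "cvae",
                         "avae", "bavae"))
  flags <- switch(variant,
    vae = list(batchSpecificSizeFactors = FALSE,
               batchSpecificDispersion = FALSE),
    batchvae = list(),
    cevae = list(conditionalEncoder = TRUE),
    cdvae = list(conditionalDecoder = TRUE),
    cvae = list(conditionalEncoder = TRUE, conditionalDecoder = TRUE),
    avae = list(adversary = TRUE, alpha = alpha),
    bavae = list(conditionalDecoder = TRUE, adversary = TRUE, alpha = alpha))
  do.call(modelConfig, c(flags, list(...)))
}
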