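#' @rdname MultimodalDataset-class
#' @param x,object a `MultimodalDataset`
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname MultimodalDataset-class
#' @export
setGeneric("modalityNames", function(x) standardGeneric("modalityNames"))

#' @rdname MultimodalDataset-class
#' @param modality modality name, one of "rna", "atac", "adt"
#' @export
setGeneric("modality", function(x, modality) standardGeneric("modality"))

#' @rdname MultimodalDataset-class
#' @export
setGeneric("batchCodes", function(x) standardGeneric("batchCodes"))

#' @rdname MultimodalDataset-class
#' @export
setGeneric("modalityMask", function(x) standardGeneric("modalityMask"))

#' @rdname MultimodalDataset-class
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))

#' Deterministic latent embedding of cells
#'
#' @param object a trained [MultimodalVAE-class]
#' @param ... further arguments passed to methods
#' @export
setGeneric("embedCells", function(object, ...) standardGeneric("embedCells"))

#' Posterior-mean size factors
#'
#' @param object a trained [MultimodalVAE-class]
#' @param ... further arguments passed to methods
#' @export
setGeneric("sizeFactors", function(object, ...) standardGeneric("sizeFactors"))
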