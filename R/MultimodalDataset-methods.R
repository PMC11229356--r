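#' Construct a MultimodalDataset
#'
#' Assembles aligned per-modality matrices, the per-cell batch variable and
#' an optional per-modality measurement mask into a validated container.
#' Batch categories are sorted lexicographically and frozen, so one-hot
#' encodings are reproducible across sessions.  Cells measured in zero
#' modalities are rejected.
#'
#' @param modalities named list of cell-by-feature matrices; names among
#'   `"rna"` (raw integer counts), `"atac"` (binary), `"adt"` (CLR scale).
#' @param batch per-cell batch labels (character or factor).
#' @param mask optional logical cells x modalities matrix (`TRUE` =
#'   measured).  Defaults to all measured.
#' @param cells optional cell identifiers; defaults to rownames of the first
#'   modality or `cell1..cellN`.
#' @param colData optional data.frame of extra per-cell annotations.
#' @return a [MultimodalDataset-class]
#' @examples
#' rna <- matrix(rpois(20, 5), 4, 5,
#'               dimnames = list(NULL, paste0("g", 1:5)))
#' ds <- MultimodalDataset(list(rna = rna), batch = c("a", "a", "b", "b"))
#' nCells(ds)
#' @export
MultimodalDataset <- function(modalities, batch, mask = NULL, cells = NULL,
                              colData = NULL) {
  stopifnot(is.list(modalities), length(modalities) >= 1L)
  modalities <- lapply(modalities, function(m) as.matrix(m))
  # canonical modality order
  ord <- intersect(MODALITY_NAMES, names(modalities))
  if (length(ord) != length(modalities))
    stop("modality names must be among: ", paste(MODALITY_NAMES, collapse = ", "))
  modalities <- modalities[ord]
  n <- nrow(modalities[[1]])
  if (is.null(cells)) {
    cells <- rownames(modalities[[1]])
    if (is.null(cells)) cells <- paste0("cell", seq_len(n))
  }
  for (m in names(modalities)) {
    if (is.null(colnames(modalities[[m]])))
      colnames(modalities[[m]]) <- paste0(m, "_f", seq_len(ncol(modalities[[m]])))
    rownames(modalities[[m]]) <- cells
  }
  # frozen lexicographic batch level ordering
  batch <- factor(as.character(batch), levels = sort(unique(as.character(batch))))
  if (is.null(mask)) {
    mask <- matrix(TRUE, n, length(modalities),
                   dimnames = list(cells, names(modalities)))
  } else {
    mask <- as.matrix(mask)
    storage.mode(mask) <- "logical"
    if (is.null(colnames(mask))) colnames(mask) <- names(modalities)
    mask <- mask[, names(modalities), drop = FALSE]
    rownames(mask) <- cells
  }
  if (any(rowSums(mask) == 0L))
    stop("cells measured in zero modalities are not allowed: ",
         paste(utils::head(cells[rowSums(mask) == 0L], 5), collapse = ", "))
  if (is.null(colData)) colData <- data.frame(row.names = cells)
  new("MultimodalDataset", cells = as.character(cells),
      modalities = modalities, batchCodes = batch,
      modalityMask = mask, colData = colData)
}

#' @rdname MultimodalDataset-class
#' @export
setMethod("nCells", "MultimodalDataset", function(x) length(x@cells))

#' @rdname MultimodalDataset-class
#' @export
setMethod("modalityNames", "MultimodalDataset", function(x) names(x@modalities))

#' @rdname MultimodalDataset-class
#' @export
setMethod("modality", "MultimodalDataset", function(x, modality) {
  if (!modality %in% names(x@modalities))
    stop("modality '", modality, "' not present")
  x@modalities[[modality]]
})

#' @rdname MultimodalDataset-class
#' @export
setMethod("batchCodes", "MultimodalDataset", function(x) x@batchCodes)

#' @rdname MultimodalDataset-class
#' @export
setMethod("modalityMask", "MultimodalDataset", function(x) x@modalityMask)

#' @rdname MultimodalDataset-class
#' @export
setMethod("cellData", "MultimodalDataset", function(x) x@colData)

#' @rdname MultimodalDataset-class
#' @param i integer/logical/character index of cells to keep
#' @param j,drop ignored
#' @export
setMethod("[", "MultimodalDataset", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@cells)
  new("MultimodalDataset",
      cells = x@cells[i],
      modalities = lapply(x@modalities, function(m) m[i, , drop = FALSE]),
      batchCodes = x@batchCodes[i],
      modalityMask = x@modalityMask[i, , drop = FALSE],
      colData = x@colData[i, , drop = FALSE])
})

setMethod("show", "MultimodalDataset", function(object) {
  cat("MultimodalDataset with", nCells(object), "cells\n")
  for (m in modalityNames(object)) {
    cat(sprintf("  %s: %d features (%d cells measured)\n", m,
                ncol(object@modalities[[m]]), sum(object@modalityMask[, m])))
  }
  cat("  batches:", paste(levels(object@batchCodes), collapse = ", "), "\n")
  if (ncol(object@colData))
    cat("  cellData:", paste(colnames(object@colData), collapse = ", "), "\n")
})

# one-hot encoding of the (frozen-order) batch variable
oneHotBatch <- function(batch, levels = base::levels(batch)) {
  m <- matrix(0, length(batch), length(levels),
              dimnames = list(NULL, levels))
  m[cbind(seq_along(batch), match(as.character(batch), levels))] <- 1
  m
}
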