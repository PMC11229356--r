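#' Centered log-ratio transform across features
#'
#' Per cell (row), `log(x + pseudocount)` centered by its mean over features,
#' the standard normalisation for antibody-derived-tag (ADT) counts.  Rows of
#' the result have exactly zero mean.
#'
#' @param counts non-negative numeric matrix (cells x features)
#' @param pseudocount positive real added before the log (default 1)
#' @return numeric matrix of the same shape; row means are 0
#' @examples
#' clrTransform(matrix(c(0, 3), 1, 2))  # c(-log(2), log(2))
#' @export
clrTransform <- function(counts, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("clrTransform: negative input values")
  if (ncol(counts) < 1L) stop("clrTransform: need at least one feature")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("clrTransform: pseudocount must be > 0")
  lg <- log(counts + pseudocount)
  out <- lg - rowMeans(lg)
  dimnames(out) <- dimnames(counts)
  out
}

#' Binarize a count matrix
#'
#' Entry is 1 iff the input entry is positive; the convention for chromatin
#' accessibility counts.  Idempotent.
#'
#' @param counts non-negative numeric matrix
#' @return 0/1 matrix of the same shape
#' @export
binarizeCounts <- function(counts) {
  out <- (as.matrix(counts) > 0) * 1
  dimnames(out) <- dimnames(counts)
  out
}

#' Per-cell subsampling of binary feature values
#'
#' Retains, for each cell, `round(fraction * n_nonzero)` of that cell's
#' nonzero entries (uniformly chosen, deterministic given `seed`) and sets
#' the remainder to 0.  The feature set itself is unchanged; this emulates a
#' low-quality assay of the same features.
#'
#' @param x binary matrix (cells x features)
#' @param fraction fraction of nonzero values to retain, in (0, 1]
#' @param seed integer seed
#' @return binary matrix of the same shape
#' @export
subsampleFeatureValues <- function(x, fraction, seed = 0L) {
  x <- as.matrix(x)
  if (!all(x %in% c(0, 1))) stop("subsampleFeatureValues: input must be binary")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("subsampleFeatureValues: fraction must be in (0, 1]")
  if (fraction == 1) return(x)
  out <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  rng <- localRNG(seed)
  on.exit(rng())
  for (i in seq_len(nrow(x))) {
    nz <- which(x[i, ] > 0)
    keep <- round(fraction * length(nz))
    if (keep > 0L) out[i, nz[sample.int(length(nz), keep)]] <- 1
  }
  out
}

#' Drop whole modalities for selected batches (mosaic construction)
#'
#' Emulates mosaic study designs in which some batches (e.g. sequencing
#' sites) measured only one modality: for every batch in `dropPlan` the named
#' modality is zeroed and its measurement mask set to `FALSE` for all cells
#' of that batch.  A plan that would leave any cell with no measured
#' modality is an error.
#'
#' @param dataset a [MultimodalDataset-class]
#' @param dropPlan named list/character: names are batch levels, values the
#'   modality to drop for that batch
#' @return a new [MultimodalDataset-class] with the same cells
#' @export
makeMosaic <- function(dataset, dropPlan) {
  stopifnot(is(dataset, "MultimodalDataset"))
  dropPlan <- as.list(dropPlan)
  if (length(dropPlan) == 0L) return(dataset)
  mask <- modalityMask(dataset)
  mods <- dataset@modalities
  batch <- as.character(batchCodes(dataset))
  for (b in names(dropPlan)) {
    m <- dropPlan[[b]]
    if (!b %in% levels(batchCodes(dataset)))
      stop("makeMosaic: unknown batch '", b, "'")
    if (!m %in% modalityNames(dataset))
      stop("makeMosaic: unknown modality '", m, "'")
    idx <- batch == b
    mask[idx, m] <- FALSE
    mods[[m]][idx, ] <- 0
  }
  if (any(rowSums(mask) == 0L))
    stop("makeMosaic: plan would remove all modalities for some cells")
  new("MultimodalDataset", cells = dataset@cells, modalities = mods,
      batchCodes = dataset@batchCodes, modalityMask = mask,
      colData = dataset@colData)
}

#' Write / read a MultimodalDataset to a plain-text container directory
#'
#' The on-disk container is a directory of MatrixMarket matrices plus TSV
#' metadata tables and a JSON manifest, readable by any standard toolchain:
#' `<mod>_matrix.mtx` and `<mod>_features.tsv` per modality, `cells.tsv`,
#' `obs.tsv` (batch, per-modality mask, any extra annotations) and
#' `manifest.json` (modality names, frozen batch level ordering).  The
#' round trip `readDataset(writeDataset(d))` preserves matrices, masks and
#' batch codes exactly.
#'
#' @param dataset a [MultimodalDataset-class]
#' @param path directory to create/overwrite
#' @return `writeDataset` returns `path` invisibly; `readDataset` returns a
#'   [MultimodalDataset-class].
#' @export
writeDataset <- function(dataset, path) {
  stopifnot(is(dataset, "MultimodalDataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (m in modalityNames(dataset)) {
    Matrix::writeMM(methods::as(Matrix::Matrix(dataset@modalities[[m]],
                                               sparse = TRUE), "generalMatrix"),
                    file.path(path, paste0(m, "_matrix.mtx")))
    utils::write.table(data.frame(feature = colnames(dataset@modalities[[m]])),
                       file.path(path, paste0(m, "_features.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  obs <- data.frame(cell = dataset@cells,
                    batch = as.character(batchCodes(dataset)),
                    stringsAsFactors = FALSE)
  for (m in modalityNames(dataset))
    obs[[paste0("mask_", m)]] <- modalityMask(dataset)[, m]
  cd <- cellData(dataset)
  for (cc in colnames(cd)) obs[[cc]] <- cd[[cc]]
  utils::write.table(obs, file.path(path, "obs.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- list(format = "scMosaicVAE-container", version = 1L,
                   modalities = modalityNames(dataset),
                   batch_levels = levels(batchCodes(dataset)),
                   extra_columns = colnames(cd))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeDataset
#' @export
readDataset <- function(path) {
  manifest_file <- file.path(path, "manifest.json")
  if (!file.exists(manifest_file))
    stop("readDataset: no manifest.json under ", path)
  manifest <- jsonlite::read_json(manifest_file, simplifyVector = TRUE)
  obs_file <- file.path(path, "obs.tsv")
  if (!file.exists(obs_file)) stop("readDataset: missing obs.tsv")
  obs <- utils::read.table(obs_file, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"batch" %in% colnames(obs))
    stop("readDataset: obs.tsv lacks the required 'batch' column")
  mods <- list()
  mask <- NULL
  for (m in manifest$modalities) {
    x <- as.matrix(Matrix::readMM(file.path(path, paste0(m, "_matrix.mtx"))))
    storage.mode(x) <- "double"
    feats <- utils::read.table(file.path(path, paste0(m, "_features.tsv")),
                               sep = "\t", header = TRUE)$feature
    if (nrow(x) != nrow(obs))
      stop("readDataset: modality '", m, "' has ", nrow(x),
           " cells but obs.tsv has ", nrow(obs))
    colnames(x) <- feats
    mods[[m]] <- x
    mask <- cbind(mask, obs[[paste0("mask_", m)]])
  }
  colnames(mask) <- manifest$modalities
  extra <- intersect(manifest$extra_columns, colnames(obs))
  cd <- obs[, extra, drop = FALSE]
  rownames(cd) <- obs$cell
  ds <- MultimodalDataset(mods, batch = obs$batch, mask = mask,
                          cells = obs$cell, colData = cd)
  # restore the persisted level ordering
  ds@batchCodes <- factor(as.character(ds@batchCodes),
                          levels = manifest$batch_levels)
  validObject(ds)
  ds
}

# run code under a temporary RNG state; returns the restore function
localRNG <- function(seed) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, envir = .GlobalEnv)
  }
}
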