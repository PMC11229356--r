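#' Integration local inverse Simpson index (iLISI)
#'
#' Perplexity-weighted local inverse Simpson index of a categorical variable
#' in embedding neighbourhoods.  For each cell, Gaussian kernel weights over
#' its `nNeighbors` nearest neighbours (Euclidean) are calibrated to the
#' given `perplexity` by bisecting the kernel bandwidth; the inverse Simpson
#' index of the weighted label distribution is averaged over cells and
#' rescaled from `[1, B]` to `[0, 1]` via `(value - 1) / (B - 1)`.  Higher
#' means better mixing of the scored variable.
#'
#' @param embedding numeric matrix, cells x dimensions
#' @param labels per-cell categorical labels (>= 2 categories)
#' @param nNeighbors neighbourhood size (default 90, capped at n - 1)
#' @param perplexity kernel perplexity (default 30)
#' @param rescale return the `[0, 1]`-rescaled value (default) or the raw
#'   index in `[1, B]`
#' @return scalar iLISI
#' @export
ilisi <- function(embedding, labels, nNeighbors = 90L, perplexity = 30,
                  rescale = TRUE) {
  embedding <- as.matrix(embedding)
  labels <- as.factor(as.character(labels))
  n <- nrow(embedding)
  B <- nlevels(labels)
  if (B < 2L) stop("ilisi: need at least 2 label categories")
  if (n <= 2L) stop("ilisi: need more than 2 cells")
  k <- min(as.integer(nNeighbors), n - 1L)
  perplexity <- min(perplexity, k * 0.99)
  d2 <- as.matrix(dist(embedding))^2
  li <- as.integer(labels)
  simpson <- numeric(n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ])
    nb <- setdiff(ord, i)[seq_len(k)]
    dd <- d2[i, nb]
    # bisection on precision beta so the weight entropy matches log(perplexity)
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      w <- exp(-dd * beta)
      sw <- sum(w)
      if (sw == 0) { H <- 0; p <- rep(0, k); p[which.min(dd)] <- 1 }
      else {
        p <- w / sw
        H <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    pb <- vapply(seq_len(B), function(b) sum(p[li[nb] == b]), numeric(1))
    simpson[i] <- sum(pb^2)
  }
  val <- mean(1 / simpson)
  if (rescale) (val - 1) / (B - 1) else val
}

#' Normalized mutual information between two labelings
#'
#' Mutual information normalized by the arithmetic mean of the two label
#' entropies; in `[0, 1]`, with 1 for identical labelings and 0 when either
#' labeling is constant (zero-entropy convention).
#'
#' @param labelsA,labelsB equal-length label vectors
#' @return scalar NMI
#' @export
nmiScore <- function(labelsA, labelsB) {
  if (length(labelsA) == 0L || length(labelsA) != length(labelsB))
    stop("nmiScore: need two equal-length, non-empty labelings")
  tab <- table(labelsA, labelsB)
  n <- sum(tab)
  pij <- tab / n
  pi <- rowSums(pij); pj <- colSums(pij)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  outer_p <- outer(pi, pj)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer_p[nz]))
  denom <- (ent(pi) + ent(pj)) / 2
  if (denom == 0) return(0)
  max(0, min(1, mi / denom))
}

#' Graph clustering of an embedding for NMI scoring
#'
#' Builds a k-nearest-neighbour graph on the embedding (Euclidean), runs
#' Leiden community detection at each resolution in `resolutions`, and
#' returns the labeling that maximizes NMI against `reference`.
#' Deterministic given `seed`.
#'
#' @param embedding numeric matrix, cells x dimensions
#' @param reference per-cell reference labels the sweep is scored against
#' @param resolutions numeric vector of Leiden resolutions
#' @param nNeighbors kNN graph degree (default 15)
#' @param seed integer seed
#' @return factor of community labels (attribute `"resolution"` holds the
#'   winning resolution, `"nmi"` its NMI)
#' @export
clusterForNmi <- function(embedding, reference,
                          resolutions = seq(0.1, 2, by = 0.1),
                          nNeighbors = 15L, seed = 0L) {
  embedding <- as.matrix(embedding)
  if (any(!is.finite(embedding))) stop("clusterForNmi: embedding must be finite")
  n <- nrow(embedding)
  k <- min(as.integer(nNeighbors), n - 1L)
  d <- as.matrix(dist(embedding))
  nbmat <- vapply(seq_len(n), function(i) {
    ord <- order(d[i, ])
    ord[ord != i][seq_len(k)]
  }, integer(k))
  edges <- cbind(rep(seq_len(n), each = k), as.integer(nbmat))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  best <- NULL; bestNmi <- -1; bestRes <- NA_real_
  restore <- localRNG(seed)
  on.exit(restore())
  for (res in resolutions) {
    set.seed(seed)
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = res, n_iterations = 3L)
    memb <- igraph::membership(cl)
    v <- nmiScore(memb, reference)
    if (v > bestNmi) { bestNmi <- v; best <- memb; bestRes <- res }
  }
  out <- factor(best)
  attr(out, "resolution") <- bestRes
  attr(out, "nmi") <- bestNmi
  out
}

#' Average-silhouette-width scores for bio-conservation and batch removal
#'
#' `aswLabel` scores how well cell-type labels separate in the embedding:
#' `(mean silhouette + 1) / 2`, in `[0, 1]`, higher = better conservation.
#' `aswBatch` scores batch mixing within cell-type groups: per group, the
#' mean over its cells of `1 - |silhouette on batch labels|`, averaged over
#' groups; higher = better mixing.  Groups containing a single batch
#' contribute perfect-mixing scores and are flagged in the
#' `"single_batch_groups"` attribute.  Distances are Euclidean on the
#' embedding.
#'
#' @param embedding numeric matrix, cells x dimensions
#' @param labels cell-type labels (`aswLabel`) / `batch` batch labels and
#'   `groups` cell-type groups (`aswBatch`)
#' @return scalar in `[0, 1]`
#' @export
aswLabel <- function(embedding, labels) {
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) < 2L) stop("aswLabel: need >= 2 label categories")
  sil <- cluster::silhouette(as.integer(labels), dist(as.matrix(embedding)))
  (mean(sil[, "sil_width"]) + 1) / 2
}

#' @rdname aswLabel
#' @param batch per-cell batch labels
#' @param groups per-cell grouping (cell types) within which batch mixing is
#'   scored
#' @export
aswBatch <- function(embedding, batch, groups) {
  embedding <- as.matrix(embedding)
  batch <- as.factor(as.character(batch))
  groups <- as.factor(as.character(groups))
  perGroup <- numeric(0)
  flagged <- character(0)
  for (gname in levels(groups)) {
    idx <- groups == gname
    b <- droplevels(batch[idx])
    if (nlevels(b) < 2L || sum(idx) < 3L) {
      perGroup <- c(perGroup, 1)   # single batch: treated as perfect mixing
      flagged <- c(flagged, gname)
      next
    }
    sil <- cluster::silhouette(as.integer(b),
                               dist(embedding[idx, , drop = FALSE]))
    perGroup <- c(perGroup, mean(1 - abs(sil[, "sil_width"])))
  }
  out <- mean(perGroup)
  attr(out, "single_batch_groups") <- flagged
  out
}

#' Tabulated metric report for an embedding
#'
#' Computes a set of integration metrics against per-cell meta-variables and
#' returns them as a tidy data.frame (metric, target variable, value, subset
#' description).
#'
#' @param embedding numeric matrix, cells x dimensions
#' @param meta data.frame of per-cell variables
#' @param ilisiVars variables to score with [ilisi()]
#' @param nmiVar reference labels for NMI (clustered via [clusterForNmi()]);
#'   `NULL` to skip
#' @param aswLabelVar labels for [aswLabel()]; `NULL` to skip
#' @param aswBatchVars `list(batch =, groups =)` variable names for
#'   [aswBatch()]; `NULL` to skip
#' @param subset optional logical mask of cells to score ("subset-then-score")
#' @param subsetDescription free-text description of the subset
#' @param seed seed for the clustering sweep
#' @return data.frame with columns metric, target, value, subset
#' @export
metricReport <- function(embedding, meta, ilisiVars = character(),
                         nmiVar = NULL, aswLabelVar = NULL,
                         aswBatchVars = NULL, subset = NULL,
                         subsetDescription = "all cells", seed = 0L) {
  if (!is.null(subset)) {
    embedding <- embedding[subset, , drop = FALSE]
    meta <- meta[subset, , drop = FALSE]
  }
  rows <- list()
  for (v in ilisiVars)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "ilisi", target = v,
      value = ilisi(embedding, meta[[v]]), subset = subsetDescription)
  if (!is.null(nmiVar)) {
    cl <- clusterForNmi(embedding, meta[[nmiVar]], seed = seed)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "nmi", target = nmiVar, value = attr(cl, "nmi"),
      subset = subsetDescription)
  }
  if (!is.null(aswLabelVar))
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "asw_label", target = aswLabelVar,
      value = aswLabel(embedding, meta[[aswLabelVar]]),
      subset = subsetDescription)
  if (!is.null(aswBatchVars))
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "asw_batch", target = aswBatchVars$batch,
      value = as.numeric(aswBatch(embedding, meta[[aswBatchVars$batch]],
                                  meta[[aswBatchVars$groups]])),
      subset = subsetDescription)
  do.call(rbind, rows)
}
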