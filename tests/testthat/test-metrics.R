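# independent reference implementation of the perplexity-weighted local
# inverse Simpson index, written as plain per-cell loops for use as an
# oracle
refLisi <- function(emb, labels, k, perplexity) {
  labels <- as.factor(labels)
  n <- nrow(emb)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(emb) - emb[i, ])^2)
    nb <- order(d2)
    nb <- nb[nb != i][seq_len(k)]
    lo <- 0; hi <- Inf; beta <- 1
    for (it in 1:60) {
      w <- exp(-beta * d2[nb]); p <- w / sum(w)
      H <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(H - log(perplexity)) < 1e-7) break
      if (H > log(perplexity)) { lo <- beta; beta <- if (is.finite(hi)) (lo + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (lo + hi) / 2 }
    }
    pb <- tapply(p, labels[nb], sum, default = 0)
    vals[i] <- 1 / sum(pb^2)
  }
  mean(vals)
}

test_that("iLISI hits its bounds for perfect mixing and perfect separation", {
  set.seed(1)
  # two batches perfectly interleaved in one tight blob
  emb <- matrix(rnorm(400, sd = 0.01), 200, 2)
  lab <- rep(c("a", "b"), 100)
  expect_gt(ilisi(emb, lab, nNeighbors = 50, perplexity = 20), 0.85)
  # two distant clusters, one batch each
  emb2 <- rbind(matrix(rnorm(200, 0, 0.1), 100, 2),
                matrix(rnorm(200, 50, 0.1), 100, 2))
  lab2 <- rep(c("a", "b"), each = 100)
  expect_lt(ilisi(emb2, lab2, nNeighbors = 50, perplexity = 20), 0.02)
  expect_error(ilisi(emb, rep("a", 200)), "2 label")
})

test_that("iLISI matches an independent neighborhood-enumeration oracle", {
  set.seed(42)
  emb <- matrix(rnorm(24), 12, 2)
  lab <- rep(c("x", "y", "z"), 4)
  mine <- ilisi(emb, lab, nNeighbors = 4, perplexity = 3, rescale = FALSE)
  ref <- refLisi(emb, lab, k = 4, perplexity = 3)
  expect_equal(mine, ref, tolerance = 1e-4)
  # rescaling maps [1, B] onto [0, 1]
  expect_equal(ilisi(emb, lab, nNeighbors = 4, perplexity = 3),
               (mine - 1) / 2, tolerance = 1e-6)
})

test_that("NMI matches hand-computed contingency values", {
  expect_equal(nmiScore(c(1, 2, 1, 3), c(1, 2, 1, 3)), 1)
  expect_equal(nmiScore(c("a", "a", "b"), c("x", "x", "x")), 0)
  # frozen 6-point example: MI = 0.4620981, H = (1.0986123 + 0.6931472)/2
  expect_equal(nmiScore(c(1, 1, 2, 2, 3, 3), c(1, 1, 1, 2, 2, 2)),
               0.5158037, tolerance = 1e-6)
  expect_error(nmiScore(integer(0), integer(0)), "non-empty")
  expect_error(nmiScore(1:3, 1:4), "equal-length")
})

test_that("graph clustering recovers well-separated blobs", {
  set.seed(5)
  centers <- rbind(c(0, 0), c(8, 0), c(0, 8))
  truth <- rep(1:3, each = 40)
  emb <- centers[truth, ] + matrix(rnorm(240, sd = 0.4), 120, 2)
  cl <- clusterForNmi(emb, truth, seed = 2)
  expect_gte(attr(cl, "nmi"), 0.99)
  # determinism
  cl2 <- clusterForNmi(emb, truth, seed = 2)
  expect_identical(as.integer(cl), as.integer(cl2))
  # a single blob collapses to one community at low resolution
  one <- matrix(rnorm(100, sd = 0.1), 50, 2)
  cl3 <- clusterForNmi(one, rep(1, 50), resolutions = 0.01, seed = 1)
  expect_lte(nlevels(cl3), 2)
})

test_that("silhouette scores separate conservation from mixing", {
  set.seed(6)
  a <- matrix(rnorm(100, 0, 0.05), 50, 2)
  b <- matrix(rnorm(100, 20, 0.05), 50, 2)
  emb <- rbind(a, b)
  type <- rep(c("t1", "t2"), each = 50)
  batch <- rep(c("b1", "b2"), 50)
  # far-apart type clusters: asw_label near 1
  expect_gt(aswLabel(emb, type), 0.95)
  # batches interleaved within every type: asw_batch near 1
  ab <- aswBatch(emb, batch, type)
  expect_gt(as.numeric(ab), 0.9)
  # batch-confounded types: poor mixing score
  ab2 <- aswBatch(emb, type, rep("all", 100))
  expect_lt(as.numeric(ab2), 0.2)
  # a single-batch group is flagged and scored as perfectly mixed
  ab3 <- aswBatch(emb, rep(c("b1", "b2"), each = 50), type)
  expect_identical(attr(ab3, "single_batch_groups"), c("t1", "t2"))
  expect_equal(as.numeric(ab3), 1)
})

test_that("silhouette scores agree with an explicit distance-table computation", {
  # 8 points on a line: two clear groups
  emb <- matrix(c(0, 1, 2, 3, 10, 11, 12, 13), ncol = 1)
  lab <- rep(c("g1", "g2"), each = 4)
  sil <- cluster::silhouette(rep(1:2, each = 4), dist(emb))
  expect_equal(aswLabel(emb, lab), (mean(sil[, 3]) + 1) / 2)
  # hand value for the first point: a = mean(1,2,3), b = mean(10,11,12,13)
  expect_equal(unname(sil[1, 3]), (11.5 - 2) / 11.5)
})

test_that("metrics are invariant to row permutation and rotation", {
  set.seed(8)
  emb <- matrix(rnorm(60 * 3), 60, 3)
  lab <- sample(rep(c("a", "b", "c"), 20))
  base <- ilisi(emb, lab, nNeighbors = 20, perplexity = 10)
  perm <- sample(60)
  expect_equal(ilisi(emb[perm, ], lab[perm], nNeighbors = 20,
                     perplexity = 10), base, tolerance = 1e-10)
  qr_rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_equal(ilisi(emb %*% qr_rot, lab, nNeighbors = 20, perplexity = 10),
               base, tolerance = 1e-6)
  expect_equal(aswLabel(emb %*% qr_rot, lab), aswLabel(emb, lab),
               tolerance = 1e-8)
})

test_that("metricReport assembles tidy rows with subsetting", {
  set.seed(9)
  emb <- matrix(rnorm(200), 100, 2)
  meta <- data.frame(batch = rep(c("b1", "b2"), 50),
                     cell_type = rep(c("t1", "t2"), each = 50),
                     donor = rep(c("d1", "d2"), c(60, 40)))
  rep1 <- metricReport(emb, meta, ilisiVars = "batch", nmiVar = "cell_type",
                       aswLabelVar = "cell_type",
                       aswBatchVars = list(batch = "batch",
                                           groups = "cell_type"))
  expect_setequal(rep1$metric, c("ilisi", "nmi", "asw_label", "asw_batch"))
  expect_true(all(rep1$value >= 0 & rep1$value <= 1))
  rep2 <- metricReport(emb, meta, ilisiVars = "batch",
                       subset = meta$donor == "d1",
                       subsetDescription = "donor d1 only")
  expect_identical(rep2$subset, "donor d1 only")
})
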