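test_that("CLR transform centers log counts per cell", {
  expect_equal(as.numeric(clrTransform(matrix(1, 1, 4))), rep(0, 4))
  expect_equal(as.numeric(clrTransform(matrix(c(0, 3), 1, 2))),
               c(-log(2), log(2)))
  set.seed(7)
  x <- matrix(rpois(160, 6), 20, 8)
  out <- clrTransform(x)
  expect_lt(max(abs(rowMeans(out))), 1e-12)
  # matches the direct formula
  expect_equal(out, log(x + 1) - rowMeans(log(x + 1)))
  expect_error(clrTransform(matrix(-1, 1, 2)), "negative")
  expect_error(clrTransform(matrix(1, 1, 2), pseudocount = 0), "pseudocount")
})

test_that("binarization thresholds at zero and is idempotent", {
  x <- matrix(c(0, 1, 5, 0, 0, 2), 2, 3)
  b <- binarizeCounts(x)
  expect_equal(as.numeric(b), c(0, 1, 1, 0, 0, 1))
  expect_equal(binarizeCounts(b), b)
  expect_equal(binarizeCounts(matrix(0, 3, 4)), matrix(0, 3, 4))
})

test_that("feature-value subsampling thins nonzero entries per cell", {
  set.seed(3)
  x <- binarizeCounts(matrix(rbinom(300, 1, 0.4), 15, 20))
  expect_identical(subsampleFeatureValues(x, 1), x)
  # per-cell exact retention count
  out <- subsampleFeatureValues(x, 0.25, seed = 5)
  expect_equal(rowSums(out), round(0.25 * rowSums(x)))
  # a cell with 10 ones at 10% retains exactly one
  one <- matrix(c(rep(1, 10), rep(0, 10)), 1, 20)
  expect_equal(sum(subsampleFeatureValues(one, 0.1, seed = 1)), 1)
  # determinism and monotonicity
  expect_identical(out, subsampleFeatureValues(x, 0.25, seed = 5))
  expect_true(all(out <= x))
  expect_error(subsampleFeatureValues(x, 0), "fraction")
  expect_error(subsampleFeatureValues(x, 1.2), "fraction")
  expect_error(subsampleFeatureValues(matrix(2, 1, 1), 0.5), "binary")
})

test_that("mosaic masking zeroes dropped modalities and conserves cells", {
  sim <- smallPairedSim()
  ds <- sim$dataset
  expect_identical(makeMosaic(ds, list()), ds)
  mo <- makeMosaic(ds, list(b2 = "rna"))
  idx <- as.character(batchCodes(mo)) == "b2"
  expect_false(any(modalityMask(mo)[idx, "rna"]))
  expect_true(all(modality(mo, "rna")[idx, ] == 0))
  # unaffected cells untouched
  expect_identical(modality(mo, "rna")[!idx, ], modality(ds, "rna")[!idx, ])
  expect_identical(mo@cells, ds@cells)
  # dropping rna everywhere is fine while atac remains measured
  expect_true(all(modalityMask(makeMosaic(ds, list(b1 = "rna",
                                                   b2 = "rna")))[, "atac"]))
  # but removing the last modality of a cell is rejected
  expect_error(makeMosaic(makeMosaic(ds, list(b1 = "rna")),
                          list(b1 = "atac")), "all modalities")
})

test_that("dataset validity enforces the modality conventions", {
  rna <- matrix(1:6, 2, 3, dimnames = list(NULL, paste0("g", 1:3)))
  expect_error(MultimodalDataset(list(rna = rna - 2), batch = c("a", "b")),
               "non-negative integers")
  atac <- matrix(c(0, 2, 1, 0), 2, 2, dimnames = list(NULL, c("p1", "p2")))
  expect_error(validObject(
    MultimodalDataset(list(atac = binarizeCounts(atac) + 1),
                      batch = c("a", "b"))), "binary")
  # a cell measured in no modality is rejected at construction
  expect_error(
    MultimodalDataset(list(rna = rna), batch = c("a", "b"),
                      mask = matrix(c(TRUE, FALSE), 2, 1)),
    "zero modalities")
  # batch level ordering is frozen lexicographically
  ds <- MultimodalDataset(list(rna = rna), batch = c("zeta", "alpha"))
  expect_identical(levels(batchCodes(ds)), c("alpha", "zeta"))
})

test_that("container round trip preserves matrices, masks and batch codes", {
  sim <- smallPairedSim(n = 25)
  ds <- makeMosaic(sim$dataset, list(b2 = "atac"))
  path <- file.path(withr::local_tempdir(), "container")
  writeDataset(ds, path)
  back <- readDataset(path)
  expect_identical(back@modalities, ds@modalities)
  expect_identical(modalityMask(back), modalityMask(ds))
  expect_identical(batchCodes(back), batchCodes(ds))
  expect_identical(back@cells, ds@cells)
  expect_identical(cellData(back)$cell_type, cellData(ds)$cell_type)
  # missing batch column is a typed failure
  obs <- utils::read.table(file.path(path, "obs.tsv"), sep = "\t", header = TRUE)
  obs$batch <- NULL
  utils::write.table(obs, file.path(path, "obs.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  expect_error(readDataset(path), "batch")
  expect_error(readDataset(file.path(path, "missing")), "manifest")
})
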