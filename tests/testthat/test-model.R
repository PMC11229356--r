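# forward-pass contracts of the encoder/decoder architecture, checked on a
# small model via the internal forward machinery

makeForwardFixture <- function(variant = "bavae", alpha = 1, n = 12,
                               dropout = 0, seedData = 4, seedInit = 8,
                               modalitySet = c("rna", "atac")) {
  sim <- simulateMultimodal(syntheticSpec(nCells = 40, nRna = 10, nAtac = 14,
                                          nAdt = 5, nBatches = 2,
                                          modalities = unique(c(modalitySet,
                                                                "rna", "atac")),
                                          seed = seedData))
  ds <- sim$dataset[seq_len(n)]
  cfg <- variantConfig(variant, alpha = alpha, latentDim = 4,
                       encoderHidden = 9, decoderHidden = 7,
                       dropout = dropout, modalitySet = modalitySet, seed = 0)
  pd <- prepModelData(ds, cfg)
  priors <- computeSizeFactorPriors(ds, cfg)
  dims <- modelDims(cfg, lapply(ds@modalities[cfg@modalitySet], colnames),
                    nlevels(batchCodes(ds)))
  set.seed(seedInit)
  params <- initVaeParams(cfg, dims)
  params <- lapply(params, function(p) p + rnorm(length(p)) * 0.05)
  list(ds = ds, cfg = cfg, pd = pd, priors = priors, dims = dims,
       params = params)
}

test_that("encoded latent rows live on the probability simplex", {
  fx <- makeForwardFixture()
  noise <- drawNoise(12, fx$dims, fx$cfg, train = FALSE)
  fw <- vaeForward(fx$params, fx$pd, fx$cfg, fx$dims, fx$priors, noise)
  z <- fw$cache$z
  expect_true(all(z >= 0))
  expect_equal(unname(rowSums(z)), rep(1, 12), tolerance = 1e-5)
})

test_that("a mosaic cell encodes identically to the same cell with zeroed input", {
  fx <- makeForwardFixture()
  ds <- fx$ds
  # drop atac for batch b1 via the mask
  mo <- makeMosaic(ds, list(b1 = "atac"))
  # manually zero the same rows but keep the mask TRUE
  idx <- as.character(batchCodes(ds)) == "b1"
  zeroed <- ds
  zeroed@modalities$atac[idx, ] <- 0
  pd_mo <- prepModelData(mo, fx$cfg)
  pd_ze <- prepModelData(zeroed, fx$cfg)
  e_mo <- vaeEmbedForward(fx$params, pd_mo, fx$cfg, fx$dims, fx$priors)
  e_ze <- vaeEmbedForward(fx$params, pd_ze, fx$cfg, fx$dims, fx$priors)
  expect_equal(e_mo$mu_z, e_ze$mu_z)
})

test_that("deterministic evaluation is reproducible", {
  fx <- makeForwardFixture()
  e1 <- vaeEmbedForward(fx$params, fx$pd, fx$cfg, fx$dims, fx$priors)
  e2 <- vaeEmbedForward(fx$params, fx$pd, fx$cfg, fx$dims, fx$priors)
  expect_identical(e1, e2)
})

test_that("rna decoder means sum to the cell size factor", {
  fx <- makeForwardFixture()
  noise <- drawNoise(12, fx$dims, fx$cfg, train = FALSE)
  fw <- vaeForward(fx$params, fx$pd, fx$cfg, fx$dims, fx$priors, noise)
  dc <- fw$cache$dec$rna
  sfv <- fw$cache$sf$rna$sfv
  expect_equal(unname(rowSums(dc$mu)), unname(sfv), tolerance = 1e-6)
  # atac probability vector including the residual sums to one
  expect_equal(unname(rowSums(fw$cache$dec$atac$P)), rep(1, 12),
               tolerance = 1e-6)
})

test_that("without a conditional decoder the reconstruction ignores the batch", {
  fx <- makeForwardFixture(variant = "batchvae")
  noise <- drawNoise(12, fx$dims, fx$cfg, train = FALSE)
  pd2 <- fx$pd
  pd2$S <- pd2$S[, c(2, 1)]  # scramble the one-hot batch
  fw1 <- vaeForward(fx$params, fx$pd, fx$cfg, fx$dims, fx$priors, noise)
  fw2 <- vaeForward(fx$params, pd2, fx$cfg, fx$dims, fx$priors, noise)
  expect_equal(fw1$cache$dec$rna$wsm, fw2$cache$dec$rna$wsm)
})

test_that("loss breakdown is additive and zero for absent modalities", {
  fx <- makeForwardFixture(variant = "bavae", alpha = 2.5)
  noise <- drawNoise(12, fx$dims, fx$cfg, train = FALSE)
  tm <- vaeForward(fx$params, fx$pd, fx$cfg, fx$dims, fx$priors, noise,
                   keep_cache = FALSE)$terms
  expect_equal(tm$total,
               tm$loss_rna + tm$loss_atac + tm$loss_adt + tm$kl_z +
                 tm$kl_l + tm$kl_d + tm$alpha * tm$loss_adv,
               tolerance = 1e-6)
  expect_identical(tm$loss_adt, 0)
  # rna-only model: only {loss_rna, kl_z, kl_l} are active
  fr <- makeForwardFixture(variant = "vae", modalitySet = "rna")
  nz <- drawNoise(12, fr$dims, fr$cfg, train = FALSE)
  t1 <- vaeForward(fr$params, fr$pd, fr$cfg, fr$dims, fr$priors, nz,
                   keep_cache = FALSE)$terms
  expect_identical(c(t1$loss_atac, t1$loss_adt, t1$kl_d, t1$loss_adv),
                   rep(0, 4))
  expect_gt(t1$loss_rna, 0)
})

test_that("masked modalities contribute exactly zero loss", {
  fx <- makeForwardFixture()
  mo <- makeMosaic(fx$ds, list(b1 = "atac", b2 = "atac"))
  # all cells missing atac is impossible via makeMosaic unless rna remains;
  # here every cell keeps rna, so atac terms must vanish
  pd <- prepModelData(mo, fx$cfg)
  noise <- drawNoise(12, fx$dims, fx$cfg, train = FALSE)
  tm <- vaeForward(fx$params, pd, fx$cfg, fx$dims, fx$priors, noise,
                   keep_cache = FALSE)$terms
  expect_identical(tm$loss_atac, 0)
  expect_identical(tm$kl_d, 0)
  expect_gt(tm$loss_rna, 0)
})

test_that("a uniform classifier yields cross-entropy log(B)", {
  fx <- makeForwardFixture(variant = "bavae")
  params <- fx$params
  params$adv_W2[] <- 0
  params$adv_b2[] <- 0
  noise <- drawNoise(12, fx$dims, fx$cfg, train = FALSE)
  tm <- vaeForward(params, fx$pd, fx$cfg, fx$dims, fx$priors, noise,
                   keep_cache = FALSE)$terms
  expect_equal(tm$loss_adv, log(2), tolerance = 1e-12)
})

test_that("variant presets expand to the documented flag combinations", {
  v <- variantConfig("vae")
  expect_false(v@conditionalEncoder || v@conditionalDecoder || v@adversary ||
               v@batchSpecificSizeFactors || v@batchSpecificDispersion)
  b <- variantConfig("batchvae")
  expect_true(b@batchSpecificSizeFactors && b@batchSpecificDispersion)
  expect_false(b@conditionalEncoder || b@conditionalDecoder || b@adversary)
  expect_true(variantConfig("cevae")@conditionalEncoder)
  expect_false(variantConfig("cevae")@conditionalDecoder)
  expect_true(variantConfig("cdvae")@conditionalDecoder)
  cv <- variantConfig("cvae")
  expect_true(cv@conditionalEncoder && cv@conditionalDecoder)
  expect_false(cv@adversary)
  av <- variantConfig("avae", alpha = 50)
  expect_true(av@adversary && !av@conditionalDecoder && av@alpha == 50)
  bv <- variantConfig("bavae", alpha = 5)
  expect_true(bv@adversary && bv@conditionalDecoder && bv@alpha == 5)
  expect_error(modelConfig(alpha = -1), "non-negative")
  expect_error(modelConfig(latentDim = 1), "latentDim")
})

test_that("gradient reversal sends the encoder the negated classifier gradient", {
  fx <- makeForwardFixture(variant = "bavae", alpha = 1)
  noise <- drawNoise(12, fx$dims, fx$cfg, train = FALSE)
  fw <- vaeForward(fx$params, fx$pd, fx$cfg, fx$dims, fx$priors, noise)
  gr <- vaeBackward(fx$params, fx$pd, fx$cfg, fx$dims, fx$priors, noise, fw)
  # same model with the adversarial loss detached (alpha = 0): encoder
  # gradients must then differ by exactly the reversed classifier pull
  cfg0 <- fx$cfg; cfg0@alpha <- 0
  fw0 <- vaeForward(fx$params, fx$pd, cfg0, fx$dims, fx$priors, noise)
  gr0 <- vaeBackward(fx$params, fx$pd, cfg0, fx$dims, fx$priors, noise, fw0)
  # classifier parameters: gradient scales linearly with alpha
  expect_equal(gr0$adv_W2, gr$adv_W2 * 0)
  # encoder-side gradient difference is the adversarial component; stepping
  # the latent against it must increase the classifier loss (reversal sign)
  dW <- gr$z_mu_W - gr0$z_mu_W
  p2 <- fx$params
  p2$z_mu_W <- p2$z_mu_W - 1e-3 * dW   # a descent step on the total loss
  fw2 <- vaeForward(p2, fx$pd, fx$cfg, fx$dims, fx$priors, noise,
                    keep_cache = FALSE)
  expect_gt(fw2$terms$loss_adv, fw$terms$loss_adv)
})
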