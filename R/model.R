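# Core probabilistic model: modality-specific encoders with size-factor
# branches, a logistic-normal latent bottleneck, batch-conditioned decoders
# with negative-binomial (rna/adt) and negative-multinomial (atac)
# likelihoods, closed-form Gaussian KL regularisers, and a batch classifier
# trained through a gradient reversal layer.  The backward pass is analytic;
# it is validated against finite differences in the test suite.

PROB_FLOOR <- 1e-8   # probabilities clamped here before logs
LV_CLAMP <- 10       # posterior log-variances clamped to +/- this
LOGSF_CLAMP <- 20    # sampled log size factors clamped to +/- this

# which size-factor slot a modality uses: rna -> l, atac/adt -> d
sfSlot <- function(m) if (m == "rna") "l" else "d"

modelDims <- function(config, featureNames, nBatches) {
  mods <- config@modalitySet
  list(mods = mods,
       G = lapply(featureNames[mods], length),
       B = as.integer(nBatches),
       H = config@encoderHidden,
       Hd = config@decoderHidden,
       k = config@latentDim,
       Ha = config@adversaryHidden,
       Bt = if (config@batchSpecificDispersion) as.integer(nBatches) else 1L)
}

# flat named parameter list; consumes the current RNG stream.  The adversary
# is initialised last (and only if enabled) so that all shared parameters
# are bit-identical across variants that differ only in the adversary.
initVaeParams <- function(config, dims) {
  p <- list()
  ceB <- if (config@conditionalEncoder) dims$B else 0L
  cdB <- if (config@conditionalDecoder) dims$B else 0L
  for (m in dims$mods) {
    G <- dims$G[[m]]
    p[[paste0("enc_W_", m)]] <- initMatrix(G + ceB, dims$H)
    p[[paste0("enc_b_", m)]] <- numeric(dims$H)
    p[[paste0("enc_g_", m)]] <- rep(1, dims$H)
    p[[paste0("enc_beta_", m)]] <- numeric(dims$H)
    p[[paste0("sf_W_", m)]] <- initMatrix(dims$H, 2L)
    p[[paste0("sf_b_", m)]] <- numeric(2L)
  }
  Hcat <- dims$H * length(dims$mods)
  p$z_mu_W <- initMatrix(Hcat, dims$k); p$z_mu_b <- numeric(dims$k)
  p$z_lv_W <- initMatrix(Hcat, dims$k); p$z_lv_b <- numeric(dims$k)
  for (m in dims$mods) {
    G <- dims$G[[m]]
    p[[paste0("dec1_W_", m)]] <- initMatrix(dims$k + cdB, dims$Hd)
    p[[paste0("dec1_b_", m)]] <- numeric(dims$Hd)
    p[[paste0("dec1_g_", m)]] <- rep(1, dims$Hd)
    p[[paste0("dec1_beta_", m)]] <- numeric(dims$Hd)
    p[[paste0("dec2_W_", m)]] <- initMatrix(dims$Hd, dims$Hd)
    p[[paste0("dec2_b_", m)]] <- numeric(dims$Hd)
    p[[paste0("dec2_g_", m)]] <- rep(1, dims$Hd)
    p[[paste0("dec2_beta_", m)]] <- numeric(dims$Hd)
    if (m == "atac") {
      # extra input node for log(d_n); extra output logit for the residual
      p$out_W_atac <- initMatrix(dims$Hd + 1L, G + 1L)
      p$out_b_atac <- numeric(G + 1L)
      p$log_r_atac <- numeric(dims$Bt)
    } else {
      p[[paste0("out_W_", m)]] <- initMatrix(dims$Hd, G)
      p[[paste0("out_b_", m)]] <- numeric(G)
      p[[paste0("log_theta_", m)]] <- matrix(0, dims$Bt, G)
    }
  }
  if (config@adversary) {
    p$adv_W1 <- initMatrix(dims$k, dims$Ha); p$adv_b1 <- numeric(dims$Ha)
    p$adv_g <- rep(1, dims$Ha); p$adv_beta <- numeric(dims$Ha)
    p$adv_W2 <- initMatrix(dims$Ha, dims$B); p$adv_b2 <- numeric(dims$B)
  }
  p
}

# model-ready tensors for a dataset: encoder inputs (log1p rna, binary atac,
# CLR adt; unmeasured rows zeroed), likelihood targets (raw rna counts,
# binary atac, min-shifted CLR adt), one-hot batch, batch index, 0/1 mask
prepModelData <- function(dataset, config, batchLevels = levels(batchCodes(dataset))) {
  mods <- config@modalitySet
  for (m in mods)
    if (!m %in% modalityNames(dataset))
      stop("dataset lacks modality '", m, "' required by the model")
  bidx <- match(as.character(batchCodes(dataset)), batchLevels)
  if (anyNA(bidx))
    stop("unseen batch label(s): ",
         paste(setdiff(unique(as.character(batchCodes(dataset))), batchLevels),
               collapse = ", "))
  mask <- modalityMask(dataset)[, mods, drop = FALSE] * 1
  xin <- list(); xtgt <- list()
  for (m in mods) {
    x <- dataset@modalities[[m]]
    tgt <- switch(m, rna = x, atac = x, adt = shiftNonNegative(x))
    inp <- switch(m, rna = log1p(x), atac = x, adt = x)
    xin[[m]] <- inp * mask[, m]
    xtgt[[m]] <- tgt
  }
  list(xin = xin, xtgt = xtgt, S = oneHotBatch(batchCodes(dataset), batchLevels),
       bidx = bidx, mask = mask, n = nCells(dataset))
}

# batch-indexed log-normal priors for the size factors, computed once from
# the data (never learned)
computeSizeFactorPriors <- function(dataset, config,
                                    batchLevels = levels(batchCodes(dataset))) {
  pd <- prepModelData(dataset, config, batchLevels)
  B <- length(batchLevels)
  priors <- list()
  for (m in config@modalitySet) {
    lib <- log(pmax(rowSums(pd$xtgt[[m]]), 1))
    meas <- pd$mask[, m] > 0
    if (config@batchSpecificSizeFactors) {
      mu <- numeric(B); v <- numeric(B)
      for (b in seq_len(B)) {
        i <- meas & pd$bidx == b
        mu[b] <- if (any(i)) mean(lib[i]) else mean(lib[meas])
        v[b] <- if (sum(i) > 1) var(lib[i]) else 1
      }
      if (config@priorVariance == "literal") {
        mu <- vapply(seq_len(B), function(b) {
          i <- meas & pd$bidx == b
          if (any(i)) log(mean(exp(lib[i]))) else log(mean(exp(lib[meas])))
        }, numeric(1))
        v <- rep(if (B > 1) var(mu) else 1, B)
      }
    } else {
      mu <- rep(mean(lib[meas]), B)
      v <- rep(var(lib[meas]), B)
    }
    priors[[m]] <- list(mu = mu, var = pmax(v, 1e-3))
  }
  priors
}

# training-time stochasticity for one mini-batch (reparameterisation noise
# and encoder dropout masks); drawn from the current RNG stream
drawNoise <- function(n, dims, config, train = TRUE) {
  nz <- list(eps_z = matrix(rnorm(n * dims$k), n, dims$k), eps_sf = list(),
             drop = list())
  for (m in dims$mods) {
    nz$eps_sf[[m]] <- rnorm(n)
    nz$drop[[m]] <- if (train && config@dropout > 0)
      matrix(rbinom(n * dims$H, 1L, 1 - config@dropout) / (1 - config@dropout),
             n, dims$H)
    else NULL
  }
  nz
}

zeroNoise <- function(n, dims) {
  nz <- list(eps_z = matrix(0, n, dims$k), eps_sf = list(), drop = list())
  for (m in dims$mods) nz$eps_sf[[m]] <- numeric(n)
  nz
}

# ---------------------------------------------------------------------------
# Forward pass.  Returns the loss breakdown (per-mini-batch means; terms for
# absent modalities are exactly 0) and, when keep_cache, everything the
# backward pass needs.
vaeForward <- function(params, data, config, dims, priors, noise,
                       train = TRUE, keep_cache = TRUE) {
  n <- nrow(data$S)
  mods <- dims$mods
  cache <- list(enc = list(), sf = list(), dec = list())

  # --- encoder trunks -------------------------------------------------------
  h <- list()
  for (m in mods) {
    xin <- data$xin[[m]]
    if (config@conditionalEncoder) xin <- cbind(xin, data$S)
    pre <- linearFwd(xin, params[[paste0("enc_W_", m)]],
                     params[[paste0("enc_b_", m)]])
    ln <- layerNormFwd(pre, params[[paste0("enc_g_", m)]],
                       params[[paste0("enc_beta_", m)]])
    a <- reluFwd(ln$y)
    hd <- if (!is.null(noise$drop[[m]])) a * noise$drop[[m]] else a
    h[[m]] <- hd
    cache$enc[[m]] <- list(xin = xin, ln = ln, lny = ln$y, a = a)
  }
  Hcat <- do.call(cbind, h[mods])

  # --- latent bottleneck ----------------------------------------------------
  mu_z <- linearFwd(Hcat, params$z_mu_W, params$z_mu_b)
  lv_pre <- linearFwd(Hcat, params$z_lv_W, params$z_lv_b)
  lvc <- clampFwd(lv_pre, -LV_CLAMP, LV_CLAMP)
  lv_z <- lvc$y
  sd_z <- exp(0.5 * lv_z)
  u <- mu_z + sd_z * noise$eps_z
  z <- softmaxRows(u)

  kl_z <- mean(klDiagGaussian(mu_z, exp(lv_z)))

  # --- size-factor posteriors ----------------------------------------------
  sf <- list()
  kl_sf <- list()
  for (m in mods) {
    out <- linearFwd(h[[m]], params[[paste0("sf_W_", m)]],
                     params[[paste0("sf_b_", m)]])
    pm <- priors[[m]]$mu[data$bidx]
    pv <- priors[[m]]$var[data$bidx]
    m_sf <- out[, 1] + pm      # prior mean carried as a fixed offset
    lvsfc <- clampFwd(out[, 2], -LV_CLAMP, LV_CLAMP)
    lv_sf <- lvsfc$y
    logsf_raw <- m_sf + exp(0.5 * lv_sf) * noise$eps_sf[[m]]
    lsfc <- clampFwd(logsf_raw, -LOGSF_CLAMP, LOGSF_CLAMP)
    sfv <- exp(lsfc$y)
    w_m <- data$mask[, m]
    nm <- max(1, sum(w_m))
    klcell <- klDiagGaussian(m_sf, exp(lv_sf), pm, pv)
    kl_sf[[m]] <- sum(klcell * w_m) / nm
    sf[[m]] <- sfv
    cache$sf[[m]] <- list(m_sf = m_sf, lv_sf = lv_sf, lv_ind = lvsfc$ind,
                          logsf = lsfc$y, logsf_ind = lsfc$ind, sfv = sfv,
                          pm = pm, pv = pv, w = w_m, nm = nm)
  }

  # --- decoders -------------------------------------------------------------
  recon <- list()
  for (m in mods) {
    din <- if (config@conditionalDecoder) cbind(z, data$S) else z
    p1 <- linearFwd(din, params[[paste0("dec1_W_", m)]],
                    params[[paste0("dec1_b_", m)]])
    ln1 <- layerNormFwd(p1, params[[paste0("dec1_g_", m)]],
                        params[[paste0("dec1_beta_", m)]])
    a1 <- reluFwd(ln1$y)
    p2 <- linearFwd(a1, params[[paste0("dec2_W_", m)]],
                    params[[paste0("dec2_b_", m)]])
    ln2 <- layerNormFwd(p2, params[[paste0("dec2_g_", m)]],
                        params[[paste0("dec2_beta_", m)]])
    a2 <- reluFwd(ln2$y)
    x <- data$xtgt[[m]]
    w_m <- data$mask[, m]
    nm <- cache$sf[[m]]$nm
    if (m == "atac") {
      a2a <- cbind(a2, cache$sf[[m]]$logsf)
      eta <- linearFwd(a2a, params$out_W_atac, params$out_b_atac)
      P <- softmaxRows(eta)
      Pcl <- pmax(P, PROB_FLOOR)
      G <- dims$G[[m]]
      r <- exp(params$log_r_atac)[if (dims$Bt > 1) data$bidx else rep(1L, n)]
      sx <- rowSums(x)
      ll <- lgamma(r + sx) - lgamma(r) - rowSums(lgamma(x + 1)) +
        r * log(Pcl[, G + 1L]) + rowSums(x * log(Pcl[, seq_len(G), drop = FALSE]))
      recon[[m]] <- sum(-ll * w_m) / nm
      cache$dec[[m]] <- list(din = din, ln1 = ln1, a1 = a1, ln2 = ln2, a2 = a2,
                             a2a = a2a, P = P, Pcl = Pcl, r = r, sx = sx)
    } else {
      rho <- linearFwd(a2, params[[paste0("out_W_", m)]],
                       params[[paste0("out_b_", m)]])
      wsm <- softmaxRows(rho)
      wcl <- pmax(wsm, PROB_FLOOR)
      mu <- wcl * sf[[m]]
      lt <- params[[paste0("log_theta_", m)]]
      theta <- exp(if (dims$Bt > 1) lt[data$bidx, , drop = FALSE]
                   else lt[rep(1L, n), , drop = FALSE])
      ll <- lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
        theta * (log(theta) - log(theta + mu)) +
        x * (log(pmax(mu, PROB_FLOOR)) - log(theta + mu))
      recon[[m]] <- sum(-rowSums(ll) * w_m) / nm
      cache$dec[[m]] <- list(din = din, ln1 = ln1, a1 = a1, ln2 = ln2, a2 = a2,
                             wsm = wsm, wcl = wcl, mu = mu, theta = theta)
    }
  }

  # --- batch classifier through the gradient reversal layer -----------------
  loss_adv <- 0
  if (config@adversary) {
    ap <- linearFwd(z, params$adv_W1, params$adv_b1)
    aln <- layerNormFwd(ap, params$adv_g, params$adv_beta)
    aa <- reluFwd(aln$y)
    logits <- linearFwd(aa, params$adv_W2, params$adv_b2)
    lse <- logSumExpRows(logits)
    loss_adv <- mean(lse - logits[cbind(seq_len(n), data$bidx)])
    cache$adv <- list(ap = ap, aln = aln, aa = aa, logits = logits, lse = lse)
  }

  terms <- list(
    loss_rna = if ("rna" %in% mods) recon$rna else 0,
    loss_atac = if ("atac" %in% mods) recon$atac else 0,
    loss_adt = if ("adt" %in% mods) recon$adt else 0,
    kl_z = kl_z,
    kl_l = if ("rna" %in% mods) kl_sf$rna else 0,
    kl_d = if ("atac" %in% mods) kl_sf$atac
           else if ("adt" %in% mods) kl_sf$adt else 0,
    loss_adv = loss_adv,
    alpha = config@alpha)
  terms$total <- terms$loss_rna + terms$loss_atac + terms$loss_adt +
    terms$kl_z + terms$kl_l + terms$kl_d +
    (if (config@adversary) config@alpha * terms$loss_adv else 0)

  if (!keep_cache) return(list(terms = terms))
  cache$mu_z <- mu_z; cache$lv_z <- lv_z; cache$lv_ind <- lvc$ind
  cache$sd_z <- sd_z; cache$u <- u; cache$z <- z; cache$Hcat <- Hcat
  cache$h <- h; cache$n <- n
  list(terms = terms, cache = cache)
}

# ---------------------------------------------------------------------------
# Analytic backward pass for the total loss.  Returns gradients in the same
# flat-list layout as the parameters.  The classifier branch receives
# +alpha * dCE while the encoder receives -alpha * dCE through the gradient
# reversal (reversal constant -1).
vaeBackward <- function(params, data, config, dims, priors, noise, fw) {
  ca <- fw$cache
  n <- ca$n
  mods <- dims$mods
  gr <- list()
  k <- dims$k
  dz <- matrix(0, n, k)
  dlogsf <- lapply(mods, function(m) numeric(n)); names(dlogsf) <- mods

  # --- decoder/likelihood backward -----------------------------------------
  for (m in mods) {
    dc <- ca$dec[[m]]
    x <- data$xtgt[[m]]
    w_m <- data$mask[, m]
    cw <- w_m / ca$sf[[m]]$nm   # per-cell weight of the reconstruction mean
    if (m == "atac") {
      G <- dims$G[[m]]
      P <- dc$P; Pcl <- dc$Pcl
      tmat <- cbind(x, dc$r)
      g <- (tmat / Pcl) * (P > PROB_FLOOR)
      deta <- -cw * softmaxRowsBwd(g, P)
      lb <- linearBwd(deta, dc$a2a, params$out_W_atac)
      gr$out_W_atac <- lb$dW; gr$out_b_atac <- lb$db
      da2 <- lb$dx[, seq_len(dims$Hd), drop = FALSE]
      dlogsf[[m]] <- dlogsf[[m]] + lb$dx[, dims$Hd + 1L]
      # dispersion r: dll/dr = psi(r+sx) - psi(r) + log p0 (residual logit
      # also carries r as a pseudo-count; that part is in deta already)
      dr_cell <- -cw * (digamma(dc$r + dc$sx) - digamma(dc$r) +
                        log(Pcl[, G + 1L]))
      dlr <- dr_cell * dc$r
      gr$log_r_atac <- if (dims$Bt > 1)
        as.numeric(crossprod(data$S, dlr))
      else sum(dlr)
    } else {
      theta <- dc$theta; mu <- dc$mu
      dmu <- cw * ((theta + x) / (theta + mu) - x / pmax(mu, PROB_FLOOR))
      dwcl <- dmu * ca$sf[[m]]$sfv
      dlogsf[[m]] <- dlogsf[[m]] +
        rowSums(dc$wcl * dmu) * ca$sf[[m]]$sfv
      dw <- dwcl * (dc$wsm > PROB_FLOOR)
      drho <- softmaxRowsBwd(dw, dc$wsm)
      lb <- linearBwd(drho, dc$a2, params[[paste0("out_W_", m)]])
      gr[[paste0("out_W_", m)]] <- lb$dW
      gr[[paste0("out_b_", m)]] <- lb$db
      da2 <- lb$dx
      dth_cell <- -cw * (digamma(x + theta) - digamma(theta) +
                         log(theta) - log(theta + mu) + 1 -
                         (theta + x) / (theta + mu))
      dlt <- dth_cell * theta
      gr[[paste0("log_theta_", m)]] <- if (dims$Bt > 1)
        crossprod(data$S, dlt)
      else matrix(colSums(dlt), 1L)
    }
    # shared decoder trunk
    dp2 <- reluBwd(da2, dc$ln2$y)
    ln2b <- layerNormBwd(dp2, dc$ln2, params[[paste0("dec2_g_", m)]])
    gr[[paste0("dec2_g_", m)]] <- ln2b$dg
    gr[[paste0("dec2_beta_", m)]] <- ln2b$dbeta
    lb2 <- linearBwd(ln2b$dx, dc$a1, params[[paste0("dec2_W_", m)]])
    gr[[paste0("dec2_W_", m)]] <- lb2$dW
    gr[[paste0("dec2_b_", m)]] <- lb2$db
    dp1 <- reluBwd(lb2$dx, dc$ln1$y)
    ln1b <- layerNormBwd(dp1, dc$ln1, params[[paste0("dec1_g_", m)]])
    gr[[paste0("dec1_g_", m)]] <- ln1b$dg
    gr[[paste0("dec1_beta_", m)]] <- ln1b$dbeta
    lb1 <- linearBwd(ln1b$dx, dc$din, params[[paste0("dec1_W_", m)]])
    gr[[paste0("dec1_W_", m)]] <- lb1$dW
    gr[[paste0("dec1_b_", m)]] <- lb1$db
    dz <- dz + lb1$dx[, seq_len(k), drop = FALSE]
  }

  # --- adversary (gradient reversal towards the encoder) --------------------
  if (config@adversary) {
    av <- ca$adv
    sm <- exp(av$logits - av$lse)
    dlogits <- sm / n
    dlogits[cbind(seq_len(n), data$bidx)] <-
      dlogits[cbind(seq_len(n), data$bidx)] - 1 / n
    dlogits <- config@alpha * dlogits
    lb2 <- linearBwd(dlogits, av$aa, params$adv_W2)
    gr$adv_W2 <- lb2$dW; gr$adv_b2 <- lb2$db
    dpa <- reluBwd(lb2$dx, av$aln$y)
    lnb <- layerNormBwd(dpa, av$aln, params$adv_g)
    gr$adv_g <- lnb$dg; gr$adv_beta <- lnb$dbeta
    lb1 <- linearBwd(lnb$dx, ca$z, params$adv_W1)
    gr$adv_W1 <- lb1$dW; gr$adv_b1 <- lb1$db
    dz <- dz - lb1$dx        # reversal: encoder ascends the classifier loss
  }

  # --- latent bottleneck backward ------------------------------------------
  du <- softmaxRowsBwd(dz, ca$z)
  dmu_z <- du + ca$mu_z / n
  dlv <- du * noise$eps_z * 0.5 * ca$sd_z +
    0.5 * (exp(ca$lv_z) - 1) / n
  dlv_pre <- dlv * ca$lv_ind
  lbm <- linearBwd(dmu_z, ca$Hcat, params$z_mu_W)
  gr$z_mu_W <- lbm$dW; gr$z_mu_b <- lbm$db
  lbv <- linearBwd(dlv_pre, ca$Hcat, params$z_lv_W)
  gr$z_lv_W <- lbv$dW; gr$z_lv_b <- lbv$db
  dHcat <- lbm$dx + lbv$dx

  # --- size-factor branches and encoder trunks ------------------------------
  for (j in seq_along(mods)) {
    m <- mods[j]
    sfc <- ca$sf[[m]]
    cwk <- sfc$w / sfc$nm
    dlog <- dlogsf[[m]] * sfc$logsf_ind
    dm_sf <- dlog + cwk * (sfc$m_sf - sfc$pm) / sfc$pv
    dlv_sf <- dlog * noise$eps_sf[[m]] * 0.5 * exp(0.5 * sfc$lv_sf) +
      cwk * 0.5 * (exp(sfc$lv_sf) / sfc$pv - 1)
    dsf_out <- cbind(dm_sf, dlv_sf * sfc$lv_ind)
    lbs <- linearBwd(dsf_out, ca$h[[m]], params[[paste0("sf_W_", m)]])
    gr[[paste0("sf_W_", m)]] <- lbs$dW
    gr[[paste0("sf_b_", m)]] <- lbs$db
    dh <- dHcat[, (j - 1L) * dims$H + seq_len(dims$H), drop = FALSE] + lbs$dx
    if (!is.null(noise$drop[[m]])) dh <- dh * noise$drop[[m]]
    ec <- ca$enc[[m]]
    dpre <- reluBwd(dh, ec$lny)
    lnb <- layerNormBwd(dpre, ec$ln, params[[paste0("enc_g_", m)]])
    gr[[paste0("enc_g_", m)]] <- lnb$dg
    gr[[paste0("enc_beta_", m)]] <- lnb$dbeta
    lbe <- linearBwd(lnb$dx, ec$xin, params[[paste0("enc_W_", m)]])
    gr[[paste0("enc_W_", m)]] <- lbe$dW
    gr[[paste0("enc_b_", m)]] <- lbe$db
  }
  gr
}

# classifier-only forward/backward on a fixed latent sample (the latent is
# treated as data here; used for extra classifier updates that keep the
# discriminator near its best response during adversarial training)
advClassifierGrads <- function(params, z, bidx) {
  n <- nrow(z)
  ap <- linearFwd(z, params$adv_W1, params$adv_b1)
  aln <- layerNormFwd(ap, params$adv_g, params$adv_beta)
  aa <- reluFwd(aln$y)
  logits <- linearFwd(aa, params$adv_W2, params$adv_b2)
  lse <- logSumExpRows(logits)
  ce <- mean(lse - logits[cbind(seq_len(n), bidx)])
  dlogits <- exp(logits - lse) / n
  dlogits[cbind(seq_len(n), bidx)] <- dlogits[cbind(seq_len(n), bidx)] - 1 / n
  lb2 <- linearBwd(dlogits, aa, params$adv_W2)
  dpa <- reluBwd(lb2$dx, aln$y)
  lnb <- layerNormBwd(dpa, aln, params$adv_g)
  lb1 <- linearBwd(lnb$dx, z, params$adv_W1)
  list(ce = ce,
       grads = list(adv_W1 = lb1$dW, adv_b1 = lb1$db, adv_g = lnb$dg,
                    adv_beta = lnb$dbeta, adv_W2 = lb2$dW, adv_b2 = lb2$db))
}

# deterministic evaluation pathway: posterior means only
vaeEmbedForward <- function(params, data, config, dims, priors) {
  n <- nrow(data$S)
  h <- list()
  for (m in dims$mods) {
    xin <- data$xin[[m]]
    if (config@conditionalEncoder) xin <- cbind(xin, data$S)
    ln <- layerNormFwd(linearFwd(xin, params[[paste0("enc_W_", m)]],
                                 params[[paste0("enc_b_", m)]]),
                       params[[paste0("enc_g_", m)]],
                       params[[paste0("enc_beta_", m)]])
    h[[m]] <- reluFwd(ln$y)
  }
  Hcat <- do.call(cbind, h[dims$mods])
  mu_z <- linearFwd(Hcat, params$z_mu_W, params$z_mu_b)
  msf <- list()
  for (m in dims$mods) {
    out <- linearFwd(h[[m]], params[[paste0("sf_W_", m)]],
                     params[[paste0("sf_b_", m)]])
    msf[[m]] <- out[, 1] + priors[[m]]$mu[data$bidx]
  }
  list(z = softmaxRows(mu_z), mu_z = mu_z, log_sf_mean = msf)
}
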