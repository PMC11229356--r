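# Shared fixtures, built in code.  Heavy model fits used by several
# acceptance properties are cached for the session.

smallPairedSim <- function(n = 60, seed = 1) {
  simulateMultimodal(syntheticSpec(nCells = n, nRna = 12, nAtac = 15,
                                   nAdt = 6, nBatches = 2,
                                   modalities = c("rna", "atac"),
                                   seed = seed))
}

tinyConfig <- function(variant = "bavae", alpha = 1, seed = 0, ...) {
  variantConfig(variant, alpha = alpha, latentDim = 4, encoderHidden = 16,
                decoderHidden = 12, seed = seed, ...)
}

.fitCache <- new.env(parent = emptyenv())

cachedFit <- function(name, expr) {
  if (!exists(name, envir = .fitCache))
    assign(name, force(expr), envir = .fitCache)
  get(name, envir = .fitCache)
}

# study-condition fits shared across the batch-removal, NMI and size-factor
# acceptance properties: the default paired benchmark, 30 training epochs
pairedBenchmarkFit <- function(variant, alpha, seed) {
  key <- paste("paired", variant, alpha, seed, sep = "_")
  cachedFit(key, {
    sim <- cachedFit("paired_sim", syntheticPreset("paired", seed = 100))
    cfg <- variantConfig(variant, alpha = alpha, seed = seed)
    model <- fitModel(sim$dataset, cfg, maxEpochs = 30)
    list(model = model, sim = sim, z = embedCells(model, sim$dataset))
  })
}
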