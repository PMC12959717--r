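# Shared desk-scale fixtures.

tinyConfig <- function(...) {
  networkConfig(stemWidth = 8L, stageWidths = c(8L, 12L, 16L, 24L),
                highSemanticWidth = 32L, contextWidth = 8L,
                decoderWidths = c(24L, 16L, 12L, 12L), ...)
}

# the configuration used for the overfit/compression experiments: full
# architecture (all modules enabled) at desk-scale widths
overfitConfig <- function() {
  networkConfig(stemWidth = 8L, stageWidths = c(8L, 16L, 24L, 32L),
                highSemanticWidth = 48L, contextWidth = 12L,
                decoderWidths = c(32L, 24L, 16L, 16L))
}

overfitSynthConfig <- function(tileSize = 128L) {
  synthConfig(tileSize = tileSize, nVessels = c(3L, 6L), vesselWidth = c(3, 9),
              contrast = 0.35, noiseSd = 0.03)
}

makeSamples <- function(n, seedBase, tileSize = 128L,
                        scfg = overfitSynthConfig(tileSize)) {
  lapply(seq_len(n), function(i) {
    s <- generateSample(scfg, seed = seedBase + i)
    list(image = s$image, mask = s$mask)
  })
}

randImage <- function(h, w, c = 3L, n = 1L, seed = 1L) {
  set.seed(seed)
  array(runif(h * w * c * n), c(h, w, c, n))
}

# Trained desk-scale model shared by the acceptance properties; built once.
.fixtureCache <- new.env(parent = emptyenv())

trainedFixture <- function() {
  if (is.null(.fixtureCache$fit)) {
    samples <- makeSamples(8, seedBase = 100)
    net <- vesselNet(overfitConfig(), seed = 1)
    fit <- trainNet(net, samples, epochs = 40L, batchSize = 4L, lr = 4e-3,
                    seed = 1)
    .fixtureCache$fit <- list(model = fit$model, history = fit$history,
                              train = samples,
                              test = makeSamples(16, seedBase = 200))
  }
  .fixtureCache$fit
}
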