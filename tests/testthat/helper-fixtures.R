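# Shared fixtures, built in code at test time.

tinyStream <- function(n = 50, width = 16, height = 16, seed = 7,
                       tMax = 5e4) {
  withr::with_seed(seed, {
    EventStream(data.frame(
      t = sort(floor(runif(n, 0, tMax))),
      x = sample.int(width, n, replace = TRUE) - 1L,
      y = sample.int(height, n, replace = TRUE) - 1L,
      p = sample(c(-1L, 1L), n, replace = TRUE)),
      width = width, height = height, tStart = 0, tEnd = tMax)
  })
}

tinySegments <- function(nPerClass = 4, seed = 5) {
  scene <- sceneModel(width = 32, height = 32)
  kin <- kinematicsParams(fixDurationMs = c(50, 120),
                          sacDurationMs = c(20, 60),
                          sacAmplitudePx = c(5, 12))
  suppressWarnings(generateDataset(scene, kin,
                                   emulatorParams(noiseRate = 0.05),
                                   nPerClass = nPerClass, seed = seed))
}

# small dense/output-only network for gradient work
tinyDenseNet <- function(nIn = 6, nHidden = 5, seed = 3,
                         surrogate = surrogateSpec()) {
  layers <- list(
    layerSpec("flatten"),
    layerSpec("dense", cIn = nIn, cOut = nHidden,
              neuron = cubaLifParams(threshold = 0.6), weightNorm = TRUE),
    layerSpec("output", cIn = nHidden, cOut = 2L,
              neuron = cubaLifParams(threshold = 0.6)))
  net <- new("NetworkSpec", layers = layers, inputShape = c(1, nIn, 1),
             surrogate = surrogate, weights = list())
  initWeights(net, seed = seed)
}
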