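# Shape propagation, parameter counting, and spiking layer primitives.

test_that("shape propagation reproduces the full-geometry chain", {
  conv1 <- layerSpec("conv", 2, 8, kernel = c(3, 3), stride = c(2, 2))
  pool <- layerSpec("pool")
  conv2 <- layerSpec("conv", 8, 8, kernel = c(3, 3), stride = c(1, 1))
  s <- propagateShape(conv1, c(360, 260, 2))
  expect_equal(s, c(179, 129, 8))
  s <- propagateShape(pool, s)
  expect_equal(s, c(90, 65, 8))
  s <- propagateShape(conv2, s)
  expect_equal(s, c(88, 63, 8))
  s <- propagateShape(pool, s)
  expect_equal(s, c(44, 32, 8))
  s <- propagateShape(layerSpec("flatten"), s)
  expect_equal(s[3], 11264)
  expect_error(propagateShape(conv1, c(2, 2, 2)), "kernel")
})

test_that("parameter counts follow the no-bias conventions", {
  expect_equal(countParameters(layerSpec("conv", 2, 8, c(3, 3), c(2, 2))),
               144)
  expect_equal(countParameters(layerSpec("conv", 8, 8, c(3, 3), c(1, 1))),
               576)
  expect_equal(countParameters(layerSpec("dense", 103, 117)), 12051)
  expect_equal(countParameters(layerSpec("output", 117, 2)), 234)
  expect_equal(countParameters(layerSpec("pool")), 0L)
  expect_equal(countParameters(layerSpec("flatten")), 0L)
})

test_that("all-zero input produces all-zero output through any layer", {
  T <- 6
  for (l in list(layerSpec("conv", 2, 4, c(3, 3), c(1, 1),
                           neuron = cubaLifParams()),
                 layerSpec("pool"),
                 layerSpec("dense", 2 * 8 * 8, 5,
                           neuron = cubaLifParams()))) {
    out <- layerForward(l, matrix(0, 2 * 8 * 8, T), inShape = c(8, 8, 2))
    expect_true(all(out$output == 0))
  }
})

test_that("pooling is a per-bin logical OR over 2x2 windows", {
  # one spike somewhere in a window -> one output spike
  x <- matrix(0, 1 * 4 * 4, 3)          # (W=4, H=4, C=1)
  x[1 + 1 * (1 + 4 * 0), 2] <- 1        # c=1, h=1, w=0 (0-based)
  out <- layerForward(layerSpec("pool"), x, inShape = c(4, 4, 1))
  expect_equal(sum(out$output), 1)
  expect_equal(out$output[1, 2], 1)     # first window, same bin
  # all four set -> still one (OR, not sum)
  x2 <- matrix(0, 16, 1)
  x2[c(1, 2, 5, 6), 1] <- 1             # the whole 2x2 block (h,w in 0..1)
  out2 <- layerForward(layerSpec("pool"), x2, inShape = c(4, 4, 1))
  expect_equal(out2$output[1, 1], 1)
  expect_equal(sum(out2$output), 1)
  # ceil-mode keeps the odd border
  out3 <- layerForward(layerSpec("pool"), matrix(1, 5 * 5, 1),
                       inShape = c(5, 5, 1))
  expect_equal(out3$outShape, c(3, 3, 1))
})

test_that("a delayed dense input contributes exactly shifted drive", {
  T <- 12; nIn <- 4
  l <- layerSpec("dense", nIn, 3, neuron = cubaLifParams(threshold = 1e9),
                 delay = TRUE)
  net <- new("NetworkSpec", layers = list(l), inputShape = c(1, nIn, 1),
             surrogate = surrogateSpec(), weights = list())
  net <- initWeights(net, seed = 2)
  wt <- net@weights[[1]]
  x <- withr::with_seed(4, matrix(rbinom(nIn * T, 1, 0.4), nIn, T))
  base <- layerForward(l, x, inShape = c(1, nIn, 1), weights = wt,
                       train = TRUE)
  wt2 <- wt; wt2$delays[2] <- 3
  del <- layerForward(l, x, inShape = c(1, nIn, 1), weights = wt2,
                      train = TRUE)
  # with a huge threshold, membrane = accumulated drive; compare drives via
  # the cached synaptic current of a manual reconstruction instead: the
  # delayed unit's drive contribution at bin t equals the undelayed one at
  # bin t - 3
  W <- spikeye:::.effectiveWeight(wt)
  contribBase <- outer(W[, 2], x[2, ])
  x2 <- cbind(matrix(0, nIn, 3), x[, 1:(T - 3)])
  driveDelta <- del$cache$U - base$cache$U  # u accumulates drive only
  # reconstruct expected drive difference and push through the u recurrence
  dDrive <- outer(W[, 2], x2[2, ] - x[2, ])
  uDelta <- matrix(0, 3, T)
  au <- wt$alphaU
  acc <- numeric(3)
  for (t in seq_len(T)) {
    acc <- (1 - au) * acc + dDrive[, t]
    uDelta[, t] <- acc
  }
  expect_equal(driveDelta, uDelta, tolerance = 1e-12)
})

test_that("weight-normalized layers use w = g * v / ||v|| per output unit", {
  l <- layerSpec("dense", 6, 4, neuron = cubaLifParams(), weightNorm = TRUE)
  net <- new("NetworkSpec", layers = list(l), inputShape = c(1, 6, 1),
             surrogate = surrogateSpec(), weights = list())
  net <- initWeights(net, seed = 7)
  wt <- net@weights[[1]]
  W <- spikeye:::.effectiveWeight(wt)
  expect_equal(sqrt(rowSums(W^2)), unname(wt$g), tolerance = 1e-9)
  # scaling a direction row leaves the effective weights unchanged
  wt2 <- wt; wt2$V[2, ] <- 5 * wt2$V[2, ]
  expect_equal(spikeye:::.effectiveWeight(wt2)[2, ], W[2, ],
               tolerance = 1e-9)
})
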