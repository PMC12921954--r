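# Spike-rate loss, gradient correctness, training loop, metrics, sweep.

test_that("spikeRateLoss evaluates the squared rate error exactly", {
  # output rates exactly at target -> zero loss
  out <- rbind(rep(c(1, 0), c(2, 8)), rep(0, 10))  # rates (0.2, 0)
  expect_equal(spikeRateLoss(out, 0, rTrue = 0.2, rFalse = 0), 0)
  # silent output, label 0, rTrue 0.5 -> 0.5 * 0.25
  expect_equal(spikeRateLoss(matrix(0, 2, 4), 0, 0.5, 0), 0.125)
  expect_error(spikeRateLoss(matrix(0, 2, 4), 0, 0.5, 0.6), "rFalse")
  # brute-force oracle on random outputs
  withr::with_seed(6, {
    for (i in 1:10) {
      o <- matrix(rbinom(2 * 12, 1, 0.4), 2, 12)
      lab <- sample(0:1, 1)
      rhat <- c(0.03, 0.03); rhat[lab + 1] <- 0.2
      manual <- 0.5 * sum((rowSums(o) / 12 - rhat)^2)
      expect_equal(spikeRateLoss(o, lab), manual)
    }
  })
})

test_that("backprop through the relaxed surrogate matches numerical
           gradients", {
  net <- tinyDenseNet(nIn = 6, nHidden = 5, seed = 3)
  T <- 7
  x <- withr::with_seed(9, matrix(rbinom(6 * T, 1, 0.5), 6, T))
  lossOf <- function(net) {
    out <- forwardPass(net, x, relaxed = TRUE)$output
    rates <- rowMeans(out)
    0.5 * sum((rates - c(0.2, 0.03))^2)
  }
  fp <- forwardPass(net, x, train = TRUE, relaxed = TRUE)
  rates <- rowMeans(fp$output)
  dOut <- matrix((rates - c(0.2, 0.03)) / T, 2, T)
  g <- spikeye:::.backwardPass(net, fp$caches, dOut, relaxed = TRUE)
  h <- 1e-6
  # dense direction weight, gain, output weight, and neuron parameters
  checks <- list(list(2L, "V", 8L), list(2L, "g", 2L), list(3L, "W", 4L))
  for (ck in checks) {
    i <- ck[[1]]; nm <- ck[[2]]; k <- ck[[3]]  # k-th element, flat
    np <- net
    np@weights[[i]][[nm]][k] <- np@weights[[i]][[nm]][k] + h
    nm2 <- net
    nm2@weights[[i]][[nm]][k] <- nm2@weights[[i]][[nm]][k] - h
    num <- (lossOf(np) - lossOf(nm2)) / (2 * h)
    expect_equal(g[[i]][[nm]][k], num, tolerance = 1e-3)
  }
  for (nm in c("alphaU", "alphaV", "threshold", "bias")) {
    np <- net; np@weights[[3]][[nm]] <- np@weights[[3]][[nm]] + h
    nm2 <- net; nm2@weights[[3]][[nm]] <- nm2@weights[[3]][[nm]] - h
    num <- (lossOf(np) - lossOf(nm2)) / (2 * h)
    expect_equal(g[[3]][[nm]], num, tolerance = 1e-3)
  }
})

test_that("conv-layer gradients also match numerical differentiation", {
  neuron <- cubaLifParams(threshold = 0.6)
  layers <- list(
    layerSpec("conv", 1, 2, kernel = c(2, 2), stride = c(1, 1),
              neuron = neuron),
    layerSpec("pool"),
    layerSpec("flatten"),
    layerSpec("output", cIn = 2 * 2 * 2, cOut = 2, neuron = neuron))
  net <- initWeights(new("NetworkSpec", layers = layers,
                         inputShape = c(4, 4, 1),
                         surrogate = surrogateSpec(), weights = list()),
                     seed = 8)
  T <- 5
  x <- withr::with_seed(3, matrix(rbinom(16 * T, 1, 0.5), 16, T))
  lossOf <- function(net) {
    out <- forwardPass(net, x, relaxed = TRUE)$output
    0.5 * sum((rowMeans(out) - c(0.2, 0.03))^2)
  }
  fp <- forwardPass(net, x, train = TRUE, relaxed = TRUE)
  dOut <- matrix((rowMeans(fp$output) - c(0.2, 0.03)) / T, 2, T)
  g <- spikeye:::.backwardPass(net, fp$caches, dOut, relaxed = TRUE)
  h <- 1e-6
  for (idx in list(c(1, 2), c(4, 1))) {
    np <- net; np@weights[[1]]$W[idx[1], idx[2]] <-
      np@weights[[1]]$W[idx[1], idx[2]] + h
    nm <- net; nm@weights[[1]]$W[idx[1], idx[2]] <-
      nm@weights[[1]]$W[idx[1], idx[2]] - h
    num <- (lossOf(np) - lossOf(nm)) / (2 * h)
    expect_equal(g[[1]]$W[idx[1], idx[2]], num, tolerance = 1e-3)
  }
})

test_that("one epoch on two samples trains, deterministically per seed", {
  segs <- tinySegments(nPerClass = 2, seed = 13)
  net <- buildSpikingConvNet(32, 32)
  r1 <- trainNetwork(net, segs, trainConfig(epochs = 1, seed = 5),
                     windowMs = 20)
  expect_equal(nrow(r1$history), 1L)
  expect_true(is.finite(r1$history$loss))
  r2 <- trainNetwork(net, segs, trainConfig(epochs = 1, seed = 5),
                     windowMs = 20)
  expect_identical(r1$history$loss, r2$history$loss)
  expect_identical(r1$net@weights[[6]]$V, r2$net@weights[[6]]$V)
})

test_that("evaluateNetwork metrics agree with their confusion counts", {
  segs <- tinySegments(nPerClass = 3, seed = 17)
  net <- initWeights(buildSpikingConvNet(32, 32), seed = 1)
  m <- evaluateNetwork(net, segs, windowMs = 20)
  cf <- m$confusion
  expect_equal(sum(cf), length(segs))
  expect_equal(m$accuracy, unname((cf["tp"] + cf["tn"]) / sum(cf)))
  if (cf["tp"] + cf["fp"] > 0)
    expect_equal(m$precision, unname(cf["tp"] / (cf["tp"] + cf["fp"])))
  if (m$precision + m$recall > 0)
    expect_equal(m$f1, 2 * m$precision * m$recall /
                   (m$precision + m$recall))
  # untrained all-one-class predictors land at 0.5 on a balanced set
  if (m$degenerate) expect_equal(m$accuracy, 0.5)
})

test_that("effective FPS bookkeeping is 1000 / window to 2 decimals", {
  expect_equal(effectiveFps(200), 5.00)
  expect_equal(effectiveFps(33), 30.30)
  expect_equal(effectiveFps(20), 50.00)
  expect_equal(effectiveFps(100), 10.00)
  expect_equal(effectiveFps(80), 12.50)
})

test_that("temporalSweep re-encodes, trains and reports per-window rows", {
  segs <- tinySegments(nPerClass = 4, seed = 23)
  sp <- splitByUser(segs, 1:7, 8:10)
  res <- temporalSweep(sp$train, sp$test, c(10, 20),
                       trainConfig(epochs = 1, seed = 3))
  expect_equal(nrow(res), 2L)
  expect_equal(res$fps, c(100, 50))
  expect_true(all(res$ok))
  expect_true(all(is.finite(res$finalLoss)))
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
})
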