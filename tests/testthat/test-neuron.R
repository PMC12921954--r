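# CUBA-LIF and LIF reference dynamics, decay helpers, surrogate kernels.

test_that("cubaLifStep follows the two-stage update and reset exactly", {
  p <- cubaLifParams(alphaU = 1, alphaV = 1, threshold = 1, bias = 0)
  st <- neuronState(1)
  r0 <- cubaLifStep(st, 0, p)
  expect_equal(r0$state$u, 0)
  expect_equal(r0$state$v, 0)
  expect_equal(r0$spikes, 0)

  r1 <- cubaLifStep(st, 1.5, p)
  expect_equal(r1$spikes, 1)         # u = 1.5, pre-reset v = 1.5 >= 1
  expect_equal(r1$state$v, 0)        # spiking neuron ends at v = 0
  expect_equal(r1$state$u, 1.5)
  expect_error(cubaLifStep(st, NaN, p), "NaN")
})

test_that("synaptic current converges to x / alphaU under constant drive", {
  p <- cubaLifParams(alphaU = 0.5, alphaV = 0.5, threshold = Inf)
  # threshold Inf is not admissible; use a huge finite one
  p <- cubaLifParams(alphaU = 0.5, alphaV = 0.5, threshold = 1e12)
  st <- neuronState(1)
  for (t in 1:40) { r <- cubaLifStep(st, 1, p); st <- r$state }
  expect_lt(abs(st$u - 1 / 0.5), 1e-6)  # geometric-series limit x/alphaU
})

test_that("thresholding is exact and v * s = 0 after every step", {
  p <- cubaLifParams(alphaU = 0.3, alphaV = 0.1, threshold = 0.8)
  st <- neuronState(50)
  withr::with_seed(1, {
    for (t in 1:30) {
      x <- runif(50, 0, 0.6)
      uPrev <- st$u; vPrev <- st$v
      r <- cubaLifStep(st, x, p)
      vbar <- (1 - p@alphaV) * vPrev + ((1 - p@alphaU) * uPrev + x)
      expect_identical(r$spikes, as.numeric(vbar >= p@threshold))
      expect_true(all(r$state$v * r$spikes == 0))
      st <- r$state
    }
  })
})

test_that("with zero input both state norms decay monotonically to zero", {
  p <- cubaLifParams(alphaU = 0.25, alphaV = 0.03, threshold = 10)
  st <- list(u = runif(10, 1, 2), v = runif(10, 1, 2))
  nu <- sqrt(sum(st$u^2)); nv <- sqrt(sum(st$v^2))
  for (t in 1:200) {
    r <- cubaLifStep(st, numeric(10), p)
    st <- r$state
    expect_lte(sqrt(sum(st$u^2)), nu + 1e-12)
    nu <- sqrt(sum(st$u^2)); nv2 <- sqrt(sum(st$v^2))
  }
  expect_lt(nu, 1e-6)
})

test_that("lifStep reference cell: immediate spiking, reset ordering and
           recurrence linearity", {
  # beta = 0, no recurrence: spikes whenever input exceeds threshold
  p <- lifParams(beta = 0, resetMode = "none", threshold = 1)
  r <- lifStep(numeric(3), c(2, 0.5, 2), p)
  expect_equal(r$spikes, c(1, 0, 1))

  # proportional reset keeps the membrane below the no-reset run
  pR <- lifParams(beta = 0.9, resetMode = "proportional", resetR = 0.2,
                  threshold = 1e9)
  pN <- lifParams(beta = 0.9, resetMode = "none", threshold = 1e9)
  withr::with_seed(5, {
    UR <- 0; UN <- 0
    for (t in 1:100) {
      x <- runif(1, 0, 2)  # spike-like non-negative drive
      UR <- lifStep(UR, x, pR)$U
      UN <- lifStep(UN, x, pN)$U
      expect_lte(UR, UN + 1e-12)
    }
  })

  # a forced spike at t-1 raises U at t by exactly vRes
  pV <- lifParams(beta = 0.5, resetMode = "none", vRes = 0.7,
                  threshold = 1e9)
  a <- lifStep(1, 0.3, pV, sPrev = 1)$U
  b <- lifStep(1, 0.3, pV, sPrev = 0)$U
  expect_equal(a - b, 0.7)
})

test_that("decay factors and time constants are exact inverses", {
  expect_equal(unname(decayFromTimeConstants(1e12, 1e12, 1)),
               c(0, 0), tolerance = 1e-10)       # tau -> Inf: no leak
  a <- decayFromTimeConstants(1, 1, 1)
  expect_equal(unname(a), rep(1 - exp(-1), 2))   # tau = dt
  tau <- timeConstantsFromDecay(0.25, 0.03)
  back <- decayFromTimeConstants(tau["tauSyn"], tau["tauMem"])
  expect_equal(unname(back), c(0.25, 0.03), tolerance = 1e-12)
})

test_that("surrogate kernels integrate to one and peak at the threshold", {
  for (fam in c("exponential", "fast-sigmoid")) {
    sg <- surrogateSpec(family = fam, width = 0.4)
    xs <- seq(-60, 60, by = 1e-3)
    mass <- sum(spikeye:::.surrogateDeriv(xs, sg)) * 1e-3
    expect_equal(mass, 1, tolerance = 1e-2)
    expect_gt(spikeye:::.surrogateDeriv(0, sg),
              spikeye:::.surrogateDeriv(0.5, sg))
    # primitive is the kernel's antiderivative
    x0 <- 0.3; h <- 1e-5
    num <- (spikeye:::.surrogatePrimitive(x0 + h, sg) -
            spikeye:::.surrogatePrimitive(x0 - h, sg)) / (2 * h)
    expect_equal(num, spikeye:::.surrogateDeriv(x0, sg), tolerance = 1e-6)
  }
})
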