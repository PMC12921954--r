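# Gaze-trajectory simulation, scene rendering and the contrast-threshold
# event emulator.

test_that("fixations hold exactly still when drift is zero", {
  kin <- kinematicsParams(driftSigma = 0)
  traj <- suppressWarnings(simulateTrajectory(kin, 1500, 64, 64, seed = 1))
  fixIdx <- which(traj@label == "fixation")
  # within each fixation interval, position is constant
  gt <- traj@groundTruth
  for (i in which(gt$label == "fixation")) {
    sel <- traj@timesMicros >= gt$tStart[i] & traj@timesMicros < gt$tEnd[i]
    expect_equal(diff(range(traj@x[sel])), 0)
    expect_equal(diff(range(traj@y[sel])), 0)
  }
})

test_that("saccade displacement integrates to its amplitude", {
  # the raised-cosine profile v ~ sin^2(pi tau / d) must integrate to A
  kin <- kinematicsParams(driftSigma = 0, sacAmplitudePx = c(10, 14),
                          velocityCap = 1e6)
  traj <- suppressWarnings(
    simulateTrajectory(kin, 3000, 256, 256, margin = 40, seed = 2))
  gt <- traj@groundTruth
  sacs <- which(gt$label == "saccade")
  sacs <- sacs[gt$tEnd[sacs] < max(traj@timesMicros)]  # complete ones
  expect_gte(length(sacs), 1L)
  for (i in sacs) {
    i0 <- which(traj@timesMicros == gt$tStart[i])
    i1 <- which(traj@timesMicros == gt$tEnd[i])
    amp <- sqrt((traj@x[i1] - traj@x[i0 - 1])^2 +
                (traj@y[i1] - traj@y[i0 - 1])^2)
    expect_gte(amp, 10 - 1e-4)
    expect_lte(amp, 14 + 1e-4)
  }
})

test_that("segment durations stay inside the configured physiology", {
  kin <- kinematicsParams()
  traj <- suppressWarnings(simulateTrajectory(kin, 5000, 360, 260, seed = 3))
  gt <- traj@groundTruth
  durMs <- (gt$tEnd - gt$tStart) / 1e3
  complete <- gt$tEnd < max(traj@timesMicros)  # last may be truncated
  expect_true(all(durMs[complete & gt$label == "fixation"] >= 50 - 1e-9))
  expect_true(all(durMs[complete & gt$label == "fixation"] <= 600 + 1))
  expect_true(all(durMs[complete & gt$label == "saccade"] >= 20 - 1e-9))
  expect_true(all(durMs[complete & gt$label == "saccade"] <= 200 + 1))
})

test_that("renderFrame draws symmetric positive discs with correct levels", {
  scene <- sceneModel(width = 65, height = 65)
  img <- renderFrame(scene, c(32, 32))
  expect_true(all(img > 0))
  expect_equal(min(img), unname(scene@intensities["pupil"]))
  expect_equal(max(img), unname(scene@intensities["sclera"]))
  # 180-degree rotational symmetry about the centre
  expect_equal(img, img[65:1, 65:1], tolerance = 1e-12)
})

test_that("shifting the gaze shifts the rendered pupil centroid", {
  scene <- sceneModel(width = 64, height = 64)
  centroid <- function(img) {
    mask <- img < 0.2  # pupil pixels
    X <- matrix(0:63, 64, 64, byrow = TRUE)
    c(sum(X * mask) / sum(mask))
  }
  c1 <- centroid(renderFrame(scene, c(28, 32)))
  c2 <- centroid(renderFrame(scene, c(34, 32)))
  expect_equal(c2 - c1, 6, tolerance = 0.5)
})

test_that("a static scene emits no events and steps emit per crossed multiple", {
  f <- matrix(0.5, 8, 8)
  ev <- emitEvents(list(f, f, f), c(0, 1000, 2000),
                   emulatorParams(noiseRate = 0))
  expect_equal(nEvents(ev), 0L)

  theta <- 0.2
  f2 <- f
  # two crossings, brightening; nudged past the second multiple so float
  # rounding cannot land infinitesimally short of the >= boundary
  f2[3, 4] <- 0.5 * exp(2.0001 * theta)
  ev2 <- emitEvents(list(f, f2), c(0, 1000),
                    emulatorParams(threshold = theta, noiseRate = 0))
  d <- eventData(ev2)
  expect_equal(nrow(d), 2L)
  expect_true(all(d$p == 1))
  expect_true(all(d$x == 3 & d$y == 2))  # 0-based (x=col 4, y=row 3)
})

test_that("non-positive intensities are rejected", {
  f <- matrix(0.5, 4, 4); g <- f; g[1, 1] <- 0
  expect_error(emitEvents(list(f, g), c(0, 1000), emulatorParams()),
               "positive")
})

test_that("events from a moving disc concentrate on the disc boundary", {
  scene <- sceneModel(width = 64, height = 64)
  xs <- seq(24, 40, by = 0.5)
  frames <- lapply(xs, function(gx) renderFrame(scene, c(gx, 32)))
  ev <- emitEvents(frames, seq_along(xs) * 1000,
                   emulatorParams(noiseRate = 0))
  d <- eventData(ev)
  expect_gt(nrow(d), 100)
  # distance of each event from the iris boundary annulus of the nearest
  # rendered position
  gx <- xs[pmin(pmax(round(d$t / 1000), 1), length(xs))]
  r <- sqrt((d$x - gx)^2 + (d$y - 32)^2)
  nearEdge <- abs(r - scene@irisRadius) <= 2 | abs(r - scene@pupilRadius) <= 2
  expect_gte(mean(nearEdge), 0.95)
})

test_that("halving the threshold never reduces the event count", {
  scene <- sceneModel(width = 32, height = 32)
  frames <- lapply(seq(10, 16, by = 0.5),
                   function(gx) renderFrame(scene, c(gx, 16)))
  times <- seq_along(frames) * 1000
  n1 <- nEvents(emitEvents(frames, times,
                           emulatorParams(threshold = 0.2, noiseRate = 0)))
  n2 <- nEvents(emitEvents(frames, times,
                           emulatorParams(threshold = 0.1, noiseRate = 0)))
  expect_gte(n2, n1)
})

test_that("polarity matches monotone brightness change, and the reference
           advances by exactly the emitted multiples", {
  theta <- 0.15
  withr::with_seed(8, {
    n <- 6
    frames <- lapply(seq_len(n), function(i) matrix(0.2 * 1.35^i, 5, 5))
  })
  ev <- emitEvents(frames, seq_len(6) * 1000,
                   emulatorParams(threshold = theta, noiseRate = 0))
  expect_true(all(eventData(ev)$p == 1))  # monotone brightening
  # conservation: theta * (signed event count per pixel) equals the total
  # reference advancement = within theta of the total log-intensity change
  d <- eventData(ev)
  perPix <- tapply(d$p, paste(d$x, d$y), sum)
  totalChange <- log(frames[[6]][1, 1]) - log(frames[[1]][1, 1])
  expect_true(all(abs(perPix * theta - totalChange) < theta))
})

test_that("generateDataset yields balanced labelled segments with a
           saccade/fixation density gap, deterministically", {
  segs <- tinySegments(nPerClass = 5, seed = 5)
  expect_length(segs, 10L)
  labs <- vapply(segs, segmentLabel, "")
  expect_equal(sum(labs == "fixation"), 5L)
  expect_equal(sum(labs == "saccade"), 5L)
  ne <- vapply(segs, nEvents, 1L)
  expect_gt(mean(ne[labs == "saccade"]), mean(ne[labs == "fixation"]))
  # labels match the simulator ground truth intervals by construction
  gt <- attr(segs, "trajectory")@groundTruth
  expect_true(all(labs %in% gt$label))
  # determinism: same seed, byte-identical event tables
  segs2 <- tinySegments(nPerClass = 5, seed = 5)
  for (i in seq_along(segs))
    expect_identical(eventData(segmentStream(segs[[i]])),
                     eventData(segmentStream(segs2[[i]])))
})
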