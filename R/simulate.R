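# Synthetic near-eye scene + event-camera emulation.
#
# The emulator follows the standard DVS model: per pixel, an event is
# emitted whenever log intensity L = log I drifts from a per-pixel
# reference by at least the contrast threshold theta, with polarity +1 for
# increases and -1 for decreases; the reference then advances by the
# crossed multiple of theta (not reset-to-current), so multiple crossings
# within one frame step each produce an event.

#' Simulate a gaze trajectory of alternating fixations and saccades
#'
#' Fixations hold position subject to a Gaussian drift random walk
#' (\code{driftSigma} px per sample); saccades are straight-line
#' displacements with a raised-cosine velocity profile
#' \eqn{v(\tau) \propto \sin^2(\pi\tau/d)}, whose peak \eqn{2A/d} is clamped
#' to the configured velocity cap. Segments alternate
#' fixation/saccade/fixation/... until the requested duration is filled.
#'
#' @param kin a \linkS4class{KinematicsParams}.
#' @param durationMs total duration in milliseconds.
#' @param width,height sensor geometry bounding the trajectory.
#' @param margin minimum distance kept between the pupil centre and the
#'   frame border, in pixels.
#' @param rateHz sampling rate of the uniform time grid (default 1 kHz).
#' @param seed RNG seed.
#' @return A \linkS4class{GazeTrajectory}.
#' @export
simulateTrajectory <- function(kin, durationMs, width, height,
                               margin = 0.25 * min(width, height),
                               rateHz = 1000, seed = 1L) {
  stopifnot(is(kin, "KinematicsParams"))
  if (durationMs < kin@fixDurationMs[1] + kin@sacDurationMs[1])
    stop("duration shorter than one fixation + one saccade")
  dtSec <- 1 / rateHz
  nTotal <- max(2L, floor(durationMs * rateHz / 1000))
  lo <- c(margin, margin)
  hi <- c(width - 1 - margin, height - 1 - margin)
  if (any(hi <= lo)) stop("margin leaves no admissible positions")

  withr::with_seed(seed, {
    pos <- lo + stats::runif(2) * (hi - lo)
    xs <- numeric(0); ys <- numeric(0); lab <- character(0)
    gt <- list()
    kindIsFix <- TRUE
    clampWarned <- FALSE
    while (length(xs) < nTotal) {
      if (kindIsFix) {
        durMs <- stats::runif(1, kin@fixDurationMs[1], kin@fixDurationMs[2])
        n <- max(1L, round(durMs * rateHz / 1000))
        steps <- matrix(stats::rnorm(2L * n, sd = kin@driftSigma), nrow = 2L)
        if (kin@driftSigma == 0) steps[] <- 0
        px <- pmin(pmax(pos[1] + cumsum(steps[1L, ]), lo[1]), hi[1])
        py <- pmin(pmax(pos[2] + cumsum(steps[2L, ]), lo[2]), hi[2])
        xs <- c(xs, px); ys <- c(ys, py)
        lab <- c(lab, rep("fixation", n))
        pos <- c(px[n], py[n])
        gt[[length(gt) + 1L]] <- c(n, 0)  # n samples, fixation
      } else {
        durMs <- stats::runif(1, kin@sacDurationMs[1], kin@sacDurationMs[2])
        n <- max(2L, round(durMs * rateHz / 1000))
        d <- n * dtSec
        amp <- stats::runif(1, kin@sacAmplitudePx[1], kin@sacAmplitudePx[2])
        ang <- stats::runif(1, 0, 2 * pi)
        target <- pos + amp * c(cos(ang), sin(ang))
        clamped <- pmin(pmax(target, lo), hi)
        if (any(clamped != target)) {
          if (!clampWarned) {
            warning("saccade amplitude incompatible with geometry; clamped")
            clampWarned <- TRUE
          }
          target <- clamped
        }
        amp <- sqrt(sum((target - pos)^2))
        dir <- if (amp > 0) (target - pos) / amp else c(0, 0)
        tau <- seq_len(n) * dtSec
        vPeak <- 2 * amp / d
        v <- pmin(vPeak * sin(pi * (tau - dtSec / 2) / d)^2, kin@velocityCap)
        disp <- cumsum(v * dtSec)
        xs <- c(xs, pos[1] + dir[1] * disp)
        ys <- c(ys, pos[2] + dir[2] * disp)
        lab <- c(lab, rep("saccade", n))
        pos <- c(pos[1] + dir[1] * disp[n], pos[2] + dir[2] * disp[n])
        gt[[length(gt) + 1L]] <- c(n, 1)
      }
      kindIsFix <- !kindIsFix
    }
    keep <- seq_len(min(length(xs), nTotal))
    xs <- xs[keep]; ys <- ys[keep]; lab <- lab[keep]
    dtMicros <- 1e6 / rateHz
    times <- (seq_along(xs) - 1) * dtMicros
    ns <- vapply(gt, `[`, 0, 1L)
    starts <- cumsum(c(0, ns[-length(ns)]))
    gtdf <- data.frame(
      tStart = starts * dtMicros,
      tEnd = (starts + ns) * dtMicros,
      label = ifelse(vapply(gt, `[`, 0, 2L) == 0, "fixation", "saccade"),
      stringsAsFactors = FALSE)
    # drop/truncate intervals beyond the kept samples
    gtdf <- gtdf[gtdf$tStart < nTotal * dtMicros, , drop = FALSE]
    gtdf$tEnd <- pmin(gtdf$tEnd, nTotal * dtMicros)
    new("GazeTrajectory", timesMicros = times, x = xs, y = ys, label = lab,
        rateHz = rateHz, groundTruth = gtdf)
  })
}

#' Render one intensity frame of the near-eye scene
#'
#' Concentric pupil/iris discs on sclera at the gaze position, with a 1-px
#' linear anti-aliasing ramp on each edge. All intensities are strictly
#' positive. Returned as an H x W matrix (row = y, column = x, origin
#' top-left).
#'
#' @param scene a \linkS4class{SceneModel}.
#' @param gaze numeric (x, y) pupil-centre position in pixels.
#' @return H x W numeric intensity matrix.
#' @export
renderFrame <- function(scene, gaze) {
  stopifnot(is(scene, "SceneModel"), length(gaze) == 2L, all(is.finite(gaze)))
  W <- scene@width; H <- scene@height
  gx <- min(max(gaze[1], 0), W - 1)
  gy <- min(max(gaze[2], 0), H - 1)
  X <- matrix(0:(W - 1), nrow = H, ncol = W, byrow = TRUE)
  Y <- matrix(0:(H - 1), nrow = H, ncol = W)
  d <- sqrt((X - gx)^2 + (Y - gy)^2)
  lv <- scene@intensities
  img <- matrix(lv["sclera"], H, W)
  if (!is.na(scene@apertureRadius)) {
    dc <- sqrt((X - (W - 1) / 2)^2 + (Y - (H - 1) / 2)^2)
    aIn <- pmin(pmax(scene@apertureRadius - dc + 0.5, 0), 1)
    img <- aIn * img + (1 - aIn) * lv["background"]
  }
  aIris <- pmin(pmax(scene@irisRadius - d + 0.5, 0), 1)
  img <- aIris * lv["iris"] + (1 - aIris) * img
  aPup <- pmin(pmax(scene@pupilRadius - d + 0.5, 0), 1)
  img <- aPup * lv["pupil"] + (1 - aPup) * img
  img
}

# One emulator step: compare current log frame to the per-pixel reference,
# emit one event per crossed theta-multiple, advance the reference.
# Timestamps are linearly interpolated in log intensity between frames.
.emitStep <- function(Lcur, Lprev, ref, theta, tPrev, tCur) {
  d <- Lcur - ref
  nCross <- floor(abs(d) / theta)
  idx <- which(nCross > 0)
  if (!length(idx)) {
    return(list(t = numeric(0), x = integer(0), y = integer(0),
                p = integer(0), ref = ref))
  }
  H <- nrow(Lcur)
  n <- nCross[idx]
  sgn <- sign(d[idx])
  pix <- rep(idx, n)
  k <- sequence(n)
  sgnRep <- rep(sgn, n)
  level <- ref[pix] + k * theta * sgnRep
  denom <- Lcur[pix] - Lprev[pix]
  frac <- (level - Lprev[pix]) / denom
  frac[!is.finite(frac)] <- 1
  frac <- pmin(pmax(frac, 0), 1)
  tEv <- floor(tPrev + frac * (tCur - tPrev))
  tEv <- pmin(tEv, tCur - 1)
  ref[idx] <- ref[idx] + n * theta * sgn
  list(t = tEv,
       x = (pix - 1L) %/% H,
       y = (pix - 1L) %% H,
       p = as.integer(sgnRep),
       ref = ref)
}

.finishEvents <- function(parts, width, height, params, tStart, tEnd) {
  ev <- data.frame(
    t = unlist(lapply(parts, `[[`, "t")),
    x = unlist(lapply(parts, `[[`, "x")),
    y = unlist(lapply(parts, `[[`, "y")),
    p = unlist(lapply(parts, `[[`, "p")))
  if (params@noiseRate > 0) {
    durSec <- (tEnd - tStart) / 1e6
    nNoise <- withr::with_seed(params@seed,
      stats::rpois(1, params@noiseRate * width * height * durSec))
    if (nNoise > 0) {
      noise <- withr::with_seed(params@seed + 1L, data.frame(
        t = floor(stats::runif(nNoise, tStart, tEnd)),
        x = sample.int(width, nNoise, replace = TRUE) - 1L,
        y = sample.int(height, nNoise, replace = TRUE) - 1L,
        p = sample(c(-1L, 1L), nNoise, replace = TRUE)))
      ev <- rbind(ev, noise)
    }
  }
  EventStream(ev, width = width, height = height,
              tStart = tStart, tEnd = tEnd)
}

#' Emit events from a rendered frame sequence
#'
#' Applies the contrast-threshold event model per pixel: the first frame
#' initializes the reference log intensity; each later frame emits one
#' event per crossed theta-multiple and advances the reference by that
#' multiple. Optional homogeneous Poisson noise events (polarity
#' equiprobable) are added at the configured rate. Output is sorted by
#' timestamp.
#'
#' @param frames list of H x W intensity matrices (all values > 0).
#' @param timesMicros frame timestamps (microseconds, increasing).
#' @param params an \linkS4class{EmulatorParams}.
#' @return An \linkS4class{EventStream} spanning
#'   \code{[timesMicros[1], last + median frame step)}.
#' @export
emitEvents <- function(frames, timesMicros, params) {
  stopifnot(is(params, "EmulatorParams"), length(frames) >= 2L,
            length(frames) == length(timesMicros))
  if (any(vapply(frames, function(f) any(f <= 0), TRUE)))
    stop("intensities must be strictly positive (log undefined)")
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  Lprev <- log(frames[[1]])
  ref <- Lprev
  parts <- vector("list", length(frames) - 1L)
  for (i in 2:length(frames)) {
    Lcur <- log(frames[[i]])
    st <- .emitStep(Lcur, Lprev, ref, params@threshold,
                    timesMicros[i - 1L], timesMicros[i])
    ref <- st$ref
    parts[[i - 1L]] <- st[c("t", "x", "y", "p")]
    Lprev <- Lcur
  }
  dt <- stats::median(diff(timesMicros))
  .finishEvents(parts, W, H, params, timesMicros[1],
                timesMicros[length(timesMicros)] + dt)
}

# Render-and-emit along a trajectory without materializing all frames.
.emitFromTrajectory <- function(scene, traj, params) {
  rateTraj <- traj@rateHz
  if (params@renderRate < 2 * rateTraj)
    warning("render rate below 2x the trajectory rate; ",
            "event timing will be coarse")
  t0 <- traj@timesMicros[1]
  t1 <- traj@timesMicros[length(traj@timesMicros)]
  frameTimes <- seq(t0, t1, by = 1e6 / params@renderRate)
  fx <- stats::approx(traj@timesMicros, traj@x, xout = frameTimes)$y
  fy <- stats::approx(traj@timesMicros, traj@y, xout = frameTimes)$y
  Lprev <- log(renderFrame(scene, c(fx[1], fy[1])))
  ref <- Lprev
  parts <- vector("list", length(frameTimes) - 1L)
  for (i in 2:length(frameTimes)) {
    Lcur <- log(renderFrame(scene, c(fx[i], fy[i])))
    st <- .emitStep(Lcur, Lprev, ref, params@threshold,
                    frameTimes[i - 1L], frameTimes[i])
    ref <- st$ref
    parts[[i - 1L]] <- st[c("t", "x", "y", "p")]
    Lprev <- Lcur
  }
  tEnd <- t1 + 1e6 / traj@rateHz  # span matches the trajectory grid
  .finishEvents(parts, scene@width, scene@height, params, t0, tEnd)
}

#' Generate a balanced, labelled synthetic dataset
#'
#' Runs simulate -> render -> emit, cuts the stream at the ground-truth
#' fixation/saccade intervals, balances both classes to \code{nPerClass},
#' and tags synthetic participant ids round-robin over \code{nUsers}.
#'
#' @param scene a \linkS4class{SceneModel}.
#' @param kin a \linkS4class{KinematicsParams}.
#' @param emulator an \linkS4class{EmulatorParams}.
#' @param nPerClass segments retained per class.
#' @param seed RNG seed (drives the trajectory, the balancing draw, and —
#'   offset deterministically — the emulator noise).
#' @param nUsers number of synthetic participants (default 10).
#' @param rateHz trajectory sampling rate.
#' @return list of \code{2 * nPerClass} \linkS4class{LabeledSegment}
#'   objects, with the source \linkS4class{GazeTrajectory} attached as
#'   attribute \code{"trajectory"}.
#' @export
generateDataset <- function(scene, kin, emulator, nPerClass, seed = 1L,
                            nUsers = 10L, rateHz = 1000) {
  stopifnot(nPerClass >= 1L)
  meanPair <- mean(kin@fixDurationMs) + mean(kin@sacDurationMs)
  durationMs <- nPerClass * 1.15 * meanPair +
    max(kin@fixDurationMs) + max(kin@sacDurationMs)
  margin <- scene@pupilRadius + 2  # pupil stays in frame; iris may clip
  for (attempt in 1:3) {
    traj <- simulateTrajectory(kin, durationMs, scene@width, scene@height,
                               margin = margin, rateHz = rateHz, seed = seed)
    nFix <- sum(traj@groundTruth$label == "fixation")
    nSac <- sum(traj@groundTruth$label == "saccade")
    if (nFix >= nPerClass && nSac >= nPerClass) break
    durationMs <- durationMs * 1.3
  }
  if (nFix < nPerClass || nSac < nPerClass)
    stop("simulated trajectory yielded too few segments")
  em <- emulator
  em@seed <- as.integer(seed + 7919L)  # noise stream tied to the dataset seed
  stream <- .emitFromTrajectory(scene, traj, em)
  segs <- alignLabels(stream, traj@groundTruth, rezero = TRUE)
  segs <- balanceClasses(segs, nPerClass, seed = seed)
  for (i in seq_along(segs))
    segs[[i]]@userId <- as.integer((i - 1L) %% nUsers + 1L)
  attr(segs, "trajectory") <- traj
  segs
}
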