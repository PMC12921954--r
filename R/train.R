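# Surrogate-gradient training: spike-rate loss, backpropagation through
# time for every layer kind, Adam optimizer, evaluation metrics and the
# temporal-resolution sweep harness.

.classes <- c("fixation", "saccade")  # indices 0, 1; saccade is positive

#' Spike-rate loss
#'
#' Target rate vector \eqn{\hat r = r_{true} 1[l] + r_{false}(1 - 1[l])};
#' loss is the squared error between the empirical mean firing rates and
#' the targets: \eqn{L = \frac{1}{2} \| \bar s - \hat r \|_2^2}.
#'
#' @param output spike matrix (nClasses x T).
#' @param label 0-based true class index.
#' @param rTrue,rFalse target rates, \code{0 <= rFalse < rTrue <= 1}.
#' @return non-negative scalar loss.
#' @export
spikeRateLoss <- function(output, label, rTrue = 0.2, rFalse = 0.03) {
  if (!(rFalse >= 0 && rFalse < rTrue && rTrue <= 1))
    stop("need 0 <= rFalse < rTrue <= 1")
  stopifnot(label %in% 0:(nrow(output) - 1))
  rates <- rowMeans(output)
  rhat <- rep(rFalse, nrow(output))
  rhat[label + 1L] <- rTrue
  0.5 * sum((rates - rhat)^2)
}

# --- backward passes --------------------------------------------------------

# BPTT through one CUBA-LIF stage. dS: gradient w.r.t. output spikes.
# Returns gradient w.r.t. the synaptic drive plus scalar neuron-parameter
# gradients (parameters are shared per layer).
# detachReset: optionally drop the d(v_t)/d(s_t) = -vbar reset term from
# the gradient. Off by default: the exact reset gradient trains better
# here (it penalizes spikes that discard accumulated potential).
.backwardNeuron <- function(dS, cache, wt, surrogate, relaxed = FALSE,
                            nBatch = 1L, detachReset = FALSE) {
  U <- cache$U; Vbar <- cache$Vbar; S <- cache$S
  n <- nrow(dS); T <- ncol(dS) %/% nBatch
  SD <- .surrogateDeriv(Vbar - wt$threshold, surrogate)
  dDrive <- matrix(0, n, ncol(dS))
  DVB <- matrix(0, n, ncol(dS))
  dsSd <- 0
  dvNext <- matrix(0, n, nBatch); duNext <- matrix(0, n, nBatch)
  oneMinusAu <- 1 - wt$alphaU
  oneMinusAv <- 1 - wt$alphaV
  for (t in T:1) {
    cols <- ((t - 1L) * nBatch + 1L):(t * nBatch)
    dv <- dvNext                      # grad wrt post-reset v_t
    ds <- if (detachReset) dS[, cols, drop = FALSE]
          else dS[, cols, drop = FALSE] - dv * Vbar[, cols, drop = FALSE]
    dvb <- dv * (1 - S[, cols, drop = FALSE]) + ds * SD[, cols, drop = FALSE]
    du <- dvb + duNext * oneMinusAu
    dDrive[, cols] <- du
    DVB[, cols] <- dvb
    dsSd <- dsSd + sum(ds * SD[, cols, drop = FALSE])
    dvNext <- dvb * oneMinusAv
    duNext <- du
  }
  dAu <- dAv <- 0
  if (T > 1L) {
    head <- seq_len((T - 1L) * nBatch)
    tail <- head + nBatch
    vPost <- Vbar[, head, drop = FALSE] * (1 - S[, head, drop = FALSE])
    dAv <- -sum(DVB[, tail, drop = FALSE] * vPost)
    dAu <- -sum(dDrive[, tail, drop = FALSE] * U[, head, drop = FALSE])
  }
  list(dDrive = dDrive, alphaU = dAu, alphaV = dAv, threshold = -dsSd,
       bias = sum(DVB))
}

# Weight-norm backward: W = g * V / ||V||_row.
.backwardWeightNorm <- function(dWef, V, g) {
  norms <- .rowNorms(V)
  Vn <- V / norms
  proj <- rowSums(dWef * Vn)
  list(g = proj, V = (g / norms) * (dWef - proj * Vn))
}

.unapplyDelays <- function(M, delays, Dmax, nBatch = 1L) {
  d <- pmin(pmax(round(delays), 0), Dmax)
  if (all(d == 0)) return(M)
  Tc <- ncol(M)
  for (dv in unique(d[d > 0])) {
    idx <- which(d == dv)
    dc <- dv * nBatch
    if (dc >= Tc) {
      M[idx, ] <- 0
    } else {
      M[idx, ] <- cbind(M[idx, (dc + 1L):Tc, drop = FALSE],
                        matrix(0, length(idx), dc))
    }
  }
  M
}

# Full-network BPTT. caches from forwardPass(train = TRUE); dOut is the
# loss gradient w.r.t. the output spike matrix. Returns per-layer gradient
# containers mirroring net@weights (delays receive no gradient).
.backwardPass <- function(net, caches, dOut, relaxed = FALSE, nBatch = 1L) {
  comp <- .compileNetwork(net)
  nL <- length(net@layers)
  grads <- vector("list", nL)
  dX <- dOut
  for (i in nL:1) {
    l <- net@layers[[i]]
    wt <- net@weights[[i]]
    cache <- caches[[i]]
    info <- comp[[i]]
    g <- list()
    if (l@kind == "flatten") {
      # identity
    } else if (l@kind == "pool") {
      P <- cache$P
      pad <- rbind(0, cache$input)
      G <- lapply(1:4, function(k) pad[P[, k] + 1L, , drop = FALSE])
      M <- pmax(G[[1]], G[[2]], G[[3]], G[[4]])
      win <- matrix(0L, nrow(P), ncol(dX))
      for (k in 4:1) {
        valid <- P[, k] > 0L
        hit <- valid & (G[[k]] == M)
        win[hit] <- k
      }
      dIn <- matrix(0, info$nIn, ncol(dX))
      for (k in 1:4) {
        valid <- which(P[, k] > 0L)
        if (!length(valid)) next
        contrib <- dX[valid, , drop = FALSE] *
          (win[valid, , drop = FALSE] == k)
        dIn[P[valid, k], ] <- dIn[P[valid, k], , drop = FALSE] + contrib
      }
      dX <- dIn
    } else if (l@kind == "conv") {
      nb <- .backwardNeuron(dX, cache, wt, net@surrogate, relaxed, nBatch)
      nPos <- nrow(cache$P); T <- ncol(dX); Cout <- l@cOut
      # drive (Cout*nPos x T) -> matmul layout (nPos*T x Cout)
      dR <- .convDriveInv(nb$dDrive, nPos, T, Cout)
      g$W <- crossprod(cache$X, dR)
      dXcol <- dR %*% t(wt$W)                       # nPos*T x K
      dIn <- matrix(0, info$nIn, T)
      iF <- .im2colIndex(cache$P, info$nIn, T)
      blk <- nPos * T
      for (k in seq_len(ncol(cache$P))) {
        ix <- iF[((k - 1L) * blk + 1L):(k * blk)]
        dIn[ix] <- dIn[ix] + dXcol[, k]
      }
      if (!is.null(l@neuron) && l@neuron@learnable)
        g[c("alphaU", "alphaV", "threshold", "bias")] <-
          nb[c("alphaU", "alphaV", "threshold", "bias")]
      dX <- dIn
    } else {  # dense / output
      nb <- .backwardNeuron(dX, cache, wt, net@surrogate, relaxed, nBatch)
      dWef <- tcrossprod(nb$dDrive, cache$xEff)
      dIn <- crossprod(cache$Wef, nb$dDrive)
      if (!is.null(wt$g)) {
        wn <- .backwardWeightNorm(dWef, wt$V, wt$g)
        g$V <- wn$V; g$g <- wn$g
      } else {
        g$W <- dWef
      }
      if (!is.null(wt$delays)) {
        nBins <- ncol(dIn) %/% nBatch
        dIn <- .unapplyDelays(dIn, wt$delays, Dmax = min(nBins - 1L, 62L),
                              nBatch = nBatch)
      }
      if (!is.null(cache$keepExp))
        dIn <- dIn * (cache$keepExp / (1 - l@dropout))
      if (!is.null(l@neuron) && l@neuron@learnable)
        g[c("alphaU", "alphaV", "threshold", "bias")] <-
          nb[c("alphaU", "alphaV", "threshold", "bias")]
      dX <- dIn
    }
    grads[[i]] <- g
  }
  grads
}

# --- Adam -------------------------------------------------------------------

.adamInit <- function(weights) {
  lapply(weights, function(wt)
    lapply(wt, function(w) list(m = w * 0, v = w * 0)))
}

.adamStep <- function(weights, grads, state, lr, step,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(weights)) {
    gi <- grads[[i]]
    if (is.null(gi)) next
    for (nm in names(gi)) {
      g <- gi[[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mh <- st$m / (1 - beta1^step)
      vh <- st$v / (1 - beta2^step)
      weights[[i]][[nm]] <- weights[[i]][[nm]] - lr * mh / (sqrt(vh) + eps)
      state[[i]][[nm]] <- st
    }
    # keep neuron parameters in their admissible ranges
    if (!is.null(weights[[i]]$alphaU))
      weights[[i]]$alphaU <- min(max(weights[[i]]$alphaU, 1e-3), 1)
    if (!is.null(weights[[i]]$alphaV))
      weights[[i]]$alphaV <- min(max(weights[[i]]$alphaV, 1e-3), 1)
    if (!is.null(weights[[i]]$threshold))
      weights[[i]]$threshold <- max(weights[[i]]$threshold, 0.01)
  }
  list(weights = weights, state = state)
}

# --- data preparation -------------------------------------------------------

# Compact encoding: per segment, the unique flat (C,H,W) x bin indices of
# the binary tensor, materialized into a dense (nIn x T) matrix on demand.
# The classification sample is the CENTRAL accumulation window of the
# segment (origin = tStart + max(0, (span - T dt) / 2)): saccades follow a
# raised-cosine velocity profile, so the central window captures peak
# motion while a leading window of a long saccade would be nearly still.
.encodeSegmentsSparse <- function(segments, dtMicros, T) {
  lapply(segments, function(seg) {
    st <- segmentStream(seg)
    H <- st@height; W <- st@width
    ev <- st@events
    idx <- integer(0)
    if (nrow(ev)) {
      origin <- st@tStart +
        max(0, (st@tEnd - st@tStart - T * dtMicros) / 2)
      rel <- ev$t - origin
      b <- floor(rel / dtMicros)
      keep <- b >= 0 & b < T
      if (any(keep)) {
        ch <- ifelse(ev$p[keep] > 0, 2L, 1L)
        idx <- unique(ch + 2L * (ev$y[keep] + H *
                 (ev$x[keep] + W * b[keep])))
      }
    }
    list(idx = as.integer(idx), label = match(segmentLabel(seg), .classes) - 1L,
         nIn = as.integer(2 * H * W))
  })
}

.materialize <- function(enc, T) {
  m <- matrix(0, enc$nIn, T)
  m[enc$idx] <- 1
  m
}

# --- trainer ----------------------------------------------------------------

#' Train the spiking classifier with surrogate-gradient BPTT
#'
#' Minimizes the spike-rate loss with Adam over minibatches. The forward
#' pass uses exact Heaviside spikes; gradients flow through the surrogate
#' kernel. Weight matrices, weight-norm gains and (when the layer's neuron
#' parameters are flagged learnable) the shared per-layer decay, threshold
#' and bias are updated; synaptic delay vectors are applied but not
#' optimized. Runs are deterministic for a fixed config seed.
#'
#' @param net a \linkS4class{NetworkSpec}; weights are initialized from the
#'   config seed if absent.
#' @param segments list of training \linkS4class{LabeledSegment}.
#' @param config a \linkS4class{TrainConfig}.
#' @param windowMs accumulation window (ms) used to encode each segment.
#' @param dtMicros bin width in microseconds.
#' @return list with \code{net} (trained) and \code{history} (data.frame
#'   of per-epoch mean train loss and optional validation accuracy).
#' @export
trainNetwork <- function(net, segments, config = trainConfig(),
                         windowMs = 33, dtMicros = 1000) {
  stopifnot(is(net, "NetworkSpec"), is(config, "TrainConfig"),
            length(segments) >= 1L)
  T <- windowToBins(windowMs, dtMicros)
  if (!length(net@weights)) net <- initWeights(net, seed = config@seed)
  enc <- .encodeSegmentsSparse(segments, dtMicros, T)
  valEnc <- list()
  withr::with_seed(config@seed, {
    if (config@valFraction > 0 && length(enc) >= 10L) {
      nVal <- max(1L, floor(config@valFraction * length(enc)))
      vi <- sample(seq_along(enc), nVal)
      valEnc <- enc[vi]
      enc <- enc[-vi]
    }
    state <- .adamInit(net@weights)
    step <- 0L
    nIn <- prod(net@inputShape)
    history <- data.frame(epoch = integer(), loss = numeric(),
                          valAccuracy = numeric())
    for (epoch in seq_len(config@epochs)) {
      ord <- sample(seq_along(enc))
      losses <- numeric(0)
      b0 <- 1L
      while (b0 <= length(ord)) {
        bIdx <- ord[b0:min(b0 + config@batchSize - 1L, length(ord))]
        b0 <- b0 + config@batchSize
        B <- length(bIdx)
        # interleave the batch along the column axis: col = b + B*(t-1)
        x <- matrix(0, nIn, B * T)
        for (b in seq_len(B)) {
          idx0 <- enc[[bIdx[b]]]$idx
          r <- (idx0 - 1L) %% nIn + 1L
          tt <- (idx0 - 1L) %/% nIn
          x[r + nIn * (b - 1L) + nIn * B * tt] <- 1
        }
        labs <- vapply(enc[bIdx], `[[`, 0L, "label")
        fp <- forwardPass(net, x, train = TRUE, nBatch = B)
        out <- fp$output
        rates <- rowMeans(array(out, c(nrow(out), B, T)), dims = 2)
        rhat <- matrix(config@rFalse, nrow(out), B)
        rhat[cbind(labs + 1L, seq_len(B))] <- config@rTrue
        perLoss <- 0.5 * colSums((rates - rhat)^2)
        if (!all(is.finite(perLoss)))
          stop(sprintf("training diverged (non-finite loss, epoch %d)",
                       epoch))
        dOut <- (rates - rhat)[, rep_len(seq_len(B), B * T),
                               drop = FALSE] / (T * B)
        g <- .backwardPass(net, fp$caches, dOut, nBatch = B)
        step <- step + 1L
        upd <- .adamStep(net@weights, g, state, config@learningRate, step)
        net@weights <- upd$weights
        state <- upd$state
        losses <- c(losses, mean(perLoss))
      }
      valAcc <- NA_real_
      if (length(valEnc)) {
        preds <- vapply(valEnc, function(e)
          decodeRate(forwardPass(net, .materialize(e, T))$output), 0L)
        valAcc <- mean(preds == vapply(valEnc, `[[`, 0L, "label"))
      }
      history <- rbind(history, data.frame(
        epoch = epoch, loss = mean(losses), valAccuracy = valAcc))
    }
  })
  list(net = net, history = history)
}

#' Evaluate the classifier on labelled segments
#'
#' Saccade is the positive class. Zero-division precision/recall are
#' reported as 0 and flagged via the \code{degenerate} field.
#'
#' @param net a trained \linkS4class{NetworkSpec}.
#' @param segments list of \linkS4class{LabeledSegment}.
#' @param windowMs,dtMicros encoding parameters (must match training).
#' @return list with \code{accuracy}, \code{precision}, \code{recall},
#'   \code{f1}, \code{confusion} (tp, fp, fn, tn), \code{degenerate}.
#' @export
evaluateNetwork <- function(net, segments, windowMs = 33, dtMicros = 1000) {
  stopifnot(length(segments) >= 1L)
  T <- windowToBins(windowMs, dtMicros)
  enc <- .encodeSegmentsSparse(segments, dtMicros, T)
  preds <- vapply(enc, function(e)
    decodeRate(forwardPass(net, .materialize(e, T))$output), 0L)
  labs <- vapply(enc, `[[`, 0L, "label")
  tp <- sum(preds == 1L & labs == 1L)
  fp <- sum(preds == 1L & labs == 0L)
  fn <- sum(preds == 0L & labs == 1L)
  tn <- sum(preds == 0L & labs == 0L)
  degenerate <- (tp + fp) == 0L || (tp + fn) == 0L
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(accuracy = (tp + tn) / length(labs), precision = precision,
       recall = recall, f1 = f1,
       confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
       degenerate = degenerate)
}

#' Effective frame rate of an accumulation window
#'
#' \code{round(1000 / windowMs, 2)}: one classification per window.
#'
#' @param windowMs accumulation window in milliseconds.
#' @return FPS rounded to 2 decimals.
#' @export
effectiveFps <- function(windowMs) round(1000 / windowMs, 2)

#' Temporal-resolution sweep
#'
#' For each accumulation window, re-encodes the segments (T = window /
#' bin width), trains a fresh network from the same config seed, and
#' evaluates on the test set. Failed rows are flagged and the sweep
#' continues.
#'
#' @param trainSegments,testSegments segment lists.
#' @param windowsMs accumulation windows in milliseconds.
#' @param config a \linkS4class{TrainConfig}.
#' @param width,height sensor geometry of the segments.
#' @param dtMicros bin width in microseconds.
#' @return data.frame with columns \code{windowMs}, \code{fps},
#'   \code{accuracy}, \code{precision}, \code{recall}, \code{f1},
#'   \code{finalLoss}, \code{ok}.
#' @export
temporalSweep <- function(trainSegments, testSegments, windowsMs,
                          config = trainConfig(), width = NULL,
                          height = NULL, dtMicros = 1000) {
  stopifnot(all(windowsMs > 0))
  if (is.null(width) || is.null(height)) {
    sz <- sensorSize(segmentStream(trainSegments[[1]]))
    width <- sz["width"]; height <- sz["height"]
  }
  rows <- lapply(windowsMs, function(w) {
    res <- tryCatch({
      net <- buildSpikingConvNet(width = width, height = height)
      tr <- trainNetwork(net, trainSegments, config, windowMs = w,
                         dtMicros = dtMicros)
      ev <- evaluateNetwork(tr$net, testSegments, windowMs = w,
                            dtMicros = dtMicros)
      data.frame(windowMs = w, fps = effectiveFps(w),
                 accuracy = ev$accuracy, precision = ev$precision,
                 recall = ev$recall, f1 = ev$f1,
                 finalLoss = utils::tail(tr$history$loss, 1), ok = TRUE)
    }, error = function(e) {
      warning(sprintf("sweep row %g ms failed: %s", w, conditionMessage(e)))
      data.frame(windowMs = w, fps = effectiveFps(w), accuracy = NA,
                 precision = NA, recall = NA, f1 = NA, finalLoss = NA,
                 ok = FALSE)
    })
    res
  })
  do.call(rbind, rows)
}
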