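# Spiking layer primitives: shape propagation, parameter counting, index
# precomputation (im2col / pooling windows) and per-layer forward passes.
#
# Flat unit order everywhere is the column-major order of an array with dim
# (C, H, W): channel fastest, then row, then column. A SpikeTensor slice at
# one bin flattens to exactly this order.

#' Propagate a layer's output shape
#'
#' Shapes are (W, H, C). Convolution (no padding):
#' \code{out = floor((in - k) / s) + 1} per spatial axis. Pooling is fixed
#' 2x2 stride-2 with ceil mode: \code{out = ceiling(in / 2)}. Flatten and
#' dense stages collapse to \code{(1, 1, n)}.
#'
#' @param layer a \linkS4class{LayerSpec}.
#' @param inShape numeric (W, H, C).
#' @return numeric (W, H, C) output shape.
#' @export
propagateShape <- function(layer, inShape) {
  stopifnot(is(layer, "LayerSpec"), length(inShape) == 3L)
  W <- inShape[1]; H <- inShape[2]; C <- inShape[3]
  switch(layer@kind,
    conv = {
      if (layer@kernel[1] > W || layer@kernel[2] > H)
        stop("kernel larger than input")
      if (C != layer@cIn) stop("channel mismatch")
      c(floor((W - layer@kernel[1]) / layer@stride[1]) + 1,
        floor((H - layer@kernel[2]) / layer@stride[2]) + 1,
        layer@cOut)
    },
    pool = c(ceiling(W / 2), ceiling(H / 2), C),
    flatten = c(1, 1, W * H * C),
    dense = ,
    output = {
      if (W * H * C != layer@cIn) stop("dense fan-in mismatch")
      c(1, 1, layer@cOut)
    })
}

#' Count trainable parameters
#'
#' Conv: \code{cIn * cOut * kx * ky}; dense/output: \code{cIn * cOut};
#' pool/flatten/dropout carry none. No bias terms anywhere (per-layer
#' neuron parameters are counted separately and are few).
#'
#' @param object a \linkS4class{LayerSpec} or \linkS4class{NetworkSpec}.
#' @return integer parameter count.
#' @export
setGeneric("countParameters", function(object) standardGeneric("countParameters"))

#' @rdname countParameters
#' @export
setMethod("countParameters", "LayerSpec", function(object) {
  switch(object@kind,
    conv = object@cIn * object@cOut * object@kernel[1] * object@kernel[2],
    dense = ,
    output = object@cIn * object@cOut,
    0L)
})

#' @rdname countParameters
#' @export
setMethod("countParameters", "NetworkSpec", function(object) {
  sum(vapply(object@layers, countParameters, 0))
})

# --- index precomputation ---------------------------------------------------

# Data-independent gather / permutation indices are cached per geometry:
# rebuilding them per sample dominates runtime otherwise.
.idxCache <- new.env(parent = emptyenv())

.cachedIndex <- function(key, builder) {
  v <- .idxCache[[key]]
  if (is.null(v)) {
    v <- builder()
    assign(key, v, envir = .idxCache)
  }
  v
}

# im2col gather indices for a conv layer over input shape (W, H, C):
# a (nPos x K) integer matrix of 1-based flat input indices, with output
# positions enumerated row-fastest (h, then w) and kernel columns in (c,
# dy, dx) order matching the weight matrix rows.
.convIndices <- function(inShape, kernel, stride) {
  key <- sprintf("conv_%s_%s_%s", paste(inShape, collapse = "x"),
                 paste(kernel, collapse = "x"),
                 paste(stride, collapse = "x"))
  .cachedIndex(key, function() .convIndicesBuild(inShape, kernel, stride))
}

.convIndicesBuild <- function(inShape, kernel, stride) {
  W <- inShape[1]; H <- inShape[2]; C <- inShape[3]
  kx <- kernel[1]; ky <- kernel[2]; sx <- stride[1]; sy <- stride[2]
  Wo <- floor((W - kx) / sx) + 1
  Ho <- floor((H - ky) / sy) + 1
  oh <- rep(seq_len(Ho) - 1L, times = Wo)
  ow <- rep(seq_len(Wo) - 1L, each = Ho)
  # kernel offset enumeration: c fastest, then dy, then dx
  cc <- rep(seq_len(C), times = ky * kx)
  dy <- rep(rep(seq_len(ky) - 1L, each = C), times = kx)
  dx <- rep(seq_len(kx) - 1L, each = C * ky)
  h0 <- oh * sy   # nPos base rows
  w0 <- ow * sx
  # flat index = c + C * (h + H * w), 0-based h/w, 1-based c
  base <- C * (h0 + H * w0)                 # nPos
  off <- cc + C * (dy + H * dx)             # K
  P <- outer(base, off, "+")
  storage.mode(P) <- "integer"
  P
}

# pooling gather indices: (nOut x 4), 0 marks a padded (absent) cell.
.poolIndices <- function(inShape) {
  key <- sprintf("pool_%s", paste(inShape, collapse = "x"))
  .cachedIndex(key, function() .poolIndicesBuild(inShape))
}

.poolIndicesBuild <- function(inShape) {
  W <- inShape[1]; H <- inShape[2]; C <- inShape[3]
  Wo <- ceiling(W / 2); Ho <- ceiling(H / 2)
  cc <- rep(seq_len(C), times = Ho * Wo)
  oh <- rep(rep(seq_len(Ho) - 1L, each = C), times = Wo)
  ow <- rep(seq_len(Wo) - 1L, each = C * Ho)
  P <- matrix(0L, C * Ho * Wo, 4L)
  k <- 0L
  for (dx in 0:1) for (dy in 0:1) {
    k <- k + 1L
    h <- 2L * oh + dy
    w <- 2L * ow + dx
    ok <- h < H & w < W
    P[, k] <- ifelse(ok, cc + C * (h + H * w), 0L)
  }
  P
}

# Compile a network: per-layer shapes, flat sizes and gather indices.
# Depends only on the layer stack and geometry, so it is cached.
.compileNetwork <- function(net) {
  key <- sprintf("net_%s_%s", paste(net@inputShape, collapse = "x"),
                 paste(vapply(net@layers, function(l)
                   paste(l@kind, l@cIn, l@cOut, paste(l@kernel, collapse = ""),
                         paste(l@stride, collapse = ""), sep = "-"), ""),
                   collapse = "|"))
  .cachedIndex(key, function() .compileNetworkBuild(net))
}

.compileNetworkBuild <- function(net) {
  shape <- net@inputShape
  out <- vector("list", length(net@layers))
  for (i in seq_along(net@layers)) {
    l <- net@layers[[i]]
    outShape <- propagateShape(l, shape)
    info <- list(kind = l@kind, inShape = shape, outShape = outShape,
                 nIn = prod(shape), nOut = prod(outShape))
    if (l@kind == "conv")
      info$P <- .convIndices(shape, l@kernel, l@stride)
    if (l@kind == "pool")
      info$P <- .poolIndices(shape)
    out[[i]] <- info
    shape <- outShape
  }
  out
}

# --- weight containers ------------------------------------------------------

.rowNorms <- function(M) sqrt(rowSums(M^2)) + 1e-12

# Effective weight matrix of a dense/output layer (weight-norm aware).
.effectiveWeight <- function(wt) {
  if (!is.null(wt$g)) wt$g * wt$V / .rowNorms(wt$V) else wt$W
}

#' Initialize network weights
#'
#' Conv kernels and dense matrices are drawn with an activity-calibrated
#' He-style scheme, \eqn{N(0, 2 / (\mathrm{fan_{in}} \cdot \rho))}: because
#' layer inputs are sparse binary spike trains, only a fraction \eqn{\rho}
#' of a unit's inputs is active in any bin, so variance preservation uses
#' the expected active fan-in rather than the full fan-in.
#' Weight-normalized layers store a direction matrix and per-output gain
#' (initialized to the row norm, so the effective weights equal the draw).
#' Delay vectors start at zero. Per-layer neuron parameters copy the
#' layer's \linkS4class{CubaLifParams}.
#'
#' @param net a \linkS4class{NetworkSpec}.
#' @param seed RNG seed.
#' @param rho assumed active-input fraction per bin (default 0.15).
#' @return the network with its \code{weights} slot populated.
#' @export
initWeights <- function(net, seed = 1L, rho = 0.15) {
  comp <- .compileNetwork(net)
  withr::with_seed(seed, {
    ws <- vector("list", length(net@layers))
    for (i in seq_along(net@layers)) {
      l <- net@layers[[i]]
      info <- comp[[i]]
      wt <- list()
      if (l@kind == "conv") {
        K <- l@cIn * l@kernel[1] * l@kernel[2]
        wt$W <- matrix(stats::rnorm(K * l@cOut, sd = sqrt(2 / (K * rho))),
                       K, l@cOut)
      } else if (l@kind %in% c("dense", "output")) {
        M <- matrix(stats::rnorm(l@cOut * l@cIn,
                                 sd = sqrt(2 / (l@cIn * rho))),
                    l@cOut, l@cIn)
        if (l@weightNorm) {
          wt$V <- M
          wt$g <- .rowNorms(M)
        } else {
          wt$W <- M
        }
        if (l@delay) wt$delays <- numeric(l@cIn)
      }
      if (!is.null(l@neuron)) {
        wt$alphaU <- l@neuron@alphaU
        wt$alphaV <- l@neuron@alphaV
        wt$threshold <- l@neuron@threshold
        wt$bias <- l@neuron@bias
      }
      ws[[i]] <- wt
    }
    net@weights <- ws
  })
  net
}

# --- per-layer forward ------------------------------------------------------

# CUBA-LIF dynamics over a (nUnits x B*T) drive matrix, column = sample +
# B * (bin - 1): the recurrence steps over bins with all batch samples in
# one contiguous column block. Returns spikes and, when cache = TRUE, the
# stored state sequences needed for BPTT.
.runNeuron <- function(drive, wt, cache = FALSE, relaxed = FALSE,
                       surrogate = NULL, nBatch = 1L) {
  n <- nrow(drive); T <- ncol(drive) %/% nBatch
  u <- matrix(0, n, nBatch); v <- matrix(0, n, nBatch)
  S <- matrix(0, n, ncol(drive))
  U <- if (cache) matrix(0, n, ncol(drive)) else NULL
  Vbar <- if (cache) matrix(0, n, ncol(drive)) else NULL
  oneMinusAu <- 1 - wt$alphaU
  oneMinusAv <- 1 - wt$alphaV
  for (t in seq_len(T)) {
    cols <- ((t - 1L) * nBatch + 1L):(t * nBatch)
    u <- oneMinusAu * u + drive[, cols, drop = FALSE]
    vb <- oneMinusAv * v + u + wt$bias
    s <- if (relaxed) .surrogatePrimitive(vb - wt$threshold, surrogate)
         else (vb >= wt$threshold) * 1
    v <- vb * (1 - s)
    S[, cols] <- s
    if (cache) { U[, cols] <- u; Vbar[, cols] <- vb }
  }
  list(S = S, U = U, Vbar = Vbar)
}

# Gather index so that inMat[idx] arranged as a (nPos*T x K) matrix is the
# im2col matrix with rows ordered position-fastest, then bin.
.im2colIndex <- function(P, nIn, T) {
  nPos <- nrow(P); K <- ncol(P)
  key <- sprintf("im2col_%d_%d_%d_%d_%d", nIn, nPos, K, T, P[1, 1])
  .cachedIndex(key, function() {
    tOff <- (seq_len(T) - 1L) * nIn
    idx <- integer(nPos * T * K)
    for (k in seq_len(K))
      idx[((k - 1L) * nPos * T + 1L):(k * nPos * T)] <-
        rep(P[, k], times = T) + rep(tOff, each = nPos)
    idx
  })
}

.im2col <- function(inMat, P, T) {
  matrix(inMat[.im2colIndex(P, nrow(inMat), T)], nrow(P) * T, ncol(P))
}

# Permutation turning the (nPos*T x Cout) matmul result into the
# (Cout*nPos x T) drive matrix in flat (C, H, W) unit order, and back.
.convPermIndex <- function(nPos, T, Cout, inverse = FALSE) {
  key <- sprintf("convperm_%d_%d_%d_%d", nPos, T, Cout, inverse)
  .cachedIndex(key, function() {
    # R[pos + nPos*(t-1), c] -> D[c + Cout*(pos-1), t]
    cIdx <- rep_len(seq_len(Cout), Cout * nPos)
    posIdx <- rep(seq_len(nPos), each = Cout)
    if (!inverse) {
      # index into R, in D's column-major order
      as.vector(outer(posIdx + (cIdx - 1L) * (nPos * T),
                      (seq_len(T) - 1L) * nPos, "+"))
    } else {
      # index into D, in R's column-major order
      posR <- rep_len(seq_len(nPos), nPos * T)
      tR <- rep(seq_len(T), each = nPos)
      off <- (tR - 1L) * (Cout * nPos)
      as.vector(vapply(seq_len(Cout), function(cc)
        cc + Cout * (posR - 1L) + off, integer(nPos * T)))
    }
  })
}

.convDrive <- function(R, nPos, T, Cout) {
  matrix(R[.convPermIndex(nPos, T, Cout)], Cout * nPos, T)
}

# inverse: drive-layout gradient back to matmul layout
.convDriveInv <- function(D, nPos, T, Cout) {
  matrix(D[.convPermIndex(nPos, T, Cout, inverse = TRUE)], nPos * T, Cout)
}

# Shift rows of a (n x B*T) matrix right by per-row integer bin delays
# (zero fill); one bin = nBatch contiguous columns.
.applyDelays <- function(M, delays, Dmax, nBatch = 1L) {
  d <- pmin(pmax(round(delays), 0), Dmax)
  if (all(d == 0)) return(M)
  Tc <- ncol(M)
  for (dv in unique(d[d > 0])) {
    idx <- which(d == dv)
    dc <- dv * nBatch
    if (dc >= Tc) {
      M[idx, ] <- 0
    } else {
      M[idx, ] <- cbind(matrix(0, length(idx), dc),
                        M[idx, seq_len(Tc - dc), drop = FALSE])
    }
  }
  M
}

#' Forward pass of a single spiking layer
#'
#' Runs one layer over a full spike sequence: conv/dense stages apply the
#' (weight-normalized, delayed) linear map per bin and then CUBA-LIF
#' dynamics; pooling is a per-bin logical OR over each 2x2 stride-2 window
#' (ceil-padded); flatten reindexes only. Dropout (train mode) zeroes a
#' sampled input unit's entire spike train and rescales survivors by
#' 1/(1-p).
#'
#' @param layer a \linkS4class{LayerSpec}.
#' @param input spike matrix (nIn x T) in flat (C, H, W) order, or a
#'   (C, H, W, T) array.
#' @param inShape numeric (W, H, C) of the input (required for conv/pool
#'   when \code{input} is a matrix).
#' @param weights weight container as produced by \code{\link{initWeights}}
#'   (NULL draws a fresh seeded init for weighted layers).
#' @param train logical; enables dropout and gradient caching.
#' @param surrogate \linkS4class{SurrogateSpec} (used by the relaxed mode).
#' @param relaxed logical; replace the Heaviside by the smooth surrogate
#'   primitive (gradient checking only).
#' @return list with \code{output} (nOut x T spike matrix), \code{outShape},
#'   and \code{cache} (when training).
#' @export
layerForward <- function(layer, input, inShape = NULL, weights = NULL,
                         train = FALSE, surrogate = surrogateSpec(),
                         relaxed = FALSE, nBatch = 1L) {
  stopifnot(is(layer, "LayerSpec"))
  if (is.array(input) && length(dim(input)) == 4L) {
    d <- dim(input)
    inShape <- c(d[3], d[2], d[1])
    input <- matrix(input, prod(d[1:3]), d[4])
  }
  if (is.null(inShape)) {
    if (layer@kind %in% c("dense", "output", "flatten"))
      inShape <- c(1, 1, nrow(input))
    else stop("inShape required for conv/pool input matrices")
  }
  if (nrow(input) != prod(inShape)) stop("input size does not match inShape")
  outShape <- propagateShape(layer, inShape)
  T <- ncol(input)  # column count B*T; bin count is T / nBatch
  if (is.null(weights) && layer@kind %in% c("conv", "dense", "output")) {
    tmp <- new("NetworkSpec", layers = list(layer), inputShape = inShape,
               surrogate = surrogate, weights = list())
    weights <- initWeights(tmp, seed = 1L)@weights[[1]]
  }
  cache <- NULL
  if (layer@kind == "flatten") {
    out <- input
  } else if (layer@kind == "pool") {
    P <- .poolIndices(inShape)
    pad <- rbind(0, input)
    out <- pmax(pad[P[, 1] + 1L, , drop = FALSE],
                pad[P[, 2] + 1L, , drop = FALSE],
                pad[P[, 3] + 1L, , drop = FALSE],
                pad[P[, 4] + 1L, , drop = FALSE])
    if (train) cache <- list(P = P, input = input)
  } else if (layer@kind == "conv") {
    P <- .convIndices(inShape, layer@kernel, layer@stride)
    nPos <- nrow(P)
    X <- .im2col(input, P, T)
    drive <- .convDrive(X %*% weights$W, nPos, T, layer@cOut)
    nr <- .runNeuron(drive, weights, cache = train, relaxed = relaxed,
                     surrogate = surrogate, nBatch = nBatch)
    out <- nr$S
    if (train) cache <- list(P = P, X = X, drive = drive, U = nr$U,
                             Vbar = nr$Vbar, S = nr$S, input = input)
  } else {  # dense / output
    x <- input
    if (train && layer@dropout > 0) {
      # per-sample masks: a dropped unit is silenced for its whole train
      keep <- matrix(stats::runif(nrow(x) * nBatch) >= layer@dropout,
                     nrow(x), nBatch)
      keepExp <- keep[, rep_len(seq_len(nBatch), T), drop = FALSE]
      x <- x * (keepExp / (1 - layer@dropout))
    } else keepExp <- NULL
    nBins <- T %/% nBatch
    if (!is.null(weights$delays))
      x <- .applyDelays(x, weights$delays, Dmax = min(nBins - 1L, 62L),
                        nBatch = nBatch)
    Wef <- .effectiveWeight(weights)
    drive <- Wef %*% x
    nr <- .runNeuron(drive, weights, cache = train, relaxed = relaxed,
                     surrogate = surrogate, nBatch = nBatch)
    out <- nr$S
    if (train) cache <- list(xEff = x, keepExp = keepExp, Wef = Wef,
                             U = nr$U, Vbar = nr$Vbar, S = nr$S)
  }
  list(output = out, outShape = outShape, cache = cache)
}
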