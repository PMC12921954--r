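# The spiking convolutional classifier: architecture builder, full forward
# pass over spike tensors, and the spike-rate decoder.

#' Build the spiking convolutional classifier
#'
#' Layer stack (geometry-parameterized):
#' Conv(2->8, 3x3, s2) -> Pool(2x2, s2) -> Conv(8->8, 3x3, s1) ->
#' Pool(2x2, s2) -> Flatten -> Dense(flat->103, dropout 0.05, delays,
#' weight-norm) -> Dense(103->117, dropout 0.05, delays, weight-norm) ->
#' Output(117->2). At the native 360x260 sensor geometry the flatten size
#' is 11,264. All spiking stages are CUBA-LIF with shared per-layer neuron
#' parameters.
#'
#' @param width,height input sensor geometry in pixels.
#' @param neuron default \linkS4class{CubaLifParams} for every spiking
#'   stage.
#' @param surrogate \linkS4class{SurrogateSpec} used during training.
#' @param denseSizes hidden dense widths (default \code{c(103, 117)}).
#' @param nClasses output neurons (default 2).
#' @return A \linkS4class{NetworkSpec} (weights not yet initialized; see
#'   \code{\link{initWeights}}).
#' @export
buildSpikingConvNet <- function(width = 360, height = 260,
                                neuron = cubaLifParams(),
                                surrogate = surrogateSpec(
                                  width = neuron@threshold / 2),
                                denseSizes = c(103L, 117L),
                                nClasses = 2L) {
  layers <- list(
    layerSpec("conv", cIn = 2L, cOut = 8L, kernel = c(3L, 3L),
              stride = c(2L, 2L), neuron = neuron),
    layerSpec("pool", kernel = c(2L, 2L), stride = c(2L, 2L)),
    layerSpec("conv", cIn = 8L, cOut = 8L, kernel = c(3L, 3L),
              stride = c(1L, 1L), neuron = neuron),
    layerSpec("pool", kernel = c(2L, 2L), stride = c(2L, 2L)),
    layerSpec("flatten"))
  shape <- c(width, height, 2)
  for (l in layers) shape <- propagateShape(l, shape)
  flat <- shape[3]
  layers <- c(layers, list(
    layerSpec("dense", cIn = as.integer(flat), cOut = denseSizes[1],
              neuron = neuron, delay = TRUE, weightNorm = TRUE,
              dropout = 0.05),
    layerSpec("dense", cIn = denseSizes[1], cOut = denseSizes[2],
              neuron = neuron, delay = TRUE, weightNorm = TRUE,
              dropout = 0.05),
    layerSpec("output", cIn = denseSizes[2], cOut = as.integer(nClasses),
              neuron = neuron)))
  net <- new("NetworkSpec", layers = layers,
             inputShape = c(width, height, 2),
             surrogate = surrogate, weights = list())
  # validate the full chain
  for (l in layers[6:8]) shape <- propagateShape(l, shape)
  net
}

#' Network shape chain
#'
#' Propagates the input geometry through every layer.
#'
#' @param net a \linkS4class{NetworkSpec}.
#' @return matrix with one row per layer, columns W, H, C.
#' @export
shapeChain <- function(net) {
  shape <- net@inputShape
  out <- matrix(0, length(net@layers), 3,
                dimnames = list(vapply(net@layers, function(l) l@kind, ""),
                                c("W", "H", "C")))
  for (i in seq_along(net@layers)) {
    shape <- propagateShape(net@layers[[i]], shape)
    out[i, ] <- shape
  }
  out
}

#' Full forward pass over a spike tensor
#'
#' Runs every layer in sequence. In eval mode (default) dropout is off and
#' the pass is deterministic for fixed weights. The returned trace records
#' the total spike count at every layer output (the complexity module's
#' accounting nodes).
#'
#' @param net a \linkS4class{NetworkSpec} with initialized weights.
#' @param input a \linkS4class{SpikeTensor}, a (C, H, W, T) array, or a
#'   flat (nIn x T) spike matrix. A minibatch may be passed as a flat
#'   matrix with \code{nBatch * T} columns (column = sample + nBatch *
#'   (bin - 1)).
#' @param train logical; enables dropout and caches state for BPTT.
#' @param relaxed logical; smooth relaxed spikes (gradient checking only).
#' @param nBatch number of interleaved samples in the column dimension.
#' @return list with \code{output} (nClasses x T spike matrix; batched
#'   runs return nClasses x nBatch*T), \code{trace} (list with
#'   \code{spikeCounts} per layer, summed over the batch, and
#'   \code{kinds}), and \code{caches} (train mode).
#' @export
forwardPass <- function(net, input, train = FALSE, relaxed = FALSE,
                        nBatch = 1L) {
  stopifnot(is(net, "NetworkSpec"))
  if (!length(net@weights))
    stop("weights not initialized; call initWeights() first")
  if (is(input, "SpikeTensor")) input <- input@values
  if (is.array(input) && length(dim(input)) == 4L) {
    d <- dim(input)
    if (d[3] != net@inputShape[1] || d[2] != net@inputShape[2])
      stop("input geometry does not match the network input shape")
    input <- matrix(input, prod(d[1:3]), d[4])
  }
  if (nrow(input) != prod(net@inputShape))
    stop("input size does not match the network input shape")
  shape <- net@inputShape
  x <- input
  caches <- vector("list", length(net@layers))
  counts <- numeric(length(net@layers))
  for (i in seq_along(net@layers)) {
    lf <- layerForward(net@layers[[i]], x, inShape = shape,
                       weights = net@weights[[i]], train = train,
                       surrogate = net@surrogate, relaxed = relaxed,
                       nBatch = nBatch)
    x <- lf$output
    shape <- lf$outShape
    caches[[i]] <- lf$cache
    counts[i] <- sum(x)
  }
  list(output = x,
       trace = list(spikeCounts = counts,
                    kinds = vapply(net@layers, function(l) l@kind, "")),
       caches = if (train) caches else NULL)
}

#' Decode the predicted class from the output spike sequence
#'
#' \eqn{\hat y = \arg\max_i \frac{1}{T} \sum_t s_i[t]}: the output neuron
#' with the highest mean firing rate. Ties resolve to the lower index.
#'
#' @param output spike matrix (nClasses x T).
#' @return 0-based class index (0 = fixation, 1 = saccade in the default
#'   labelling).
#' @export
decodeRate <- function(output) {
  stopifnot(is.matrix(output), ncol(output) >= 1L)
  which.max(rowMeans(output)) - 1L
}

#' Save / load network checkpoints
#'
#' Weights, layer stack and surrogate spec are serialized with
#' \code{saveRDS}.
#'
#' @param net a \linkS4class{NetworkSpec}.
#' @param path checkpoint file.
#' @return \code{path} (save) or the restored \linkS4class{NetworkSpec}
#'   (load).
#' @export
saveCheckpoint <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  net <- readRDS(path)
  stopifnot(is(net, "NetworkSpec"))
  net
}
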