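#' @import methods
NULL

# ---------------------------------------------------------------------------
# Event data model
# ---------------------------------------------------------------------------

#' EventStream: an ordered asynchronous event-camera recording
#'
#' An event camera reports per-pixel brightness changes as discrete events
#' \eqn{e_i = (x_i, y_i, t_i, p_i)}: column \code{x}, row \code{y} (0-based,
#' origin top-left), timestamp \code{t} in integer microseconds, and polarity
#' \code{p} (+1 brightness increase, -1 decrease). An \code{EventStream}
#' couples the event table with the sensor geometry and the half-open time
#' span \code{[tStart, tEnd)} it covers.
#'
#' @slot events data.frame with columns \code{t}, \code{x}, \code{y},
#'   \code{p}, sorted by \code{t} (non-decreasing).
#' @slot width,height sensor geometry in pixels.
#' @slot tStart,tEnd recording span in microseconds, half-open.
#' @exportClass EventStream
setClass("EventStream",
  representation(
    events = "data.frame",
    width = "numeric",
    height = "numeric",
    tStart = "numeric",
    tEnd = "numeric"
  )
)

setValidity("EventStream", function(object) {
  ev <- object@events
  msgs <- character()
  need <- c("t", "x", "y", "p")
  if (!all(need %in% names(ev)))
    return(sprintf("events must have columns %s", paste(need, collapse = ", ")))
  if (length(object@width) != 1L || length(object@height) != 1L ||
      object@width < 1 || object@height < 1)
    msgs <- c(msgs, "width and height must be positive scalars")
  if (object@tEnd < object@tStart)
    msgs <- c(msgs, "tEnd must be >= tStart")
  if (nrow(ev) > 0L) {
    if (is.unsorted(ev$t)) msgs <- c(msgs, "timestamps must be non-decreasing")
    if (any(ev$x < 0 | ev$x >= object@width))
      msgs <- c(msgs, "x out of sensor geometry")
    if (any(ev$y < 0 | ev$y >= object@height))
      msgs <- c(msgs, "y out of sensor geometry")
    if (!all(ev$p %in% c(-1, 1)))
      msgs <- c(msgs, "polarity must be -1 or +1")
    if (any(ev$t < object@tStart) || any(ev$t >= object@tEnd))
      msgs <- c(msgs, "all events must lie inside [tStart, tEnd)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an EventStream
#'
#' Events are re-sorted by timestamp; the span defaults to
#' \code{[min(t), max(t) + 1)} (or \code{[0, 0)} for an empty table).
#'
#' @param events data.frame with columns \code{t}, \code{x}, \code{y},
#'   \code{p} (any order); polarities must be -1/+1.
#' @param width,height sensor geometry in pixels.
#' @param tStart,tEnd optional half-open span in microseconds.
#' @return An \linkS4class{EventStream}.
#' @examples
#' ev <- data.frame(t = c(10, 0, 5), x = 1:3, y = 0L, p = c(1, -1, 1))
#' s <- EventStream(ev, width = 8, height = 8)
#' nEvents(s)
#' @export
EventStream <- function(events, width, height, tStart = NULL, tEnd = NULL) {
  events <- as.data.frame(events)[, c("t", "x", "y", "p"), drop = FALSE]
  if (nrow(events) > 0L) {
    events <- events[order(events$t), , drop = FALSE]
    rownames(events) <- NULL
  }
  if (is.null(tStart))
    tStart <- if (nrow(events)) min(events$t) else 0
  if (is.null(tEnd))
    tEnd <- if (nrow(events)) max(events$t) + 1 else 0
  new("EventStream", events = events, width = as.numeric(width),
      height = as.numeric(height), tStart = as.numeric(tStart),
      tEnd = as.numeric(tEnd))
}

#' LabeledSegment: an event-stream segment with its eye-movement class
#'
#' @slot stream the \linkS4class{EventStream} covering one annotated interval.
#' @slot label \code{"fixation"} or \code{"saccade"}.
#' @slot userId integer participant identifier.
#' @slot eye \code{"left"} or \code{"right"}.
#' @exportClass LabeledSegment
setClass("LabeledSegment",
  representation(stream = "EventStream", label = "character",
                 userId = "integer", eye = "character")
)

setValidity("LabeledSegment", function(object) {
  if (!object@label %in% c("fixation", "saccade"))
    return("label must be 'fixation' or 'saccade'")
  if (!object@eye %in% c("left", "right"))
    return("eye must be 'left' or 'right'")
  TRUE
})

#' @rdname LabeledSegment-class
#' @param stream an \linkS4class{EventStream}.
#' @param label \code{"fixation"} or \code{"saccade"}.
#' @param userId participant id.
#' @param eye \code{"left"} or \code{"right"}.
#' @export
LabeledSegment <- function(stream, label, userId = 1L, eye = "left") {
  new("LabeledSegment", stream = stream, label = as.character(label),
      userId = as.integer(userId), eye = as.character(eye))
}

# ---------------------------------------------------------------------------
# Spike tensor
# ---------------------------------------------------------------------------

#' SpikeTensor: binary spatio-temporal discretization of an event stream
#'
#' Events are binned into a binary tensor \eqn{S \in \{0,1\}^{C \times H
#' \times W \times T}} with C = 2 polarity channels (channel 1 = OFF/-1,
#' channel 2 = ON/+1), bin width \eqn{\Delta t}, and \eqn{T} temporal bins.
#' Repeated events in one cell saturate at 1.
#'
#' @slot values binary numeric array of dim (2, H, W, T).
#' @slot dtMicros bin width in microseconds.
#' @slot originMicros timestamp mapped to bin 1.
#' @slot dropped number of events that fell at or beyond bin T.
#' @exportClass SpikeTensor
setClass("SpikeTensor",
  representation(values = "array", dtMicros = "numeric",
                 originMicros = "numeric", dropped = "integer")
)

setValidity("SpikeTensor", function(object) {
  d <- dim(object@values)
  if (length(d) != 4L) return("values must be a 4-d array (C, H, W, T)")
  if (d[1] != 2L) return("first dimension must have 2 polarity channels")
  if (d[4] < 1L) return("need at least one temporal bin")
  if (object@dtMicros <= 0) return("dtMicros must be positive")
  v <- object@values
  if (length(v) && !all(v == 0 | v == 1)) return("values must be binary")
  TRUE
})

# ---------------------------------------------------------------------------
# Neuron parameter containers
# ---------------------------------------------------------------------------

#' CUBA-LIF neuron parameters
#'
#' Discrete-time current-based leaky integrate-and-fire dynamics:
#' \deqn{u[t] = (1 - \alpha_u) u[t-1] + x[t]}
#' \deqn{v[t] = (1 - \alpha_v) v[t-1] + u[t] + b}
#' \deqn{s[t] = \Theta(v[t] - \vartheta), \quad v[t] \leftarrow v[t](1 - s[t])}
#'
#' @slot alphaU synaptic-current decay in (0, 1].
#' @slot alphaV membrane-potential decay in (0, 1].
#' @slot threshold firing threshold \eqn{\vartheta > 0}.
#' @slot bias constant membrane drive \eqn{b} (voltage units).
#' @slot learnable whether the trainer may update these parameters.
#' @exportClass CubaLifParams
setClass("CubaLifParams",
  representation(alphaU = "numeric", alphaV = "numeric",
                 threshold = "numeric", bias = "numeric",
                 learnable = "logical")
)

setValidity("CubaLifParams", function(object) {
  if (object@alphaU <= 0 || object@alphaU > 1) return("alphaU must be in (0, 1]")
  if (object@alphaV <= 0 || object@alphaV > 1) return("alphaV must be in (0, 1]")
  if (object@threshold <= 0) return("threshold must be positive")
  TRUE
})

#' @rdname CubaLifParams-class
#' @param alphaU,alphaV decay factors in (0, 1].
#' @param threshold firing threshold (> 0).
#' @param bias constant membrane drive.
#' @param learnable logical; expose to the optimizer.
#' @export
cubaLifParams <- function(alphaU = 0.5, alphaV = 0.25, threshold = 1.25,
                          bias = 0, learnable = TRUE) {
  new("CubaLifParams", alphaU = alphaU, alphaV = alphaV,
      threshold = threshold, bias = bias, learnable = learnable)
}

#' LIF reference neuron parameters (recurrent membrane cell)
#'
#' Reference single-state leaky integrate-and-fire cell with optional spike
#' feedback and a proportional reset term:
#' \deqn{U_t = (1 - R)(\beta U_{t-1} + V^{res} s_{t-1} + I_t)}
#' with the \eqn{(1-R)} factor dropped when \code{resetMode = "none"}.
#' Provided for comparison; the classifier uses CUBA-LIF.
#'
#' @slot beta membrane decay in [0, 1).
#' @slot resetMode \code{"proportional"} or \code{"none"}.
#' @slot resetR proportional reset magnitude R in [0, 1).
#' @slot vRes recurrent weight applied to the previous spike.
#' @slot threshold firing threshold.
#' @exportClass LifParams
setClass("LifParams",
  representation(beta = "numeric", resetMode = "character",
                 resetR = "numeric", vRes = "numeric", threshold = "numeric")
)

setValidity("LifParams", function(object) {
  if (object@beta < 0 || object@beta >= 1) return("beta must be in [0, 1)")
  if (!object@resetMode %in% c("proportional", "none"))
    return("resetMode must be 'proportional' or 'none'")
  if (object@resetR < 0 || object@resetR >= 1) return("resetR must be in [0, 1)")
  TRUE
})

#' @rdname LifParams-class
#' @param beta membrane decay in [0, 1).
#' @param resetMode \code{"proportional"} or \code{"none"}.
#' @param resetR proportional reset magnitude.
#' @param vRes recurrent spike weight.
#' @param threshold firing threshold.
#' @export
lifParams <- function(beta = 0.9, resetMode = "proportional", resetR = 0.1,
                      vRes = 0, threshold = 1) {
  new("LifParams", beta = beta, resetMode = resetMode, resetR = resetR,
      vRes = vRes, threshold = threshold)
}

#' Surrogate-gradient specification
#'
#' The forward pass always uses the exact Heaviside spike function; only the
#' backward sensitivity is replaced by a smooth kernel centred on the
#' threshold. Families: \code{"exponential"} with
#' \eqn{\sigma'(x) = e^{-|x|/\sigma} / (2\sigma)} and \code{"fast-sigmoid"}
#' with \eqn{\sigma'(x) = 1 / (2\sigma (1 + |x|/\sigma)^2)}; both integrate
#' to one.
#'
#' @slot family \code{"fast-sigmoid"} (default) or \code{"exponential"}.
#' @slot width kernel width \eqn{\sigma > 0} in membrane-potential units.
#' @exportClass SurrogateSpec
setClass("SurrogateSpec",
  representation(family = "character", width = "numeric"))

setValidity("SurrogateSpec", function(object) {
  if (!object@family %in% c("exponential", "fast-sigmoid"))
    return("family must be 'exponential' or 'fast-sigmoid'")
  if (object@width <= 0) return("width must be positive")
  TRUE
})

#' @rdname SurrogateSpec-class
#' @param family kernel family.
#' @param width kernel width (> 0).
#' @export
surrogateSpec <- function(family = "fast-sigmoid", width = 0.625) {
  new("SurrogateSpec", family = family, width = width)
}

# ---------------------------------------------------------------------------
# Architecture
# ---------------------------------------------------------------------------

#' LayerSpec: one stage of the spiking convolutional network
#'
#' @slot kind one of \code{"conv"}, \code{"pool"}, \code{"dense"},
#'   \code{"flatten"}, \code{"output"}.
#' @slot cIn,cOut channel / unit counts (weighted layers).
#' @slot kernel,stride integer pairs (x, y) for conv/pool stages.
#' @slot neuron \linkS4class{CubaLifParams} for spiking stages, or NULL.
#' @slot delay logical; apply per-input synaptic delays (dense stages).
#' @slot weightNorm logical; per-output-unit weight normalization.
#' @slot dropout dropout probability applied to the stage input (train mode).
#' @exportClass LayerSpec
setClass("LayerSpec",
  representation(kind = "character", cIn = "integer", cOut = "integer",
                 kernel = "integer", stride = "integer", neuron = "ANY",
                 delay = "logical", weightNorm = "logical",
                 dropout = "numeric")
)

setValidity("LayerSpec", function(object) {
  kinds <- c("conv", "pool", "dense", "flatten", "output")
  if (!object@kind %in% kinds)
    return(sprintf("kind must be one of %s", paste(kinds, collapse = ", ")))
  if (object@kind %in% c("conv", "pool")) {
    if (any(object@kernel < 1L) || any(object@stride < 1L))
      return("kernel and stride must be positive")
  }
  if (object@kind %in% c("conv", "dense", "output")) {
    if (object@cIn < 1L || object@cOut < 1L)
      return("cIn and cOut must be positive for weighted layers")
  }
  if (object@dropout < 0 || object@dropout >= 1)
    return("dropout must be in [0, 1)")
  TRUE
})

#' @rdname LayerSpec-class
#' @param kind layer kind.
#' @param cIn,cOut input/output channels or unit counts.
#' @param kernel,stride length-2 integer vectors (x, y).
#' @param neuron \linkS4class{CubaLifParams} or NULL.
#' @param delay logical, per-input synaptic delays.
#' @param weightNorm logical, weight normalization.
#' @param dropout dropout probability on the stage input.
#' @export
layerSpec <- function(kind, cIn = 0L, cOut = 0L, kernel = c(1L, 1L),
                      stride = c(1L, 1L), neuron = NULL, delay = FALSE,
                      weightNorm = FALSE, dropout = 0) {
  new("LayerSpec", kind = kind, cIn = as.integer(cIn), cOut = as.integer(cOut),
      kernel = as.integer(kernel), stride = as.integer(stride),
      neuron = neuron, delay = delay, weightNorm = weightNorm,
      dropout = as.numeric(dropout))
}

#' NetworkSpec: an ordered stack of layers bound to an input geometry
#'
#' @slot layers list of \linkS4class{LayerSpec}.
#' @slot inputShape numeric (W, H, C) of the spike-tensor input.
#' @slot surrogate \linkS4class{SurrogateSpec} used in training.
#' @slot weights named list of per-layer weight containers (empty until
#'   \code{initWeights} is called).
#' @exportClass NetworkSpec
setClass("NetworkSpec",
  representation(layers = "list", inputShape = "numeric",
                 surrogate = "SurrogateSpec", weights = "list")
)

setValidity("NetworkSpec", function(object) {
  if (length(object@inputShape) != 3L) return("inputShape must be (W, H, C)")
  if (!all(vapply(object@layers, is, TRUE, class2 = "LayerSpec")))
    return("layers must all be LayerSpec objects")
  TRUE
})

# ---------------------------------------------------------------------------
# Simulator parameter containers
# ---------------------------------------------------------------------------

#' Near-eye scene model for the event-camera emulator
#'
#' Concentric dark-pupil / iris discs on a bright sclera, with an optional
#' static circular aperture beyond which a background level applies. All
#' intensities are strictly positive so log-intensity exists.
#'
#' @slot pupilRadius,irisRadius disc radii in pixels (pupil < iris).
#' @slot intensities named numeric: pupil, iris, sclera, background, each in
#'   (0, 1].
#' @slot width,height sensor geometry in pixels.
#' @slot apertureRadius radius of the eye opening in pixels (NA disables).
#' @exportClass SceneModel
setClass("SceneModel",
  representation(pupilRadius = "numeric", irisRadius = "numeric",
                 intensities = "numeric", width = "numeric",
                 height = "numeric", apertureRadius = "numeric")
)

setValidity("SceneModel", function(object) {
  need <- c("pupil", "iris", "sclera", "background")
  if (!all(need %in% names(object@intensities)))
    return("intensities must name pupil, iris, sclera, background")
  if (any(object@intensities <= 0) || any(object@intensities > 1))
    return("intensities must be in (0, 1]")
  if (object@pupilRadius <= 0 || object@pupilRadius >= object@irisRadius)
    return("need 0 < pupilRadius < irisRadius")
  TRUE
})

#' @rdname SceneModel-class
#' @param width,height sensor geometry in pixels.
#' @param pupilRadius,irisRadius disc radii in pixels.
#' @param intensities named numeric levels in (0, 1].
#' @param apertureRadius eye-opening radius in pixels (NA = full frame sclera).
#' @export
sceneModel <- function(width = 360, height = 260,
                       pupilRadius = 0.08 * min(width, height),
                       irisRadius = 0.25 * min(width, height),
                       intensities = c(pupil = 0.05, iris = 0.3,
                                       sclera = 0.9, background = 0.6),
                       apertureRadius = NA_real_) {
  new("SceneModel", pupilRadius = pupilRadius, irisRadius = irisRadius,
      intensities = intensities, width = as.numeric(width),
      height = as.numeric(height), apertureRadius = as.numeric(apertureRadius))
}

#' Event-camera emulator parameters
#'
#' @slot threshold contrast threshold \eqn{\theta > 0} in log-intensity units.
#' @slot renderRate frame-render rate in Hz.
#' @slot noiseRate spurious-event rate (events / pixel / second).
#' @slot seed RNG seed for noise.
#' @exportClass EmulatorParams
setClass("EmulatorParams",
  representation(threshold = "numeric", renderRate = "numeric",
                 noiseRate = "numeric", seed = "integer")
)

setValidity("EmulatorParams", function(object) {
  if (object@threshold <= 0) return("threshold must be positive")
  if (object@renderRate <= 0) return("renderRate must be positive")
  if (object@noiseRate < 0) return("noiseRate must be non-negative")
  TRUE
})

#' @rdname EmulatorParams-class
#' @param threshold contrast threshold in log-intensity units.
#' @param renderRate frame rate of the rendered intensity sequence (Hz).
#' @param noiseRate homogeneous Poisson noise rate (events/pixel/s).
#' @param seed RNG seed.
#' @export
emulatorParams <- function(threshold = 0.15, renderRate = 2000,
                           noiseRate = 0.1, seed = 1L) {
  new("EmulatorParams", threshold = threshold, renderRate = renderRate,
      noiseRate = noiseRate, seed = as.integer(seed))
}

#' Gaze kinematics parameters
#'
#' Physiological defaults: fixations last 50-600 ms with slow drift;
#' saccades last 20-200 ms, follow a raised-cosine (sin^2) velocity profile
#' and are capped at a configured peak velocity, the pixel-domain analogue
#' of ~700 deg/s (about 4.3 px/deg for a near-eye DAVIS geometry).
#'
#' @slot fixDurationMs,sacDurationMs duration ranges (ms).
#' @slot sacAmplitudePx amplitude range (pixels).
#' @slot driftSigma fixational drift standard deviation (pixels per sample).
#' @slot velocityCap peak-velocity cap (pixels per second).
#' @exportClass KinematicsParams
setClass("KinematicsParams",
  representation(fixDurationMs = "numeric", sacDurationMs = "numeric",
                 sacAmplitudePx = "numeric", driftSigma = "numeric",
                 velocityCap = "numeric")
)

setValidity("KinematicsParams", function(object) {
  rng <- function(r) length(r) == 2L && r[1] > 0 && r[1] <= r[2]
  if (!rng(object@fixDurationMs)) return("fixDurationMs must be an ordered positive range")
  if (!rng(object@sacDurationMs)) return("sacDurationMs must be an ordered positive range")
  if (!rng(object@sacAmplitudePx)) return("sacAmplitudePx must be an ordered positive range")
  if (object@driftSigma < 0) return("driftSigma must be non-negative")
  if (object@velocityCap <= 0) return("velocityCap must be positive")
  TRUE
})

#' @rdname KinematicsParams-class
#' @param fixDurationMs fixation duration range in ms.
#' @param sacDurationMs saccade duration range in ms.
#' @param sacAmplitudePx saccade amplitude range in pixels.
#' @param driftSigma fixational drift sd in pixels per trajectory sample.
#' @param velocityCap saccade peak-velocity cap in pixels per second.
#' @export
kinematicsParams <- function(fixDurationMs = c(50, 600),
                             sacDurationMs = c(20, 200),
                             sacAmplitudePx = c(30, 120),
                             driftSigma = 0.005,
                             velocityCap = 3000) {
  new("KinematicsParams", fixDurationMs = fixDurationMs,
      sacDurationMs = sacDurationMs, sacAmplitudePx = sacAmplitudePx,
      driftSigma = driftSigma, velocityCap = velocityCap)
}

#' GazeTrajectory: pupil-centre motion on a uniform time grid
#'
#' @slot timesMicros sample times (microseconds, uniform grid).
#' @slot x,y pupil-centre position per sample (pixels, continuous).
#' @slot label per-sample class, \code{"fixation"} or \code{"saccade"}.
#' @slot rateHz sampling rate of the grid.
#' @slot groundTruth data.frame of the generating intervals
#'   (\code{tStart}, \code{tEnd} microseconds, \code{label}).
#' @exportClass GazeTrajectory
setClass("GazeTrajectory",
  representation(timesMicros = "numeric", x = "numeric", y = "numeric",
                 label = "character", rateHz = "numeric",
                 groundTruth = "data.frame")
)

setValidity("GazeTrajectory", function(object) {
  n <- length(object@timesMicros)
  if (length(object@x) != n || length(object@y) != n ||
      length(object@label) != n)
    return("times, x, y, label must have equal length")
  if (n > 1L) {
    d <- diff(object@timesMicros)
    if (any(abs(d - d[1]) > 1e-6)) return("time grid must be uniform")
  }
  TRUE
})

# ---------------------------------------------------------------------------
# Training / reporting containers
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' Defaults mirror the study protocol: spike-rate loss, Adam, learning rate
#' 0.01, batch size 8. The epoch count is scaled to the experiment at hand
#' (100 at full scale; desk-scale runs use fewer).
#'
#' @slot epochs,batchSize,learningRate optimizer settings.
#' @slot rTrue,rFalse target firing rates for the true / non-target class.
#' @slot seed RNG seed controlling init, shuffling and dropout.
#' @slot valFraction fraction of training segments held out for per-epoch
#'   validation metrics (0 disables).
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(epochs = "integer", batchSize = "integer",
                 learningRate = "numeric", rTrue = "numeric",
                 rFalse = "numeric", seed = "integer",
                 valFraction = "numeric")
)

setValidity("TrainConfig", function(object) {
  if (!(object@rFalse >= 0 && object@rFalse < object@rTrue &&
        object@rTrue <= 1))
    return("need 0 <= rFalse < rTrue <= 1")
  if (object@epochs < 1L || object@batchSize < 1L)
    return("epochs and batchSize must be positive")
  if (object@learningRate <= 0) return("learningRate must be positive")
  TRUE
})

#' @rdname TrainConfig-class
#' @param epochs number of passes over the training set.
#' @param batchSize minibatch size.
#' @param learningRate Adam step size.
#' @param rTrue,rFalse target output firing rates.
#' @param seed RNG seed.
#' @param valFraction validation holdout fraction within the training set.
#' @export
trainConfig <- function(epochs = 100L, batchSize = 8L, learningRate = 0.01,
                        rTrue = 0.2, rFalse = 0.03, seed = 1L,
                        valFraction = 0) {
  new("TrainConfig", epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), learningRate = learningRate,
      rTrue = rTrue, rFalse = rFalse, seed = as.integer(seed),
      valFraction = valFraction)
}

#' ComplexityReport: layer-wise SNN-vs-ANN operation accounting
#'
#' One row per accounting node (the output of each network stage, node 0 =
#' first conv output). Columns: unit count (ANN activations), equivalent-ANN
#' MACs, mean SNN spike events per sample, and synaptic operations
#' (synops). Totals follow the table conventions: the node-0 MAC cell
#' mirrors its unit count and is excluded from the MAC total, while the
#' activation total includes node 0.
#'
#' @slot nodes data.frame with columns \code{node}, \code{stage},
#'   \code{shapeW}, \code{shapeH}, \code{shapeC}, \code{units}, \code{macs},
#'   \code{events}, \code{synops}.
#' @slot totals named numeric: \code{units}, \code{macs}, \code{events},
#'   \code{synops} (event/synop totals NA when no traces were profiled).
#' @exportClass ComplexityReport
setClass("ComplexityReport",
  representation(nodes = "data.frame", totals = "numeric"))
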