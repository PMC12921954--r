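# Generics, accessors and show methods for the core containers.

#' Number of events in a stream or segment
#' @param object an \linkS4class{EventStream} or \linkS4class{LabeledSegment}.
#' @return integer event count.
#' @export
setGeneric("nEvents", function(object) standardGeneric("nEvents"))

#' @rdname nEvents
#' @export
setMethod("nEvents", "EventStream", function(object) nrow(object@events))

#' @rdname nEvents
#' @export
setMethod("nEvents", "LabeledSegment", function(object) nrow(object@stream@events))

#' Event table of a stream
#' @param object an \linkS4class{EventStream}.
#' @return data.frame with columns t, x, y, p sorted by t.
#' @export
setGeneric("eventData", function(object) standardGeneric("eventData"))

#' @rdname eventData
#' @export
setMethod("eventData", "EventStream", function(object) object@events)

#' Sensor geometry (width, height) in pixels
#' @param object an object carrying a sensor geometry.
#' @return named numeric c(width, height).
#' @export
setGeneric("sensorSize", function(object) standardGeneric("sensorSize"))

#' @rdname sensorSize
#' @export
setMethod("sensorSize", "EventStream", function(object)
  c(width = object@width, height = object@height))

#' @rdname sensorSize
#' @export
setMethod("sensorSize", "SceneModel", function(object)
  c(width = object@width, height = object@height))

#' Time span of a stream
#' @param object an \linkS4class{EventStream}.
#' @return numeric c(tStart, tEnd) in microseconds (half-open).
#' @export
setGeneric("timeSpan", function(object) standardGeneric("timeSpan"))

#' @rdname timeSpan
#' @export
setMethod("timeSpan", "EventStream", function(object)
  c(tStart = object@tStart, tEnd = object@tEnd))

#' Class label of a segment
#' @param object a \linkS4class{LabeledSegment}.
#' @return character label.
#' @export
setGeneric("segmentLabel", function(object) standardGeneric("segmentLabel"))

#' @rdname segmentLabel
#' @export
setMethod("segmentLabel", "LabeledSegment", function(object) object@label)

#' Participant id of a segment
#' @param object a \linkS4class{LabeledSegment}.
#' @return integer user id.
#' @export
setGeneric("userId", function(object) standardGeneric("userId"))

#' @rdname userId
#' @export
setMethod("userId", "LabeledSegment", function(object) object@userId)

#' Event stream carried by a segment
#' @param object a \linkS4class{LabeledSegment}.
#' @return the \linkS4class{EventStream}.
#' @export
setGeneric("segmentStream", function(object) standardGeneric("segmentStream"))

#' @rdname segmentStream
#' @export
setMethod("segmentStream", "LabeledSegment", function(object) object@stream)

#' Spike values array of a tensor
#' @param object a \linkS4class{SpikeTensor}.
#' @return binary array of dim (2, H, W, T).
#' @export
setGeneric("spikeValues", function(object) standardGeneric("spikeValues"))

#' @rdname spikeValues
#' @export
setMethod("spikeValues", "SpikeTensor", function(object) object@values)

#' Number of temporal bins of a tensor
#' @param object a \linkS4class{SpikeTensor}.
#' @return integer T.
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))

#' @rdname nBins
#' @export
setMethod("nBins", "SpikeTensor", function(object) dim(object@values)[4])

#' Count of events dropped during encoding
#' @param object a \linkS4class{SpikeTensor}.
#' @return integer drop tally.
#' @export
setGeneric("droppedEvents", function(object) standardGeneric("droppedEvents"))

#' @rdname droppedEvents
#' @export
setMethod("droppedEvents", "SpikeTensor", function(object) object@dropped)

# -- show methods -----------------------------------------------------------

setMethod("show", "EventStream", function(object) {
  cat(sprintf("EventStream: %d events, %gx%g px, span [%g, %g) us\n",
              nrow(object@events), object@width, object@height,
              object@tStart, object@tEnd))
})

setMethod("show", "LabeledSegment", function(object) {
  cat(sprintf("LabeledSegment: %s, user %d (%s eye), %d events over %g ms\n",
              object@label, object@userId, object@eye,
              nrow(object@stream@events),
              (object@stream@tEnd - object@stream@tStart) / 1e3))
})

setMethod("show", "SpikeTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "SpikeTensor: (C=%d, H=%d, W=%d, T=%d), dt = %g us, %d spikes, %d dropped\n",
    d[1], d[2], d[3], d[4], object@dtMicros, sum(object@values),
    object@dropped))
})

setMethod("show", "NetworkSpec", function(object) {
  cat(sprintf("NetworkSpec: input (W=%g, H=%g, C=%g), %d layers%s\n",
              object@inputShape[1], object@inputShape[2], object@inputShape[3],
              length(object@layers),
              if (length(object@weights)) ", weights initialized" else ""))
  for (i in seq_along(object@layers)) {
    l <- object@layers[[i]]
    cat(sprintf("  [%d] %-7s", i, l@kind))
    if (l@kind %in% c("conv"))
      cat(sprintf(" %d->%d k%dx%d s%dx%d", l@cIn, l@cOut, l@kernel[1],
                  l@kernel[2], l@stride[1], l@stride[2]))
    if (l@kind %in% c("dense", "output"))
      cat(sprintf(" %d->%d%s%s%s", l@cIn, l@cOut,
                  if (l@dropout > 0) sprintf(" dropout %.2g", l@dropout) else "",
                  if (l@delay) " delay" else "",
                  if (l@weightNorm) " wnorm" else ""))
    cat("\n")
  }
})

setMethod("show", "ComplexityReport", function(object) {
  cat("ComplexityReport (per accounting node):\n")
  print(object@nodes, row.names = FALSE)
  cat("Totals:\n")
  print(object@totals)
})

setMethod("show", "GazeTrajectory", function(object) {
  cat(sprintf(
    "GazeTrajectory: %d samples at %g Hz, %d segments (%d fixation / %d saccade)\n",
    length(object@timesMicros), object@rateHz, nrow(object@groundTruth),
    sum(object@groundTruth$label == "fixation"),
    sum(object@groundTruth$label == "saccade")))
})
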