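# Event-stream -> binary spike-tensor encoding and spike-rate maps.

#' Encode an event stream as a binary spike tensor
#'
#' Each event with relative time \eqn{t' = t - origin} is assigned to bin
#' \eqn{b = \lfloor t' / \Delta t \rfloor}; the tensor cell (channel(p), y,
#' x, b) is set to 1. Channel mapping: p = -1 -> channel 1 (OFF), p = +1 ->
#' channel 2 (ON). Repeated hits saturate at 1; events with \eqn{b \ge T}
#' are dropped and tallied. Events before the origin are an error (slice
#' first).
#'
#' @param stream an \linkS4class{EventStream}.
#' @param dtMicros bin width in microseconds (> 0).
#' @param T number of temporal bins (>= 1).
#' @param origin timestamp mapped to bin 1 (default: the stream's tStart).
#' @return A \linkS4class{SpikeTensor} of dim (2, H, W, T).
#' @export
encodeSpikes <- function(stream, dtMicros = 1000, T, origin = NULL) {
  stopifnot(is(stream, "EventStream"), dtMicros > 0, T >= 1)
  if (is.null(origin)) origin <- stream@tStart
  H <- stream@height; W <- stream@width
  vals <- array(0, dim = c(2L, H, W, as.integer(T)))
  ev <- stream@events
  dropped <- 0L
  if (nrow(ev)) {
    rel <- ev$t - origin
    if (any(rel < 0))
      stop("events precede the encoding origin; slice the stream first")
    b <- floor(rel / dtMicros)
    keep <- b < T
    dropped <- sum(!keep)
    if (any(keep)) {
      ch <- ifelse(ev$p[keep] > 0, 2L, 1L)
      idx <- ch + 2L * (ev$y[keep] + H * (ev$x[keep] + W * b[keep]))
      vals[idx] <- 1
    }
  }
  new("SpikeTensor", values = vals, dtMicros = as.numeric(dtMicros),
      originMicros = as.numeric(origin), dropped = as.integer(dropped))
}

#' Spike-rate map of a tensor
#'
#' Element-wise mean over the time axis:
#' \eqn{r_{p,y,x} = \frac{1}{T} \sum_t S[p, y, x, t]}.
#'
#' @param S a \linkS4class{SpikeTensor}.
#' @return numeric array of dim (2, H, W) with values in [0, 1].
#' @export
spikeRateMap <- function(S) {
  stopifnot(is(S, "SpikeTensor"))
  d <- dim(S@values)
  apply(S@values, c(1, 2, 3), mean)
}

#' Number of temporal bins covering an accumulation window
#'
#' \eqn{T = \lceil \mathrm{window\,ms} \times 1000 / \Delta t \rceil}: the
#' window is expressed in milliseconds at the API surface, converted
#' exactly to microseconds, and partial trailing bins are rounded up so no
#' in-window event is un-binnable.
#'
#' @param windowMs accumulation window in milliseconds (> 0).
#' @param dtMicros bin width in microseconds (> 0).
#' @return integer bin count T.
#' @export
windowToBins <- function(windowMs, dtMicros = 1000) {
  stopifnot(windowMs > 0, dtMicros > 0)
  as.integer(ceiling(windowMs * 1000 / dtMicros))
}
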