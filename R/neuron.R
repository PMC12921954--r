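# Neuron dynamics: CUBA-LIF, the LIF reference cell, decay helpers and the
# surrogate spike function.

#' One discrete CUBA-LIF step
#'
#' Applies, in order:
#' \deqn{u \leftarrow (1 - \alpha_u) u + x_t}
#' \deqn{v \leftarrow (1 - \alpha_v) v + u + b}
#' \deqn{s = \Theta(v - \vartheta), \quad v \leftarrow v (1 - s)}
#' so spiking neurons end the step with v = 0.
#'
#' @param state list with numeric vectors \code{u} and \code{v} (use
#'   \code{neuronState(n)} for a zero state).
#' @param x input synaptic drive, same length as the state.
#' @param params a \linkS4class{CubaLifParams}.
#' @return list with \code{state} (updated \code{u}, \code{v}) and binary
#'   \code{spikes}.
#' @export
cubaLifStep <- function(state, x, params) {
  stopifnot(is(params, "CubaLifParams"))
  if (any(is.na(x))) stop("NaN/NA input to cubaLifStep")
  u <- (1 - params@alphaU) * state$u + x
  v <- (1 - params@alphaV) * state$v + u + params@bias
  s <- as.numeric(v >= params@threshold)
  v <- v * (1 - s)
  list(state = list(u = u, v = v), spikes = s)
}

#' Zero neuron state
#' @param n number of neurons.
#' @return list with zero vectors \code{u} and \code{v}.
#' @export
neuronState <- function(n) list(u = numeric(n), v = numeric(n))

#' One step of the recurrent LIF reference cell
#'
#' \deqn{U \leftarrow (1 - R)(\beta U + V^{res} s_{prev} + I)}
#' with the \eqn{(1 - R)} factor dropped when \code{resetMode = "none"};
#' then threshold and spike as in \code{\link{cubaLifStep}} (spiking
#' neurons are zeroed). Provided as a reference model; the classifier uses
#' CUBA-LIF.
#'
#' @param U membrane potential vector.
#' @param input synaptic input vector.
#' @param params a \linkS4class{LifParams}.
#' @param sPrev previous-step spike vector (for the recurrent term).
#' @return list with \code{U} and \code{spikes}.
#' @export
lifStep <- function(U, input, params, sPrev = numeric(length(U))) {
  stopifnot(is(params, "LifParams"))
  if (any(is.na(input))) stop("NaN/NA input to lifStep")
  U <- params@beta * U + params@vRes * sPrev + input
  if (params@resetMode == "proportional") U <- (1 - params@resetR) * U
  s <- as.numeric(U >= params@threshold)
  U <- U * (1 - s)
  list(U = U, spikes = s)
}

#' Decay factors from time constants
#'
#' \eqn{\alpha = 1 - e^{-\Delta t / \tau}}; large \eqn{\tau} means little
#' leak. Invertible via \code{\link{timeConstantsFromDecay}}.
#'
#' @param tauSyn,tauMem synaptic / membrane time constants (> 0, same units
#'   as \code{dt}).
#' @param dt simulation step.
#' @return named numeric \code{c(alphaU, alphaV)}.
#' @export
decayFromTimeConstants <- function(tauSyn, tauMem, dt = 1) {
  stopifnot(tauSyn > 0, tauMem > 0, dt > 0)
  c(alphaU = 1 - exp(-dt / tauSyn), alphaV = 1 - exp(-dt / tauMem))
}

#' @rdname decayFromTimeConstants
#' @param alphaU,alphaV decay factors in (0, 1).
#' @return named numeric \code{c(tauSyn, tauMem)}.
#' @export
timeConstantsFromDecay <- function(alphaU, alphaV, dt = 1) {
  stopifnot(alphaU > 0, alphaU < 1, alphaV > 0, alphaV < 1)
  c(tauSyn = -dt / log(1 - alphaU), tauMem = -dt / log(1 - alphaV))
}

# Surrogate derivative kernel, evaluated at v - threshold. Both families
# integrate to one, so the total backward "mass" matches the Heaviside jump.
.surrogateDeriv <- function(x, surrogate) {
  s <- surrogate@width
  switch(surrogate@family,
    "exponential" = exp(-abs(x) / s) / (2 * s),
    "fast-sigmoid" = 1 / (2 * s * (1 + abs(x) / s)^2))
}

# Smooth primitive of the kernel (a relaxed spike in [0, 1]); used only by
# the gradient-check relaxed mode, never in the standard forward pass.
.surrogatePrimitive <- function(x, surrogate) {
  s <- surrogate@width
  switch(surrogate@family,
    "exponential" = ifelse(x < 0, 0.5 * exp(x / s), 1 - 0.5 * exp(-x / s)),
    "fast-sigmoid" = 0.5 + 0.5 * (x / s) / (1 + abs(x / s)))
}
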