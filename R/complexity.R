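# SNN-vs-ANN computational-complexity accounting: per-node unit counts,
# equivalent-ANN MACs, measured spike events, synaptic operations, sparsity
# ratios, and the energy estimate.
#
# Accounting nodes are the outputs of each network stage in order (node 0 =
# first conv output); the flatten stage is a pure reindexing and is not a
# node. The fan-out convention is uniform (border effects ignored): one
# spike at node k-1 triggers fanOut(stage k) downstream accumulates.

#' Uniform fan-out of a network stage
#'
#' Conv: \code{kx * ky * cOut / (sx * sy)}; pool (2x2 stride 2) and
#' flatten: 1; dense/output: the output width.
#'
#' @param layer a \linkS4class{LayerSpec}.
#' @return numeric fan-out.
#' @export
stageFanOut <- function(layer) {
  stopifnot(is(layer, "LayerSpec"))
  switch(layer@kind,
    conv = layer@kernel[1] * layer@kernel[2] * layer@cOut /
      (layer@stride[1] * layer@stride[2]),
    pool = 1,
    flatten = 1,
    dense = ,
    output = as.numeric(layer@cOut))
}

# Accounting-node table skeleton: one row per non-flatten stage.
.accountingNodes <- function(net) {
  shapes <- shapeChain(net)
  keep <- which(vapply(net@layers, function(l) l@kind != "flatten", TRUE))
  data.frame(
    node = seq_along(keep) - 1L,
    stage = vapply(net@layers[keep], function(l) l@kind, ""),
    layerIndex = keep,
    shapeW = shapes[keep, "W"], shapeH = shapes[keep, "H"],
    shapeC = shapes[keep, "C"],
    units = shapes[keep, "W"] * shapes[keep, "H"] * shapes[keep, "C"],
    fanOut = vapply(net@layers[keep], stageFanOut, 0))
}

#' Equivalent-ANN MAC counts per accounting node
#'
#' Node 0 (the first conv output) reports its own unit count in the MAC
#' cell by convention and is excluded from the total; every later node k
#' counts \code{units(k-1) * fanOut(stage k)}. The total sums nodes 1..K.
#'
#' @param net a \linkS4class{NetworkSpec}.
#' @return data.frame with per-node \code{units} and \code{macs}, plus
#'   attribute \code{"total"} (also in the last row of the report from
#'   \code{\link{complexityReport}}).
#' @export
countAnnMacs <- function(net) {
  nd <- .accountingNodes(net)
  macs <- numeric(nrow(nd))
  macs[1] <- nd$units[1]
  if (nrow(nd) > 1)
    for (k in 2:nrow(nd)) macs[k] <- nd$units[k - 1] * nd$fanOut[k]
  nd$macs <- macs
  attr(nd, "total") <- sum(macs[-1])
  nd
}

#' Measured SNN activity per accounting node
#'
#' Events(node k) is the mean spike count per sample at that node, taken
#' from forward-pass traces; synops(node k) = events(k-1) * fanOut(stage k)
#' for k >= 1 (node 0 has no upstream synapses and reports NA).
#'
#' @param net a \linkS4class{NetworkSpec}.
#' @param traces list of traces from \code{\link{forwardPass}} (the
#'   \code{trace} element), one per sample.
#' @return data.frame with per-node \code{events} and \code{synops}, plus
#'   attributes \code{"totalEvents"} and \code{"totalSynops"}.
#' @export
countSnnActivity <- function(net, traces) {
  if (!length(traces)) stop("need at least one forward trace")
  nd <- .accountingNodes(net)
  counts <- vapply(traces, function(tr) tr$spikeCounts[nd$layerIndex],
                   numeric(nrow(nd)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = nrow(nd))
  nd$events <- rowMeans(counts)
  syn <- rep(NA_real_, nrow(nd))
  if (nrow(nd) > 1)
    for (k in 2:nrow(nd)) syn[k] <- nd$events[k - 1] * nd$fanOut[k]
  nd$synops <- syn
  attr(nd, "totalEvents") <- sum(nd$events)
  attr(nd, "totalSynops") <- sum(syn[-1])
  nd
}

#' Build a full complexity report
#'
#' @param net a \linkS4class{NetworkSpec}.
#' @param traces optional list of forward traces; without them the event
#'   and synop columns are NA.
#' @return A \linkS4class{ComplexityReport}.
#' @export
complexityReport <- function(net, traces = NULL) {
  ann <- countAnnMacs(net)
  nodes <- ann[c("node", "stage", "shapeW", "shapeH", "shapeC", "units",
                 "macs")]
  totals <- c(units = sum(ann$units), macs = attr(ann, "total"),
              events = NA_real_, synops = NA_real_)
  nodes$events <- NA_real_
  nodes$synops <- NA_real_
  if (!is.null(traces) && length(traces)) {
    snn <- countSnnActivity(net, traces)
    nodes$events <- snn$events
    nodes$synops <- snn$synops
    totals["events"] <- attr(snn, "totalEvents")
    totals["synops"] <- attr(snn, "totalSynops")
  }
  new("ComplexityReport", nodes = nodes, totals = totals)
}

#' Sparsity ratios of a complexity report
#'
#' Event sparsity = total ANN activations / total SNN events; synapse
#' sparsity = total ANN MACs / total synops. Reported rounded to 2
#' decimals.
#'
#' @param report a \linkS4class{ComplexityReport} with measured activity,
#'   or a named numeric with \code{units}, \code{macs}, \code{events},
#'   \code{synops}.
#' @return named numeric \code{c(eventSparsity, synapseSparsity)}.
#' @export
sparsityRatios <- function(report) {
  tot <- if (is(report, "ComplexityReport")) report@totals else report
  if (!all(c("units", "macs", "events", "synops") %in% names(tot)))
    stop("need totals units, macs, events, synops")
  if (is.na(tot["events"]) || is.na(tot["synops"]) ||
      tot["events"] == 0 || tot["synops"] == 0)
    stop("event/synop totals absent or zero")
  c(eventSparsity = round(unname(tot["units"] / tot["events"]), 2),
    synapseSparsity = round(unname(tot["macs"] / tot["synops"]), 2))
}

#' Energy parameters for the operation-count estimate
#'
#' Defaults are a common 45 nm convention (0.9 pJ per accumulate, 4.6 pJ
#' per multiply-accumulate); they are configuration values, not measured
#' claims.
#'
#' @slot eAc energy per accumulate operation (J).
#' @slot eMac energy per multiply-accumulate (J).
#' @slot T simulation bins.
#' @slot fr average firing rate in [0, 1].
#' @exportClass EnergyParams
setClass("EnergyParams",
  representation(eAc = "numeric", eMac = "numeric", T = "numeric",
                 fr = "numeric"))

setValidity("EnergyParams", function(object) {
  if (object@eAc <= 0 || object@eMac <= 0) return("energies must be positive")
  if (object@fr < 0 || object@fr > 1) return("fr must be in [0, 1]")
  if (object@T < 1) return("T must be >= 1")
  TRUE
})

#' @rdname EnergyParams-class
#' @param eAc,eMac per-operation energies in joules.
#' @param T simulation bins.
#' @param fr average firing rate.
#' @export
energyParams <- function(eAc = 0.9e-12, eMac = 4.6e-12, T = 33, fr = 0.01) {
  new("EnergyParams", eAc = eAc, eMac = eMac, T = T, fr = fr)
}

#' Energy estimate from operation counts
#'
#' \deqn{E(F) = T (f_r E_{AC} O_{AC} + E_{MAC} O_{MAC})}
#'
#' @param oAc accumulate-operation count.
#' @param oMac multiply-accumulate count.
#' @param params an \linkS4class{EnergyParams}.
#' @return energy in joules.
#' @export
energyEstimate <- function(oAc, oMac, params = energyParams()) {
  stopifnot(oAc >= 0, oMac >= 0, is(params, "EnergyParams"))
  params@T * (params@fr * params@eAc * oAc + params@eMac * oMac)
}
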