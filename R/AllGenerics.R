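#' Build the pseudo-first-order generator matrix
#'
#' @param model a [CycleModel-class]
#' @param cond a [Conditions-class]
#' @return square generator matrix (per second); columns sum to zero
#' @export
setGeneric("rateMatrix", function(model, cond) standardGeneric("rateMatrix"))

#' Steady-state occupancy of a cycle model
#'
#' @param model a [CycleModel-class]
#' @param cond a [Conditions-class]
#' @return named occupancy vector (non-negative, sums to 1)
#' @export
setGeneric("steadyState", function(model, cond) standardGeneric("steadyState"))

#' State labels of a model
#' @param object a [CycleModel-class]
#' @export
setGeneric("modelStates", function(object) standardGeneric("modelStates"))

#' Transition table of a model
#' @param object a [CycleModel-class]
#' @export
setGeneric("modelTransitions",
           function(object) standardGeneric("modelTransitions"))

#' Per-state anion-conductance weights (bound row already scaled)
#' @param object a [CycleModel-class]
#' @export
setGeneric("conductingWeights",
           function(object) standardGeneric("conductingWeights"))

#' Inhibitor-coupling parameters (kOn, kOff, KU, alpha, conductanceScale)
#' @param object a [CycleModel-class]
#' @export
setGeneric("inhibitorCoupling",
           function(object) standardGeneric("inhibitorCoupling"))

#' Sample times of a trace or trajectory
#' @param object a [CurrentTrace-class] (ms) or
#'   [OccupancyTrajectory-class] (s)
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))

#' Current values of a trace
#' @param object a [CurrentTrace-class]
#' @export
setGeneric("traceCurrent", function(object) standardGeneric("traceCurrent"))

#' Occupancy matrix of a trajectory
#' @param object an [OccupancyTrajectory-class]
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))
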