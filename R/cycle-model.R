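#' Create a Conditions object
#'
#' @param sOut,sIn external/internal substrate concentration (uM)
#' @param naOut,naIn external/internal Na+ concentration (mM)
#' @param iConc allosteric inhibitor concentration (uM)
#' @param voltage membrane voltage (mV)
#' @return a [Conditions-class]
#' @examples
#' conditions(sOut = 1000, iConc = 100, voltage = 0)
#' @export
conditions <- function(sOut = 0, sIn = 0, naOut = 140, naIn = 10,
                       iConc = 0, voltage = 0) {
  new("Conditions", sOut = sOut, sIn = sIn, naOut = naOut, naIn = naIn,
      iConc = iConc, voltage = voltage)
}

.condVector <- function(cond) {
  c(sOut = cond@sOut, sIn = cond@sIn, naOut = cond@naOut,
    naIn = cond@naIn, iConc = cond@iConc, voltage = cond@voltage)
}

.condFromVector <- function(v) {
  new("Conditions", sOut = v[["sOut"]], sIn = v[["sIn"]],
      naOut = v[["naOut"]], naIn = v[["naIn"]], iConc = v[["iConc"]],
      voltage = v[["voltage"]])
}

#' Construct a CycleModel directly
#'
#' Low-level constructor used for small test models and by [buildCycle()].
#' For the standard two-row transport cycle use [buildCycle()].
#'
#' @param states character vector of state labels
#' @param transitions data.frame with columns from, to, kf, kr, ligand,
#'   zDelta, type
#' @param kOn,kOff inhibitor association/dissociation rate constants
#' @param alpha translocation-activity factor of bound states, in \[0, 1\]
#' @param conductanceScale anion-conductance scale of bound states
#'   (defaults to \code{alpha})
#' @param conductingWeights named numeric vector of per-state weights
#' @param mirrored logical, TRUE for the two-row topology
#' @return a validated [CycleModel-class]
#' @export
cycleModel <- function(states, transitions, kOn = 1, kOff = 1, alpha = 0,
                       conductanceScale = alpha,
                       conductingWeights = numeric(), mirrored = FALSE) {
  transitions$ligand <- as.character(transitions$ligand)
  transitions$type <- as.character(transitions$type)
  new("CycleModel", states = states, transitions = transitions,
      kOn = kOn, kOff = kOff, alpha = alpha,
      conductanceScale = conductanceScale,
      conductingWeights = conductingWeights, mirrored = mirrored)
}

.requireParam <- function(x, field, where) {
  if (is.null(x[[field]]))
    stop("missing model parameter '", field, "' in ", where, call. = FALSE)
  x[[field]]
}

#' Build the two-row transport-cycle model
#'
#' Constructs the alternating-access transport cycle with a mirror row of
#' allosteric-inhibitor-bound states. Every inhibitor-free transition gets a
#' mirrored counterpart in the bound row; translocation-type transitions
#' (transport-domain movements) in the bound row are scaled by the
#' translocation-activity factor \code{alpha} in both directions, all other
#' rates are unchanged. Every state is connected to its mirror by an
#' inhibitor binding/unbinding transition (association rate
#' \code{k_on * [I]}, dissociation rate \code{k_off}).
#'
#' @param params parameter list with elements \code{states} (6 labels,
#'   outward apo through inward apo), \code{transitions} (list of lists with
#'   fields from, to, k0_forward, k0_reverse, ligand, z_delta, type),
#'   \code{inhibitor} (k_on, k_off, alpha, optional conductance_scale) and
#'   \code{conducting_weights} (named). See [defaultModelParams()] for the
#'   shipped calibrated sets.
#' @return a validated [CycleModel-class] with 12 states
#' @examples
#' m <- buildCycle(defaultModelParams("asct2_wt"))
#' length(modelStates(m))
#' @export
buildCycle <- function(params) {
  states <- .requireParam(params, "states", "model parameters")
  inhib <- .requireParam(params, "inhibitor", "model parameters")
  trSpec <- .requireParam(params, "transitions", "model parameters")
  weights <- .requireParam(params, "conducting_weights", "model parameters")

  kOn <- .requireParam(inhib, "k_on", "inhibitor block")
  kOff <- .requireParam(inhib, "k_off", "inhibitor block")
  alpha <- .requireParam(inhib, "alpha", "inhibitor block")
  gamma <- if (is.null(inhib$conductance_scale)) alpha else
    inhib$conductance_scale
  if (is.na(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be in [0, 1], got ", alpha, call. = FALSE)
  if (kOn <= 0 || kOff <= 0)
    stop("inhibitor k_on and k_off must be > 0", call. = FALSE)

  rows <- lapply(seq_along(trSpec), function(i) {
    t <- trSpec[[i]]
    for (f in c("from", "to", "k0_forward", "k0_reverse", "ligand",
                "z_delta", "type"))
      .requireParam(t, f, paste0("transition ", i))
    if (t$k0_forward <= 0 || t$k0_reverse <= 0)
      stop("rate constants of transition ", i, " (", t$from, " -> ", t$to,
           ") must be strictly positive", call. = FALSE)
    data.frame(from = t$from, to = t$to, kf = t$k0_forward,
               kr = t$k0_reverse, ligand = t$ligand, zDelta = t$z_delta,
               type = t$type, stringsAsFactors = FALSE)
  })
  free <- do.call(rbind, rows)
  if (!all(free$from %in% states) || !all(free$to %in% states))
    stop("transition references unknown state", call. = FALSE)

  ## mirror row: same rates, translocation-type steps scaled by alpha
  bound <- free
  bound$from <- paste0(free$from, ".U")
  bound$to <- paste0(free$to, ".U")
  scale <- ifelse(free$type == "translocation", alpha, 1)
  bound$kf <- free$kf * scale
  bound$kr <- free$kr * scale

  binding <- data.frame(
    from = states, to = paste0(states, ".U"),
    kf = kOn, kr = kOff, ligand = "I", zDelta = 0,
    type = "inhibitor", stringsAsFactors = FALSE)

  w <- unlist(weights)
  allStates <- c(states, paste0(states, ".U"))
  wFull <- setNames(numeric(length(allStates)), allStates)
  wFull[names(w)] <- w
  wFull[paste0(names(w), ".U")] <- w * gamma

  cycleModel(states = allStates,
             transitions = rbind(free, bound, binding),
             kOn = kOn, kOff = kOff, alpha = alpha,
             conductanceScale = gamma, conductingWeights = wFull,
             mirrored = TRUE)
}

#' Read a kinetic parameter file
#'
#' Model calibration constants live in versioned YAML files with sections
#' \code{states}, \code{transitions}, \code{inhibitor} and
#' \code{conducting_weights}.
#'
#' @param path YAML file path
#' @return parameter list suitable for [buildCycle()]
#' @export
readModelParams <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  yaml::read_yaml(path)
}

#' Shipped calibrated parameter sets
#'
#' @param name one of "eaat1", "asct2_wt", "asct2_dm", "asct2_f136y"
#' @return parameter list suitable for [buildCycle()]
#' @export
defaultModelParams <- function(name = c("eaat1", "asct2_wt", "asct2_dm",
                                        "asct2_f136y")) {
  name <- match.arg(name)
  path <- system.file("params", paste0(name, ".yaml"), package = "slc1kin",
                      mustWork = TRUE)
  readModelParams(path)
}

## ---------------------------------------------------------------------------
## Rate matrix

## Effective edge rates under given concentrations/voltage.
## Forward rates of ligand-tagged edges are multiplied by the matching
## concentration; electrogenic rates carry a symmetric Eyring voltage split:
## kf * exp(-z u / 2), kr * exp(+z u / 2) with u = F V / RT.
.edgeRates <- function(tr, condVec) {
  concOf <- c(none = 1, S_out = condVec[["sOut"]], S_in = condVec[["sIn"]],
              Na_out = condVec[["naOut"]], Na_in = condVec[["naIn"]],
              I = condVec[["iConc"]])
  u <- .FoRT_mV * condVec[["voltage"]]
  vf <- exp(-tr$zDelta * u / 2)
  list(kf = tr$kf * concOf[tr$ligand] * vf, kr = tr$kr / vf)
}

.buildGenerator <- function(model, condVec) {
  st <- model@states
  n <- length(st)
  tr <- model@transitions
  from <- match(tr$from, st)
  to <- match(tr$to, st)
  rates <- .edgeRates(tr, condVec)
  Q <- matrix(0, n, n, dimnames = list(st, st))
  for (e in seq_len(nrow(tr))) {
    Q[to[e], from[e]] <- Q[to[e], from[e]] + rates$kf[e]
    Q[from[e], to[e]] <- Q[from[e], to[e]] + rates$kr[e]
  }
  diag(Q) <- diag(Q) - colSums(Q)
  Q
}

#' @describeIn rateMatrix generator for a model under given conditions
#' @export
setMethod("rateMatrix", signature("CycleModel", "Conditions"),
  function(model, cond) {
    validObject(model); validObject(cond)
    .buildGenerator(model, .condVector(cond))
  })

## ---------------------------------------------------------------------------
## Steady state

## Communicating-class analysis of the generator: returns the indices of the
## unique closed class, errors if several closed classes coexist.
.closedClass <- function(Q) {
  A <- Q; diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(t(A) > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  closed <- vapply(seq_len(comp$no), function(cl) {
    inside <- which(memb == cl)
    !any(A[-inside, inside, drop = FALSE] > 0)
  }, TRUE)
  if (sum(closed) > 1L) {
    labs <- vapply(which(closed), function(cl)
      paste(rownames(Q)[memb == cl], collapse = ","), "")
    stop("reducible state graph with ", sum(closed),
         " disconnected closed components: {",
         paste(labs, collapse = "} {"), "}", call. = FALSE)
  }
  which(memb == which(closed))
}

#' @describeIn steadyState null-space solve on the closed communicating
#'   class; states unreachable under the given conditions get occupancy 0
#' @export
setMethod("steadyState", signature("CycleModel", "Conditions"),
  function(model, cond) {
    Q <- rateMatrix(model, cond)
    st <- model@states
    cl <- .closedClass(Q)
    Qc <- Q[cl, cl, drop = FALSE]
    scale <- max(abs(Qc))
    if (scale == 0) stop("degenerate generator: all rates zero")
    n <- length(cl)
    ## Qp = 0 with 1'p = 1 is equivalent to (Q + 11')p = 1, which is
    ## nonsingular for an irreducible generator; fall back to the SVD null
    ## space when the rate scales span too many orders of magnitude
    sol <- tryCatch(
      solve(Qc / scale + matrix(1, n, n), rep(1, n)),
      error = function(e) {
        v <- svd(Qc / scale)$v[, n]
        v / sum(v)
      })
    sol[sol < 0 & sol > -1e-10] <- 0
    if (any(sol < 0)) stop("steady-state solve produced negative occupancy")
    p <- setNames(numeric(length(st)), st)
    p[cl] <- sol / sum(sol)
    p
  })

## ---------------------------------------------------------------------------
## Time integration

## Normalize a schedule argument to list(durations_ms, conds = matrix).
.scheduleMatrix <- function(schedule) {
  if (is(schedule, "ExchangeProtocol")) {
    durations <- schedule@durations
    condList <- schedule@segmentConditions
  } else {
    durations <- vapply(schedule, function(s) s$duration_ms, 0)
    condList <- lapply(schedule, function(s) s$conditions)
  }
  conds <- do.call(rbind, lapply(condList, .condVector))
  list(durations = durations, conds = conds)
}

#' Integrate the master equation over a piecewise-constant schedule
#'
#' Propagates the occupancy vector through a timeline of conditions using a
#' stiff ODE solver (lsoda), one constant generator per segment. Probability
#' is conserved at every sample; under constant conditions the long-time
#' limit equals [steadyState()].
#'
#' @param model a [CycleModel-class]
#' @param schedule an [ExchangeProtocol-class] (mixingTau ignored here; see
#'   [runExchange()]) or a list of \code{list(duration_ms=, conditions=)}
#'   segments
#' @param p0 initial occupancy (sums to 1); defaults to the steady state of
#'   the first segment's conditions
#' @param dt output sampling interval (ms)
#' @return an [OccupancyTrajectory-class]
#' @export
integrateOccupancy <- function(model, schedule, p0 = NULL, dt = 0.1) {
  sm <- .scheduleMatrix(schedule)
  st <- model@states
  if (is.null(p0))
    p0 <- steadyState(model, .condFromVector(sm$conds[1, ]))
  if (abs(sum(p0) - 1) > 1e-6) stop("p0 must sum to 1")
  p0 <- setNames(as.numeric(p0), st)

  dtS <- dt / 1000
  bounds <- cumsum(c(0, sm$durations)) / 1000
  total <- bounds[length(bounds)]
  outT <- seq(0, total, by = dtS)

  occ <- matrix(NA_real_, length(outT), length(st),
                dimnames = list(NULL, st))
  condOut <- matrix(NA_real_, length(outT), 6,
                    dimnames = list(NULL, colnames(sm$conds)))
  occ[1, ] <- p0
  condOut[1, ] <- sm$conds[1, ]
  p <- p0
  for (seg in seq_along(sm$durations)) {
    t0 <- bounds[seg]; t1 <- bounds[seg + 1]
    sel <- which(outT > t0 + 1e-12 & outT <= t1 + 1e-12)
    locT <- unique(c(0, outT[sel] - t0, t1 - t0))
    Q <- .buildGenerator(model, sm$conds[seg, ])
    sol <- tryCatch(
      deSolve::lsoda(y = p, times = locT,
                     func = function(t, y, parms) list(parms %*% y),
                     parms = Q, rtol = 1e-10, atol = 1e-12),
      warning = function(w) stop("stiff-solver failure in segment ", seg,
                                 ": ", conditionMessage(w), call. = FALSE))
    if (length(sel)) {
      ## map output times onto solver rows (times were passed verbatim)
      rows <- match(round((outT[sel] - t0) * 1e9), round(sol[, 1] * 1e9))
      occ[sel, ] <- sol[rows, -1, drop = FALSE]
      condOut[sel, ] <- matrix(sm$conds[seg, ], length(sel), 6, byrow = TRUE)
    }
    p <- setNames(sol[nrow(sol), -1], st)
    p <- p / sum(p)
  }
  occ[occ < 0 & occ > -1e-9] <- 0
  occ <- occ / rowSums(occ)
  new("OccupancyTrajectory", times = outT, occupancy = occ,
      conditions = condOut)
}

## ---------------------------------------------------------------------------
## Observables

#' Anion current from a state-occupancy trajectory
#'
#' The uncoupled anion-channel current is modeled as proportional to the
#' conductance-weighted state occupancy,
#' \eqn{I(t) = -g \sum_s w_s p_s(t)} (inward negative, normalized units,
#' g = 1). Inhibitor-bound conducting states carry the weights already
#' scaled by \code{conductanceScale}.
#'
#' @param traj an [OccupancyTrajectory-class]
#' @param model the [CycleModel-class] that produced it
#' @return a [CurrentTrace-class] (times in ms)
#' @export
anionCurrent <- function(traj, model) {
  w <- setNames(numeric(length(model@states)), model@states)
  cw <- model@conductingWeights
  w[names(cw)] <- cw
  i <- -as.numeric(traj@occupancy %*% w)
  new("CurrentTrace", times = traj@times * 1000, current = i)
}

#' Transport (coupled) current from a state-occupancy trajectory
#'
#' The electrogenic transport current is the charge-weighted sum of net
#' transition fluxes,
#' \eqn{I(t) = \sum_e z_e (k_f^e(t) p_{from}(t) - k_r^e(t) p_{to}(t))}
#' in normalized units. For an electroneutral homo-exchange steady state the
#' time average is zero.
#'
#' @param traj an [OccupancyTrajectory-class]
#' @param model the [CycleModel-class] that produced it
#' @return a [CurrentTrace-class] (times in ms)
#' @export
transportCurrent <- function(traj, model) {
  tr <- model@transitions
  st <- model@states
  from <- match(tr$from, st)
  to <- match(tr$to, st)
  nT <- length(traj@times)
  i <- numeric(nT)
  cm <- traj@conditions
  concCols <- c(none = NA, S_out = "sOut", S_in = "sIn", Na_out = "naOut",
                Na_in = "naIn", I = "iConc")
  u <- .FoRT_mV * cm[, "voltage"]
  for (e in seq_len(nrow(tr))) {
    z <- tr$zDelta[e]
    if (z == 0) next
    conc <- if (tr$ligand[e] == "none") 1 else cm[, concCols[[tr$ligand[e]]]]
    vf <- exp(-z * u / 2)
    flux <- tr$kf[e] * conc * vf * traj@occupancy[, from[e]] -
      tr$kr[e] / vf * traj@occupancy[, to[e]]
    i <- i + z * flux
  }
  ## net positive charge moving inward is an inward (negative) current
  new("CurrentTrace", times = traj@times * 1000, current = -i)
}

#' Net steady-state cycle flux through the translocation step
#'
#' @param model a [CycleModel-class]
#' @param cond a [Conditions-class]
#' @return net forward flux (per second, summed over free and bound rows)
#' @export
cycleFlux <- function(model, cond) {
  p <- steadyState(model, cond)
  tr <- model@transitions
  rates <- .edgeRates(tr, .condVector(cond))
  ## at steady state the net flux around the single loop is equal through
  ## the loaded-translocation and the empty-relocation steps; summing both
  ## (over both rows) counts the turnover twice
  sel <- which(tr$type == "translocation")
  sum(rates$kf[sel] * p[tr$from[sel]] - rates$kr[sel] * p[tr$to[sel]]) / 2
}

## ---------------------------------------------------------------------------
## Accessors and show

#' @describeIn CycleModel state labels
#' @param object a CycleModel
#' @export
setMethod("modelStates", "CycleModel", function(object) object@states)

#' @describeIn CycleModel transition table
#' @export
setMethod("modelTransitions", "CycleModel",
          function(object) object@transitions)

#' @describeIn CycleModel per-state anion-conductance weights
#' @export
setMethod("conductingWeights", "CycleModel", function(object) {
  w <- setNames(numeric(length(object@states)), object@states)
  w[names(object@conductingWeights)] <- object@conductingWeights
  w
})

#' @describeIn CycleModel inhibitor-coupling parameters
#' @export
setMethod("inhibitorCoupling", "CycleModel", function(object) {
  c(kOn = object@kOn, kOff = object@kOff, KU = object@kOff / object@kOn,
    alpha = object@alpha, conductanceScale = object@conductanceScale)
})

setMethod("show", "CycleModel", function(object) {
  cat("CycleModel with", length(object@states), "states,",
      nrow(object@transitions), "transitions\n")
  if (object@mirrored) {
    ic <- inhibitorCoupling(object)
    cat(sprintf("  inhibitor: k_on %.4g /s/uM, k_off %.4g /s (K_U %.4g uM)\n",
                ic["kOn"], ic["kOff"], ic["KU"]))
    cat(sprintf("  alpha %.3g, bound-state conductance scale %.3g\n",
                object@alpha, object@conductanceScale))
  }
  invisible(object)
})

#' @describeIn OccupancyTrajectory sample times (seconds)
#' @param object an OccupancyTrajectory
#' @export
setMethod("sampleTimes", "OccupancyTrajectory", function(object) object@times)

#' @describeIn OccupancyTrajectory occupancy matrix
#' @export
setMethod("occupancy", "OccupancyTrajectory", function(object)
  object@occupancy)

setMethod("show", "OccupancyTrajectory", function(object) {
  cat("OccupancyTrajectory:", length(object@times), "samples x",
      ncol(object@occupancy), "states, t in [0,",
      round(max(object@times), 4), "] s\n")
  invisible(object)
})

#' @describeIn CurrentTrace sample times (ms)
#' @param object a CurrentTrace
#' @export
setMethod("sampleTimes", "CurrentTrace", function(object) object@times)

#' @describeIn CurrentTrace current values (normalized)
#' @export
setMethod("traceCurrent", "CurrentTrace", function(object) object@current)

setMethod("show", "CurrentTrace", function(object) {
  cat(sprintf("CurrentTrace: %d samples, %.4g ms, range [%.4g, %.4g]\n",
              length(object@times), diff(range(object@times)),
              min(object@current), max(object@current)))
  if (nrow(object@annotations))
    cat("  events:", paste(object@annotations$label, collapse = ", "), "\n")
  invisible(object)
})
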