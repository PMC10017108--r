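#' @import methods
#' @importFrom stats coef fitted lm median resid rnorm sd setNames vcov
NULL

## Ligand tags a transition's forward (binding-direction) rate may carry.
.LIGANDS <- c("none", "S_out", "S_in", "Na_out", "Na_in", "I")

## Faraday/(R*T) at 22 degrees C, per millivolt.
.FoRT_mV <- 96485.33212 / (8.31446262 * 295.15) / 1000

#' Experimental conditions at an instant
#'
#' Holds the external/internal substrate and sodium concentrations, the
#' allosteric inhibitor concentration and the membrane voltage that together
#' determine the pseudo-first-order rate matrix of a [CycleModel].
#'
#' Units follow electrophysiological convention: substrate and inhibitor in
#' micromolar, sodium in millimolar, voltage in millivolts.
#'
#' @slot sOut,sIn external/internal substrate concentration (uM)
#' @slot naOut,naIn external/internal Na+ concentration (mM)
#' @slot iConc allosteric inhibitor concentration (uM)
#' @slot voltage membrane voltage (mV)
#' @seealso [conditions()]
#' @export
setClass("Conditions",
  representation(sOut = "numeric", sIn = "numeric",
                 naOut = "numeric", naIn = "numeric",
                 iConc = "numeric", voltage = "numeric"),
  prototype(sOut = 0, sIn = 0, naOut = 140, naIn = 10, iConc = 0,
            voltage = 0))

setValidity("Conditions", function(object) {
  conc <- c(object@sOut, object@sIn, object@naOut, object@naIn, object@iConc)
  if (length(conc) != 5L || any(is.na(conc)) || any(conc < 0))
    return("all concentrations must be single non-negative numbers")
  if (length(object@voltage) != 1L || !is.finite(object@voltage))
    return("voltage must be a single finite number (mV)")
  TRUE
})

#' Alternating-access transport-cycle model with allosteric inhibitor states
#'
#' A kinetic state model for an SLC1 transporter. States are arranged in two
#' rows: an inhibitor-free row and a mirror inhibitor-bound row; every free
#' state is connected to its mirror by an inhibitor binding/unbinding
#' transition. Translocation-type transitions in the bound row are scaled by
#' the translocation-activity factor \code{alpha} (0 = full block of
#' transport-domain movement, 1 = no effect), while ligand binding steps are
#' unaffected. Anion-conductance weights of bound states are scaled by
#' \code{conductanceScale}.
#'
#' Transitions are stored as a data.frame with columns \code{from},
#' \code{to}, \code{kf}, \code{kr}, \code{ligand}, \code{zDelta},
#' \code{type}. Ligand-tagged forward rates are per second per unit
#' concentration (uM for substrate/inhibitor, mM for Na+); all other rates
#' are per second. \code{zDelta} is the apparent charge moved in the forward
#' direction (elementary charges), split symmetrically between forward and
#' reverse rates (Eyring convention).
#'
#' Small non-mirrored models can be constructed directly with
#' [cycleModel()] for testing and for reduced analyses; the full two-row
#' topology is built and checked by [buildCycle()].
#'
#' @slot states character vector of unique state labels
#' @slot transitions data.frame of transitions (see Details)
#' @slot kOn,kOff inhibitor association (per s per uM) / dissociation (per s)
#' @slot alpha translocation-activity factor of inhibitor-bound states, in
#'   \[0, 1\]
#' @slot conductanceScale anion-conductance scale of inhibitor-bound states,
#'   in \[0, 1\]
#' @slot conductingWeights named numeric, per-state anion-conductance weight
#' @slot mirrored logical; TRUE when built as the two-row topology
#' @export
setClass("CycleModel",
  representation(states = "character", transitions = "data.frame",
                 kOn = "numeric", kOff = "numeric", alpha = "numeric",
                 conductanceScale = "numeric",
                 conductingWeights = "numeric", mirrored = "logical"),
  prototype(kOn = 1, kOff = 1, alpha = 0, conductanceScale = 0,
            mirrored = FALSE))

setValidity("CycleModel", function(object) {
  st <- object@states
  if (anyDuplicated(st)) return("state labels must be unique")
  tr <- object@transitions
  need <- c("from", "to", "kf", "kr", "ligand", "zDelta", "type")
  if (!all(need %in% names(tr)))
    return(paste("transitions must have columns:", paste(need, collapse = ", ")))
  if (!all(tr$from %in% st) || !all(tr$to %in% st))
    return("every transition must reference existing states")
  ## intrinsic rate constants must be > 0 (checked in buildCycle); stored
  ## bound-row translocation rates may be exactly 0 when alpha = 0
  if (any(!is.finite(tr$kf)) || any(!is.finite(tr$kr)) ||
      any(tr$kf < 0) || any(tr$kr < 0))
    return("rate constants must be non-negative and finite")
  if (any(!is.finite(tr$zDelta)))
    return("zDelta values must be finite")
  if (!all(tr$ligand %in% .LIGANDS))
    return(paste("unknown ligand tag; allowed:", paste(.LIGANDS, collapse = ", ")))
  if (length(object@alpha) != 1L || is.na(object@alpha) ||
      object@alpha < 0 || object@alpha > 1)
    return("alpha must be a single value in [0, 1]")
  if (object@kOn <= 0 || object@kOff <= 0)
    return("inhibitor kOn and kOff must be > 0")
  w <- object@conductingWeights
  if (length(w) && (is.null(names(w)) || !all(names(w) %in% st)))
    return("conductingWeights must be named by state label")
  if (any(!is.finite(w)) || any(w < 0))
    return("conductingWeights must be finite and non-negative")
  if (object@mirrored) {
    n <- length(st)
    if (n %% 2L != 0L) return("mirrored model needs an even state count")
    half <- n / 2L
    if (!identical(st[(half + 1L):n], paste0(st[seq_len(half)], ".U")))
      return("bound-row labels must mirror the free row with suffix '.U'")
  }
  TRUE
})

#' Time course of state occupancies
#'
#' Result of [integrateOccupancy()] or [runExchange()]: per-time probability
#' vectors over the model states, together with the effective conditions
#' (concentrations after solution-exchange filtering, voltage) at each
#' sample, which are needed to convert occupancies into transition fluxes.
#'
#' @slot times sample times (seconds), strictly increasing
#' @slot occupancy matrix, one row per time, one column per state
#' @slot conditions matrix with columns sOut, sIn, naOut, naIn, iConc,
#'   voltage giving the effective conditions at each sample
#' @export
setClass("OccupancyTrajectory",
  representation(times = "numeric", occupancy = "matrix",
                 conditions = "matrix"))

setValidity("OccupancyTrajectory", function(object) {
  if (is.unsorted(object@times, strictly = TRUE))
    return("times must be strictly increasing")
  if (nrow(object@occupancy) != length(object@times))
    return("occupancy must have one row per time point")
  s <- rowSums(object@occupancy)
  if (any(abs(s - 1) > 1e-6))
    return("occupancy rows must sum to 1")
  if (min(object@occupancy) < -1e-8)
    return("occupancies must be non-negative")
  TRUE
})

#' Sampled current trace
#'
#' A uniformly sampled current time series in normalized units (inward
#' currents negative), with protocol annotations (solution-exchange or
#' voltage-jump event times).
#'
#' @slot times sample times (ms), uniform and strictly increasing
#' @slot current normalized current
#' @slot annotations data.frame with columns \code{time_ms}, \code{label}
#' @export
setClass("CurrentTrace",
  representation(times = "numeric", current = "numeric",
                 annotations = "data.frame"),
  prototype(annotations = data.frame(time_ms = numeric(), label = character())))

setValidity("CurrentTrace", function(object) {
  if (length(object@times) != length(object@current))
    return("times and current must have equal length")
  if (length(object@times) > 1L) {
    dt <- diff(object@times)
    if (any(dt <= 0)) return("times must be strictly increasing")
    if (diff(range(dt)) > 1e-6 * stats::median(dt))
      return("sampling must be uniform")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Protocols

#' Rapid solution-exchange protocol
#'
#' A piecewise timeline of conditions applied to the cell, with a
#' single-exponential solution-exchange (mixing) time constant describing
#' how fast concentrations at the membrane reach each segment's target.
#'
#' @slot durations segment durations (ms), all > 0
#' @slot segmentConditions list of [Conditions-class], one per segment
#' @slot mixingTau solution-exchange time constant (ms), >= 0
#' @export
setClass("ExchangeProtocol",
  representation(durations = "numeric", segmentConditions = "list",
                 mixingTau = "numeric"),
  prototype(mixingTau = 3))

setValidity("ExchangeProtocol", function(object) {
  if (length(object@durations) == 0L) return("protocol must have segments")
  if (any(object@durations <= 0)) return("durations must be > 0")
  if (length(object@durations) != length(object@segmentConditions))
    return("one Conditions object per segment required")
  if (!all(vapply(object@segmentConditions, is, TRUE, class2 = "Conditions")))
    return("segmentConditions must all be Conditions objects")
  if (object@mixingTau < 0) return("mixingTau must be >= 0")
  TRUE
})

#' Paired-pulse recovery protocol
#'
#' Two identical substrate applications separated by a variable inter-pulse
#' interval; the fractional recovery of the second peak versus interval
#' reports the transporter turnover/relaxation time.
#'
#' @slot pulseConditions conditions during the pulses
#' @slot restConditions conditions between and around the pulses
#' @slot pulseDuration pulse length (ms)
#' @slot intervals inter-pulse intervals (ms), >= 2 values, strictly
#'   increasing
#' @slot mixingTau solution-exchange time constant (ms)
#' @export
setClass("PairedPulseProtocol",
  representation(pulseConditions = "Conditions", restConditions = "Conditions",
                 pulseDuration = "numeric", intervals = "numeric",
                 mixingTau = "numeric"),
  prototype(pulseDuration = 100, mixingTau = 0))

setValidity("PairedPulseProtocol", function(object) {
  iv <- object@intervals
  if (length(iv) < 2L) return("need at least 2 inter-pulse intervals")
  if (any(iv <= 0) || is.unsorted(iv, strictly = TRUE))
    return("intervals must be positive and strictly increasing")
  if (object@pulseDuration <= 0) return("pulseDuration must be > 0")
  TRUE
})

#' Voltage-jump protocol with blocker subtraction
#'
#' Steps the membrane voltage from a holding potential to each test
#' potential and integrates the transporter-specific transient charge after
#' subtracting a reference trace in which the transporter's mobile charge is
#' immobilized by a bound competitive blocker.
#'
#' @slot holdingV holding potential (mV)
#' @slot stepVs test potentials (mV), non-empty
#' @slot stepDuration step length (ms), > 0
#' @slot baselineConditions conditions of the test recording
#' @slot blockerConditions conditions of the blocker recording
#' @export
setClass("VoltageJumpProtocol",
  representation(holdingV = "numeric", stepVs = "numeric",
                 stepDuration = "numeric",
                 baselineConditions = "Conditions",
                 blockerConditions = "Conditions"),
  prototype(holdingV = 0, stepDuration = 50))

setValidity("VoltageJumpProtocol", function(object) {
  if (length(object@stepVs) == 0L) return("stepVs must be non-empty")
  if (object@stepDuration <= 0) return("stepDuration must be > 0")
  TRUE
})

## ---------------------------------------------------------------------------
## Fit results

#' Partial-inhibition dose-response fit
#'
#' Parameters of the dose-response model
#' \deqn{I([U]) = I_1 - I_2 \frac{[U]}{K_i + [U]}}
#' where \eqn{I_1} is the uninhibited current, \eqn{I_2} the maximal
#' inhibitable current (\eqn{I_2 < I_1} indicates partial inhibition) and
#' \eqn{K_i} the apparent inhibition constant.
#'
#' @slot I1,I2 current amplitudes (normalized)
#' @slot Ki apparent inhibition constant (uM)
#' @slot residualFraction (I1 - I2)/I1, the activity remaining at
#'   saturating inhibitor
#' @slot se named standard errors (I1, I2, Ki)
#' @slot partial TRUE when the saturating residual exceeds twice its SE
#' @slot status "ok" or "no-fit"
#' @export
setClass("DoseResponseFit",
  representation(I1 = "numeric", I2 = "numeric", Ki = "numeric",
                 residualFraction = "numeric", se = "numeric",
                 partial = "logical", status = "character"),
  prototype(status = "ok"))

#' Michaelis-Menten substrate-activation fit
#'
#' @slot Km apparent Michaelis constant (uM)
#' @slot Imax saturating current (normalized)
#' @slot se named standard errors
#' @slot nonSaturating TRUE when the largest tested concentration is below
#'   the Km estimate (warning flag)
#' @export
setClass("MMFit",
  representation(Km = "numeric", Imax = "numeric", se = "numeric",
                 nonSaturating = "logical"))

#' Biexponential transient fit
#'
#' Fit of \eqn{I(t) = I_1 e^{-t/\tau_{rise}} + I_2 e^{-t/\tau_{decay}} + c}.
#' When the second amplitude is insignificant (< 2 SE) the fit collapses to a
#' single exponential and only \code{tauDecay} is reported.
#'
#' @slot I1,I2 component amplitudes
#' @slot tauRise,tauDecay time constants (ms); tauRise is NA for
#'   single-exponential fits
#' @slot baseline additive offset
#' @slot rss residual sum of squares
#' @slot se named standard errors
#' @slot status "ok", "single-exp" or "no-fit"
#' @export
setClass("BiexpFit",
  representation(I1 = "numeric", I2 = "numeric", tauRise = "numeric",
                 tauDecay = "numeric", baseline = "numeric", rss = "numeric",
                 se = "numeric", status = "character"))

#' Inhibition-mechanism call from the Ki-versus-substrate pattern
#'
#' Classifies the inhibition mechanism from how the apparent Ki depends on
#' the substrate concentration: flat (non-competitive), linear with slope
#' Ki(0)/Km (competitive), or rising then saturating (mixed).
#'
#' @slot verdict one of "competitive", "non-competitive", "mixed"
#' @slot Ki0 Ki extrapolated to zero substrate (uM)
#' @slot slopeStat slope z-statistic of the Ki-vs-substrate regression
#' @slot residuals named relative residuals of the candidate models
#' @export
setClass("MechanismCall",
  representation(verdict = "character", Ki0 = "numeric",
                 slopeStat = "numeric", residuals = "numeric"))

#' Boltzmann fit of a charge-voltage relationship
#'
#' Fit of \eqn{Q(V) = Q_{max} / (1 + \exp(z_{app} F (V - V_{1/2}) / RT))}
#' (plus an optional additive offset for jump-referenced charge data).
#'
#' @slot Qmax total mobile charge (normalized)
#' @slot Vhalf midpoint potential (mV)
#' @slot zApp apparent valence (elementary charges)
#' @slot offset additive offset (0 unless requested)
#' @slot se named standard errors
#' @slot converged logical convergence flag
#' @slot saturatedWarning TRUE when the data cover only one side of the
#'   midpoint (wide-error warning)
#' @export
setClass("QVFit",
  representation(Qmax = "numeric", Vhalf = "numeric", zApp = "numeric",
                 offset = "numeric", se = "numeric", converged = "logical",
                 saturatedWarning = "logical"))

#' Paired-pulse recovery fit
#'
#' @slot data data.frame with columns interval_ms, peak1, peak2, ratio
#' @slot tau recovery time constant(s) (ms); one or two values
#' @slot amplitude fitted recovery amplitude(s)
#' @slot se standard errors of tau
#' @export
setClass("RecoveryFit",
  representation(data = "data.frame", tau = "numeric",
                 amplitude = "numeric", se = "numeric"))

## ---------------------------------------------------------------------------
## Synthetic data

#' Measurement-noise model for synthetic recordings
#'
#' @slot gaussianSd Gaussian noise standard deviation, as a fraction of the
#'   peak signal
#' @slot baselineOffset constant additive offset (normalized units)
#' @slot driftRate linear baseline drift (per second; traces only)
#' @slot seed integer RNG seed; identical seeds give identical datasets
#' @export
setClass("NoiseModel",
  representation(gaussianSd = "numeric", baselineOffset = "numeric",
                 driftRate = "numeric", seed = "numeric"),
  prototype(gaussianSd = 0.03, baselineOffset = 0, driftRate = 0, seed = 1))

setValidity("NoiseModel", function(object) {
  if (object@gaussianSd < 0) return("gaussianSd must be >= 0")
  if (object@seed != round(object@seed)) return("seed must be an integer")
  TRUE
})

#' Scenario preset with its complete generating truth
#'
#' Bundles a named experimental scenario: the kinetic-model parameter set it
#' simulates and the generating-truth record (dose-response, substrate
#' activation, recovery and Q-V parameters) used by the synthetic-data
#' generators and recoverable by the inference layer.
#'
#' @slot name preset name
#' @slot modelParams full kinetic parameter list (as read from the model
#'   YAML, overrides applied)
#' @slot truth named list of generating truths
#' @export
setClass("ScenarioPreset",
  representation(name = "character", modelParams = "list", truth = "list"))
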