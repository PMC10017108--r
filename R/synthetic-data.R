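## Seeded synthetic-data generators: every dataset shape the analysis layer
## consumes can be produced from a scenario preset plus a noise model, with
## the complete generating truth attached.

## Run fun() under a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, fun) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}

#' Create a measurement-noise model
#'
#' @param gaussianSd Gaussian noise SD as a fraction of the peak signal.
#'   The default of 3\% matches the visual quality of published whole-cell
#'   recordings.
#' @param baselineOffset constant additive offset
#' @param driftRate linear baseline drift (per second; applied to traces)
#' @param seed integer seed; identical seeds give identical datasets
#' @return a [NoiseModel-class]
#' @export
noiseModel <- function(gaussianSd = 0.03, baselineOffset = 0,
                       driftRate = 0, seed = 1) {
  new("NoiseModel", gaussianSd = gaussianSd, baselineOffset = baselineOffset,
      driftRate = driftRate, seed = seed)
}

.PRESETS <- list(
  eaat1_slow_inhibitor = list(
    model = "eaat1",
    truth = list(
      dose = list(I1 = 1, I2 = 1, Ki = 0.6),
      mm = list(Km = 20, Imax = 1),
      recovery = list(tauControlMs = 95, regime = "slow", KU = 0.6,
                      IApp = 0.2),
      decayTauMs = 11,
      qv = list(Qmax = 1, Vhalf = -30, zApp = 1, inhibitedQmaxScale = 0.5),
      pulse = list(sOut = 1000, sIn = 0, naOut = 140, naIn = 10))),
  asct2_wt_partial = list(
    model = "asct2_wt",
    truth = list(
      dose = list(I1 = 1, I2 = 0.45, Ki = 77),
      mm = list(Km = 280, Imax = 1),
      recovery = list(tauControlMs = 15, regime = "fast", KU = 77,
                      IApp = 100),
      qv = list(Qmax = 1, Vhalf = -30, zApp = 1, inhibitedQmaxScale = 0.5),
      pulse = list(sOut = 1000, sIn = 10000, naOut = 140, naIn = 130))),
  asct2_double_mutant = list(
    model = "asct2_dm",
    truth = list(
      dose = list(I1 = 1, I2 = 1, Ki = 4.3),
      mm = list(Km = 280, Imax = 1),
      recovery = list(tauControlMs = 15, regime = "fast", KU = 4.3,
                      IApp = 100),
      mechanism = list(kind = "mixed", Ki0 = 4.3, KiInf = 20, KmP = 300),
      qv = list(Qmax = 1, Vhalf = -30, zApp = 1, inhibitedQmaxScale = 0.5),
      pulse = list(sOut = 1000, sIn = 10000, naOut = 140, naIn = 130))),
  asct2_f136y = list(
    model = "asct2_f136y",
    truth = list(
      dose = list(I1 = 1, I2 = 1, Ki = 30),
      mm = list(Km = 790, Imax = 1),
      recovery = list(tauControlMs = 15, regime = "fast", KU = 30,
                      IApp = 100),
      pulse = list(sOut = 1000, sIn = 10000, naOut = 140, naIn = 130))),
  compound302_wt = list(
    model = "asct2_wt",
    modelOverrides = list(inhibitor = list(k_on = 8.4034, k_off = 2000,
                                           alpha = 0,
                                           conductance_scale = 0)),
    truth = list(
      dose = list(I1 = 1, I2 = 1, Ki = 238),
      mm = list(Km = 280, Imax = 1),
      recovery = list(tauControlMs = 19, regime = "fast", KU = 238,
                      IApp = 300),
      pulse = list(sOut = 1000, sIn = 10000, naOut = 140, naIn = 130))),
  compound302_double_mutant = list(
    model = "asct2_dm",
    modelOverrides = list(inhibitor = list(k_on = 22.222, k_off = 2000,
                                           alpha = 0,
                                           conductance_scale = 0)),
    truth = list(
      dose = list(I1 = 1, I2 = 1, Ki = 90),
      mm = list(Km = 280, Imax = 1),
      recovery = list(tauControlMs = 15, regime = "fast", KU = 90,
                      IApp = 300),
      pulse = list(sOut = 1000, sIn = 10000, naOut = 140, naIn = 130))))

#' Available scenario presets
#' @return character vector of preset names
#' @export
presetNames <- function() names(.PRESETS)

## Recursive list merge (overrides win).
.mergeLists <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .mergeLists(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Create a scenario preset
#'
#' A preset bundles a named experimental scenario — which transporter, which
#' inhibitor, slow or fast inhibitor equilibration, full or partial block —
#' with its kinetic parameter set and the complete generating-truth record
#' used by the synthetic-data generators.
#'
#' @param name one of [presetNames()], or "custom" (supply full
#'   \code{overrides})
#' @param overrides named list merged over the preset's model parameters
#'   (e.g. \code{list(inhibitor = list(alpha = 0.5))})
#' @param truthOverrides named list merged over the truth record
#' @return a [ScenarioPreset-class]
#' @examples
#' p <- scenarioPreset("asct2_wt_partial")
#' p@truth$dose$Ki
#' @export
scenarioPreset <- function(name, overrides = list(),
                           truthOverrides = list()) {
  if (name == "custom") {
    mp <- overrides
    truth <- truthOverrides
  } else {
    if (!name %in% names(.PRESETS))
      stop("unknown preset '", name, "'; see presetNames()")
    p <- .PRESETS[[name]]
    mp <- defaultModelParams(p$model)
    if (!is.null(p$modelOverrides)) mp <- .mergeLists(mp, p$modelOverrides)
    mp <- .mergeLists(mp, overrides)
    truth <- .mergeLists(p$truth, truthOverrides)
  }
  new("ScenarioPreset", name = name, modelParams = mp, truth = truth)
}

setMethod("show", "ScenarioPreset", function(object) {
  cat("ScenarioPreset '", object@name, "'\n", sep = "")
  d <- object@truth$dose
  if (!is.null(d))
    cat(sprintf("  dose truth: I1 %.3g, I2 %.3g, Ki %.4g uM\n",
                d$I1, d$I2, d$Ki))
  invisible(object)
})

.pulseConditions <- function(preset, iConc = 0, sOut = NULL) {
  p <- preset@truth$pulse
  conditions(sOut = if (is.null(sOut)) p$sOut else sOut, sIn = p$sIn,
             naOut = p$naOut, naIn = p$naIn, iConc = iConc)
}

#' Generate a synthetic inhibitor dose-response dataset
#'
#' In "analytic" mode currents are computed directly from the preset's
#' generating truth via the partial-inhibition dose-response model; in
#' "model" mode they are steady-state anion-current amplitudes of the
#' kinetic cycle model at each dose. Gaussian noise (fraction of peak) and
#' a baseline offset are then applied under the noise model's seed.
#'
#' @param preset a [ScenarioPreset-class]
#' @param doses inhibitor concentrations (uM), must include 0
#' @param noise a [NoiseModel-class]
#' @param mode "analytic" or "model"
#' @param sOut substrate concentration for model mode (uM); default 100
#' @return list with \code{data} (data.frame dose_uM, current),
#'   \code{truth} and \code{seed}
#' @export
genDoseResponse <- function(preset, doses, noise = noiseModel(0),
                            mode = c("analytic", "model"), sOut = 100) {
  mode <- match.arg(mode)
  if (!any(doses == 0)) stop("doses must include 0")
  tr <- preset@truth$dose
  if (mode == "analytic") {
    i <- tr$I1 - tr$I2 * doses / (tr$Ki + doses)
  } else {
    model <- buildCycle(preset@modelParams)
    i <- vapply(doses, function(d) {
      p <- steadyState(model, .pulseConditions(preset, iConc = d,
                                               sOut = sOut))
      abs(sum(conductingWeights(model) * p))
    }, 0)
  }
  i <- .withSeed(noise@seed, function()
    i + rnorm(length(i), 0, noise@gaussianSd * max(abs(i))) +
      noise@baselineOffset)
  list(data = data.frame(dose_uM = doses, current = i), truth = tr,
       seed = noise@seed, mode = mode)
}

#' Generate a synthetic substrate-activation dataset
#'
#' Hyperbolic (Michaelis-Menten) activation curve from the preset's
#' substrate truth ("analytic") or from steady-state anion currents of the
#' kinetic model ("model"), plus seeded noise.
#'
#' @param preset a [ScenarioPreset-class]
#' @param concs substrate concentrations (uM)
#' @param noise a [NoiseModel-class]
#' @param mode "analytic" or "model"
#' @return list with \code{data} (data.frame conc_uM, current),
#'   \code{truth} and \code{seed}
#' @export
genSubstrateActivation <- function(preset, concs, noise = noiseModel(0),
                                   mode = c("analytic", "model")) {
  mode <- match.arg(mode)
  tr <- preset@truth$mm
  if (mode == "analytic") {
    i <- tr$Imax * concs / (tr$Km + concs)
  } else {
    model <- buildCycle(preset@modelParams)
    i <- vapply(concs, function(s) {
      p <- steadyState(model, .pulseConditions(preset, sOut = s))
      abs(sum(conductingWeights(model) * p))
    }, 0)
  }
  i <- .withSeed(noise@seed, function()
    i + rnorm(length(i), 0, noise@gaussianSd * max(abs(i))) +
      noise@baselineOffset)
  list(data = data.frame(conc_uM = concs, current = i), truth = tr,
       seed = noise@seed, mode = mode)
}

#' Generate a synthetic paired-pulse recovery series
#'
#' Simulates the full paired-pulse protocol (control and inhibited) from
#' the preset's kinetic model, adds seeded trace noise, and attaches the
#' generating truth: the control recovery time constant and the inhibited
#' one implied by the preset's inhibitor-equilibration regime — scaled by
#' \eqn{([I] + K_U)/K_U} in the fast regime, unchanged in the slow regime.
#'
#' @param preset a [ScenarioPreset-class]
#' @param intervals inter-pulse intervals (ms)
#' @param noise a [NoiseModel-class]
#' @param iConc inhibitor concentration (uM); default: the preset's
#'   standard application concentration
#' @param observable "transport" or "anion"
#' @param dt sampling interval (ms)
#' @param pulseDuration pulse length (ms)
#' @return list with \code{traces} (control/inhibited lists of
#'   [CurrentTrace-class]), \code{truth} and \code{seed}
#' @export
genPairedPulse <- function(preset, intervals, noise = noiseModel(0),
                           iConc = NULL, observable = "transport",
                           dt = 0.2, pulseDuration = 100) {
  rec <- preset@truth$recovery
  if (is.null(iConc)) iConc <- rec$IApp
  model <- buildCycle(preset@modelParams)
  KU <- rec$KU
  ratio <- if (rec$regime == "fast") (iConc + KU) / KU else 1
  mkTraces <- function(ic) {
    lapply(intervals, function(iv) {
      prot <- exchangeProtocol(list(
        list(duration_ms = 50, conditions = .pulseConditions(preset, ic,
                                                             sOut = 0)),
        list(duration_ms = pulseDuration,
             conditions = .pulseConditions(preset, ic)),
        list(duration_ms = iv, conditions = .pulseConditions(preset, ic,
                                                             sOut = 0)),
        list(duration_ms = pulseDuration,
             conditions = .pulseConditions(preset, ic)),
        list(duration_ms = 50, conditions = .pulseConditions(preset, ic,
                                                             sOut = 0))),
        mixingTau = 0)
      runExchange(model, prot, observable = observable, dt = dt)
    })
  }
  control <- mkTraces(0)
  inhibited <- mkTraces(iConc)
  addNoise <- function(traces) lapply(traces, function(trc) {
    peak <- max(abs(trc@current))
    trc@current <- trc@current +
      rnorm(length(trc@current), 0, noise@gaussianSd * peak) +
      noise@baselineOffset + noise@driftRate * trc@times / 1000
    trc
  })
  out <- .withSeed(noise@seed, function()
    list(control = addNoise(control), inhibited = addNoise(inhibited)))
  list(traces = out,
       truth = list(tauControlMs = rec$tauControlMs,
                    tauInhibitedMs = rec$tauControlMs * ratio,
                    tauRatio = ratio, KU = KU, iConc = iConc,
                    regime = rec$regime),
       seed = noise@seed)
}

#' Generate a synthetic charge-voltage (Q-V) table
#'
#' "analytic" mode evaluates the Boltzmann truth directly (Qmax scaled down
#' under inhibition, midpoint unchanged); "model" mode integrates
#' voltage-jump charge movements of the kinetic model via
#' [voltageJumpCharge()]. Seeded noise is added as a fraction of the
#' largest |Q|.
#'
#' @param preset a [ScenarioPreset-class]
#' @param voltages test potentials (mV), at least 5
#' @param noise a [NoiseModel-class]
#' @param inhibited logical; apply the preset's inhibitor
#' @param mode "analytic" or "model"
#' @return list with \code{data} (data.frame V_mV, Q), \code{truth} and
#'   \code{seed}
#' @export
genQV <- function(preset, voltages, noise = noiseModel(0),
                  inhibited = FALSE, mode = c("analytic", "model")) {
  mode <- match.arg(mode)
  if (length(voltages) < 5) stop("need at least 5 voltages")
  tr <- preset@truth$qv
  if (is.null(tr)) stop("preset has no Q-V truth")
  qmax <- tr$Qmax * if (inhibited) tr$inhibitedQmaxScale else 1
  if (mode == "analytic") {
    q <- qmax / (1 + exp(tr$zApp * .FoRT_mV * (voltages - tr$Vhalf)))
  } else {
    model <- buildCycle(preset@modelParams)
    rec <- preset@truth$recovery
    cond <- .pulseConditions(preset,
                             iConc = if (inhibited) rec$IApp else 0,
                             sOut = 0)
    prot <- voltageJumpProtocol(holdingV = 0, stepVs = voltages,
                                stepDuration = 50,
                                baselineConditions = cond,
                                blockerConditions = cond)
    q <- voltageJumpCharge(model, prot)$Q
  }
  q <- .withSeed(noise@seed, function()
    q + rnorm(length(q), 0, noise@gaussianSd * max(abs(q))) +
      noise@baselineOffset)
  list(data = data.frame(V_mV = voltages, Q = q),
       truth = c(tr, list(QmaxEffective = qmax, inhibited = inhibited)),
       seed = noise@seed)
}
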