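#' Create a rapid solution-exchange protocol
#'
#' @param segments list of \code{list(duration_ms =, conditions =)} entries
#' @param mixingTau solution-exchange time constant (ms); concentrations at
#'   the membrane relax single-exponentially toward each segment's target.
#'   The default of 3 ms gives a 10--90\% rise of ~6.6 ms, inside the 5--10
#'   ms resolution of piezo-driven whole-cell solution exchange.
#' @return an [ExchangeProtocol-class]
#' @export
exchangeProtocol <- function(segments, mixingTau = 3) {
  new("ExchangeProtocol",
      durations = vapply(segments, function(s) s$duration_ms, 0),
      segmentConditions = lapply(segments, function(s) s$conditions),
      mixingTau = mixingTau)
}

#' Create a paired-pulse recovery protocol
#'
#' @param pulseConditions,restConditions [Conditions-class] during/between
#'   pulses
#' @param pulseDuration pulse length (ms)
#' @param intervals inter-pulse intervals (ms), strictly increasing
#' @param mixingTau solution-exchange time constant (ms)
#' @return a [PairedPulseProtocol-class]
#' @export
pairedPulseProtocol <- function(pulseConditions, restConditions,
                                pulseDuration = 100, intervals,
                                mixingTau = 0) {
  new("PairedPulseProtocol", pulseConditions = pulseConditions,
      restConditions = restConditions, pulseDuration = pulseDuration,
      intervals = intervals, mixingTau = mixingTau)
}

#' Create a voltage-jump protocol
#'
#' @param holdingV holding potential (mV)
#' @param stepVs test potentials (mV)
#' @param stepDuration step length (ms)
#' @param baselineConditions conditions of the test recording
#' @param blockerConditions conditions of the blocker reference recording
#' @return a [VoltageJumpProtocol-class]
#' @export
voltageJumpProtocol <- function(holdingV = 0,
                                stepVs = seq(-100, 60, by = 20),
                                stepDuration = 50,
                                baselineConditions = conditions(),
                                blockerConditions = baselineConditions) {
  new("VoltageJumpProtocol", holdingV = holdingV, stepVs = stepVs,
      stepDuration = stepDuration, baselineConditions = baselineConditions,
      blockerConditions = blockerConditions)
}

## ---------------------------------------------------------------------------

## Integrate with exponential solution mixing: concentrations relax toward
## each segment's target with time constant tauS; voltage switches
## instantly. Returns an OccupancyTrajectory whose conditions matrix holds
## the effective (filtered) concentrations.
.integrateMixing <- function(model, sm, p0, dt, tauMs) {
  st <- model@states
  tauS <- tauMs / 1000
  dtS <- dt / 1000
  bounds <- cumsum(c(0, sm$durations)) / 1000
  outT <- seq(0, bounds[length(bounds)], by = dtS)
  nC <- ncol(sm$conds)
  occ <- matrix(NA_real_, length(outT), length(st),
                dimnames = list(NULL, st))
  condOut <- matrix(NA_real_, length(outT), nC,
                    dimnames = list(NULL, colnames(sm$conds)))
  occ[1, ] <- p0
  condOut[1, ] <- sm$conds[1, ]
  p <- setNames(as.numeric(p0), st)
  cEff <- sm$conds[1, ]            # pre-equilibrated in segment-1 solution
  concIdx <- seq_len(5)            # sOut, sIn, naOut, naIn, iConc
  for (seg in seq_along(sm$durations)) {
    t0 <- bounds[seg]; t1 <- bounds[seg + 1]
    target <- sm$conds[seg, ]
    c0 <- cEff
    effAt <- function(tt) {
      v <- target
      v[concIdx] <- target[concIdx] +
        (c0[concIdx] - target[concIdx]) * exp(-tt / tauS)
      v
    }
    sel <- which(outT > t0 + 1e-12 & outT <= t1 + 1e-12)
    locT <- unique(c(0, outT[sel] - t0, t1 - t0))
    sol <- tryCatch(
      deSolve::lsoda(y = p, times = locT,
                     func = function(t, y, parms) {
                       list(.buildGenerator(model, effAt(t)) %*% y)
                     }, rtol = 1e-9, atol = 1e-11),
      warning = function(w) stop("stiff-solver failure in segment ", seg,
                                 ": ", conditionMessage(w), call. = FALSE))
    if (length(sel)) {
      rows <- match(round((outT[sel] - t0) * 1e9), round(sol[, 1] * 1e9))
      occ[sel, ] <- sol[rows, -1, drop = FALSE]
      condOut[sel, ] <- t(vapply(outT[sel] - t0, effAt, numeric(nC)))
    }
    p <- setNames(sol[nrow(sol), -1], st)
    p <- p / sum(p)
    cEff <- effAt(t1 - t0)
  }
  occ[occ < 0 & occ > -1e-9] <- 0
  occ <- occ / rowSums(occ)
  new("OccupancyTrajectory", times = outT, occupancy = occ,
      conditions = condOut)
}

#' Simulate a rapid solution-exchange recording
#'
#' Runs the cycle model through a piecewise solution timeline, applying the
#' protocol's exponential mixing filter to the concentrations before they
#' enter the rate matrix, and returns the requested current observable
#' annotated with segment boundaries. With \code{mixingTau = 0} the result
#' is identical to an instantaneous-jump [integrateOccupancy()] run.
#'
#' @param model a [CycleModel-class]
#' @param protocol an [ExchangeProtocol-class]
#' @param observable "anion" or "transport"
#' @param dt sampling interval (ms)
#' @param p0 initial occupancy; defaults to the steady state of the first
#'   segment
#' @param returnTrajectory if TRUE, return
#'   \code{list(trace =, trajectory =)} instead of the bare trace
#' @return a [CurrentTrace-class] (or a list, see \code{returnTrajectory})
#' @export
runExchange <- function(model, protocol, observable = c("anion", "transport"),
                        dt = 0.1, p0 = NULL, returnTrajectory = FALSE) {
  observable <- match.arg(observable)
  validObject(protocol)
  sm <- .scheduleMatrix(protocol)
  if (is.null(p0))
    p0 <- steadyState(model, .condFromVector(sm$conds[1, ]))
  traj <- if (protocol@mixingTau == 0)
    integrateOccupancy(model, protocol, p0 = p0, dt = dt)
  else .integrateMixing(model, sm, p0, dt, protocol@mixingTau)
  trace <- if (observable == "anion") anionCurrent(traj, model) else
    transportCurrent(traj, model)
  onsets <- cumsum(sm$durations)
  trace@annotations <- data.frame(
    time_ms = c(0, onsets[-length(onsets)]),
    label = paste0("segment", seq_along(sm$durations), ".onset"))
  if (returnTrajectory) list(trace = trace, trajectory = traj) else trace
}

## Peak amplitude after an onset: maximum |current - baseline| within the
## detection window, baseline taken just before the onset.
.peakAfter <- function(trace, onsetMs, windowMs) {
  t <- trace@times; i <- trace@current
  pre <- which(t <= onsetMs)
  base <- if (length(pre)) i[max(pre)] else i[1]
  win <- which(t >= onsetMs & t <= onsetMs + windowMs)
  max(abs(i[win] - base))
}

#' Fit a recovery curve
#'
#' Fits \eqn{r(\Delta) = 1 - \sum_k A_k e^{-\Delta/\tau_k}} (one or two
#' components) to paired-pulse recovery ratios.
#'
#' @param intervals inter-pulse intervals (ms)
#' @param ratios peak2/peak1 recovery ratios
#' @param components 1 or 2 exponential components
#' @return a [RecoveryFit-class]
#' @export
fitRecovery <- function(intervals, ratios, components = 1) {
  df <- data.frame(x = intervals, y = ratios)
  a0 <- max(min(1 - min(ratios), 1), 0.05)
  t0 <- intervals[which.min(abs(ratios - (1 - a0 / 2)))]
  if (!is.finite(t0) || t0 <= 0) t0 <- stats::median(intervals)
  if (components == 1) {
    fit <- minpack.lm::nlsLM(y ~ 1 - A * exp(-x / tau), data = df,
                             start = list(A = a0, tau = t0),
                             lower = c(0, 1e-3),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(fit)
    se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
      rep(NA_real_, 2))
    new("RecoveryFit",
        data = data.frame(interval_ms = intervals, ratio = ratios),
        tau = unname(cf["tau"]), amplitude = unname(cf["A"]),
        se = c(tau = unname(se[2])))
  } else {
    fit <- minpack.lm::nlsLM(
      y ~ 1 - A1 * exp(-x / tau1) - A2 * exp(-x / tau2), data = df,
      start = list(A1 = a0 / 2, tau1 = t0 / 3, A2 = a0 / 2, tau2 = t0 * 3),
      lower = c(0, 1e-3, 0, 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 400))
    cf <- coef(fit)
    ord <- order(c(cf["tau1"], cf["tau2"]))
    taus <- unname(c(cf["tau1"], cf["tau2"])[ord])
    amps <- unname(c(cf["A1"], cf["A2"])[ord])
    se <- tryCatch(sqrt(diag(vcov(fit)))[c(2, 4)][ord],
                   error = function(e) rep(NA_real_, 2))
    new("RecoveryFit",
        data = data.frame(interval_ms = intervals, ratio = ratios),
        tau = taus, amplitude = amps, se = setNames(se, c("tau1", "tau2")))
  }
}

#' Paired-pulse recovery analysis of a cycle model
#'
#' Simulates the paired-pulse protocol for every inter-pulse interval,
#' measures the fractional recovery of the second peak (peak amplitudes are
#' baseline-subtracted maxima of |current| within the detection window
#' after each pulse onset) and fits the recovery time constant(s).
#'
#' @param model a [CycleModel-class]
#' @param protocol a [PairedPulseProtocol-class]
#' @param observable "anion" or "transport"
#' @param dt sampling interval (ms)
#' @param window peak-detection window after pulse onset (ms)
#' @param preMs settling time before the first pulse (ms)
#' @param components exponential components of the recovery fit (1 or 2)
#' @param nonMonotoneTol tolerated non-monotonicity of the ratios before a
#'   warning is raised
#' @return a [RecoveryFit-class]; its \code{data} slot has one row per
#'   interval with peak1, peak2 and ratio
#' @export
pairedPulseRecovery <- function(model, protocol,
                                observable = c("transport", "anion"),
                                dt = 0.1, window = 50, preMs = 50,
                                components = 1, nonMonotoneTol = 0.02) {
  observable <- match.arg(observable)
  validObject(protocol)
  ## snap all segment boundaries to the sampling grid so both pulse onsets
  ## are sampled at the same phase of the fast rising transient; otherwise
  ## the peak ratio picks up a sampling-phase artifact
  snap <- function(x) pmax(round(x / dt) * dt, dt)
  pd <- snap(protocol@pulseDuration)
  preMs <- snap(preMs)
  intervals <- snap(protocol@intervals)
  res <- lapply(intervals, function(iv) {
    prot <- exchangeProtocol(list(
      list(duration_ms = preMs, conditions = protocol@restConditions),
      list(duration_ms = pd, conditions = protocol@pulseConditions),
      list(duration_ms = iv, conditions = protocol@restConditions),
      list(duration_ms = pd, conditions = protocol@pulseConditions),
      list(duration_ms = max(window, 20), conditions = protocol@restConditions)),
      mixingTau = protocol@mixingTau)
    trace <- runExchange(model, prot, observable = observable, dt = dt)
    w <- min(window, pd)
    p1 <- .peakAfter(trace, preMs, w)
    p2 <- .peakAfter(trace, preMs + pd + iv, w)
    c(peak1 = p1, peak2 = p2)
  })
  peaks <- do.call(rbind, res)
  ratio <- peaks[, "peak2"] / peaks[, "peak1"]
  if (any(diff(ratio) < -nonMonotoneTol))
    warning("recovery ratios are non-monotone beyond tolerance; ",
            "fit returned anyway")
  fit <- fitRecovery(intervals, ratio, components = components)
  fit@data <- data.frame(interval_ms = intervals,
                         peak1 = peaks[, "peak1"], peak2 = peaks[, "peak2"],
                         ratio = ratio)
  fit
}

## ---------------------------------------------------------------------------

## Composite-Simpson integral of a uniformly sampled signal (trapezoid on
## the last interval when the sample count is even).
.simpson <- function(y, dt) {
  n <- length(y)
  if (n < 3) return(sum((y[-1] + y[-n]) / 2) * dt)
  m <- if (n %% 2L == 1L) n else n - 1L
  idx <- seq_len(m)
  w <- rep(c(2, 4), length.out = m)
  w[1] <- 1; w[m] <- 1
  q <- sum(w * y[idx]) * dt / 3
  if (m < n) q <- q + (y[n - 1] + y[n]) / 2 * dt
  q
}

## Reference model for blocker subtraction: a bound competitive blocker
## immobilizes the transporter's charge, so all conformational and binding
## rates are scaled to ~0 (inhibitor association kept so the object stays
## valid; it moves no charge).
.blockerModel <- function(model, eps = 1e-9) {
  tr <- model@transitions
  sel <- tr$type != "inhibitor"
  tr$kf[sel] <- tr$kf[sel] * eps
  tr$kr[sel] <- tr$kr[sel] * eps
  out <- model
  out@transitions <- tr
  out
}

#' Voltage-jump charge movement (Q-V analysis)
#'
#' For each test potential, jumps the voltage from holding, integrates the
#' transporter transport current over the step and subtracts the same
#' integral from a blocker reference simulation in which the transporter's
#' mobile charge is immobilized. The resulting Q(V) reports the voltage
#' dependence of the electrogenic partial reactions (Na+ binding,
#' translocation) available at the given conditions.
#'
#' @param model a [CycleModel-class]
#' @param protocol a [VoltageJumpProtocol-class]
#' @param dt sampling interval (ms)
#' @return data.frame with columns \code{V_mV} and \code{Q} (normalized
#'   charge)
#' @export
voltageJumpCharge <- function(model, protocol, dt = 0.05) {
  validObject(protocol)
  blocker <- .blockerModel(model)
  holdTest <- protocol@baselineConditions
  holdTest@voltage <- protocol@holdingV
  holdBlk <- protocol@blockerConditions
  holdBlk@voltage <- protocol@holdingV
  p0 <- steadyState(model, holdTest)
  p0b <- steadyState(model, holdBlk)   # frozen at its pre-blocker state
  dtS <- dt / 1000
  settledWarned <- FALSE
  qs <- vapply(protocol@stepVs, function(v) {
    stepTest <- holdTest; stepTest@voltage <- v
    stepBlk <- holdBlk; stepBlk@voltage <- v
    sched <- list(list(duration_ms = protocol@stepDuration,
                       conditions = stepTest))
    trTest <- transportCurrent(
      integrateOccupancy(model, sched, p0 = p0, dt = dt), model)
    schedB <- list(list(duration_ms = protocol@stepDuration,
                        conditions = stepBlk))
    trBlk <- transportCurrent(
      integrateOccupancy(blocker, schedB, p0 = p0b, dt = dt), blocker)
    net <- trTest@current - trBlk@current
    tail5 <- mean(abs(utils::tail(net, max(3, length(net) %/% 20))))
    if (!settledWarned && max(abs(net)) > 0 &&
        tail5 > 0.01 * max(abs(net))) {
      warning("integration window may be shorter than 5x the transient ",
              "time constant")
      settledWarned <<- TRUE
    }
    .simpson(net, dtS)
  }, 0)
  data.frame(V_mV = protocol@stepVs, Q = qs)
}

setMethod("show", "RecoveryFit", function(object) {
  cat("RecoveryFit:", nrow(object@data), "intervals; tau =",
      paste(sprintf("%.3g ms", object@tau), collapse = ", "), "\n")
  invisible(object)
})
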