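## Nonlinear fitting layer: dose-response, substrate activation, mechanism
## classification, pre-equilibrium rate constants, biexponential transients
## and Boltzmann Q-V. All fits use trust-region least squares (nlsLM) with
## physical bounds and log-spaced multistarts on the scale parameters.

.relResid <- function(obs, pred) {
  sqrt(mean((obs - pred)^2)) / mean(abs(obs))
}

#' Fit a partial-inhibition dose-response curve
#'
#' Fits \eqn{I([U]) = I_1 - I_2 [U]/(K_i + [U])} by bounded least squares
#' with \eqn{0 \le I_2 \le I_1}. Partial inhibition is flagged when the
#' saturating residual current \eqn{I_1 - I_2} exceeds twice its standard
#' error. Flat data (no inhibition signal) give a "no-fit" result rather
#' than an error.
#'
#' @param doses inhibitor concentrations (uM), at least 4 values including 0
#' @param currents current amplitudes (normalized), same length
#' @param weights optional least-squares weights
#' @param bootstrap if TRUE, add a residual-resampling bootstrap SE for Ki
#' @param nboot bootstrap draws
#' @param bootSeed bootstrap RNG seed
#' @return a [DoseResponseFit-class]
#' @examples
#' d <- c(0, 5, 10, 25, 50, 100, 200, 500)
#' i <- 1 - 0.45 * d / (77 + d)
#' fitDoseResponse(d, i)@Ki
#' @export
fitDoseResponse <- function(doses, currents, weights = NULL,
                            bootstrap = FALSE, nboot = 500, bootSeed = 1) {
  if (length(doses) < 4) stop("need at least 4 dose points")
  if (!any(doses == 0)) stop("doses must include 0")
  if (length(doses) != length(currents))
    stop("doses and currents must have equal length")
  noFit <- function() new("DoseResponseFit", I1 = NA_real_, I2 = NA_real_,
                          Ki = NA_real_, residualFraction = NA_real_,
                          se = c(I1 = NA_real_, I2 = NA_real_,
                                 Ki = NA_real_),
                          partial = NA, status = "no-fit")
  span <- diff(range(currents))
  if (!is.finite(span) || span < 1e-3 * max(abs(currents))) return(noFit())

  df <- data.frame(d = doses, y = currents)
  if (is.null(weights)) weights <- rep(1, nrow(df))
  i1Start <- mean(currents[doses == 0])
  fStart <- min(max((i1Start - min(currents)) / i1Start, 0.05), 1)
  posDoses <- sort(unique(doses[doses > 0]))
  kiStarts <- exp(seq(log(min(posDoses)), log(max(posDoses)),
                      length.out = 5))
  fits <- lapply(kiStarts, function(k0) {
    tryCatch(
      minpack.lm::nlsLM(y ~ I1 - (f * I1) * d / (Ki + d), data = df,
                        weights = weights,
                        start = list(I1 = i1Start, f = fStart, Ki = k0),
                        lower = c(1e-12, 0, 1e-9), upper = c(Inf, 1, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) return(noFit())
  rss <- vapply(fits, function(f) sum(resid(f)^2), 0)
  fit <- fits[[which.min(rss)]]
  cf <- coef(fit)
  I1 <- unname(cf["I1"]); f <- unname(cf["f"]); Ki <- unname(cf["Ki"])
  I2 <- I1 * f
  V <- tryCatch(vcov(fit), error = function(e)
    matrix(NA_real_, 3, 3, dimnames = list(names(cf), names(cf))))
  ## delta method for I2 = f*I1 and the residual I1 - I2 = I1*(1 - f)
  gI2 <- c(f, I1, 0)
  gRes <- c(1 - f, -I1, 0)
  seI2 <- sqrt(drop(t(gI2) %*% V %*% gI2))
  seRes <- sqrt(drop(t(gRes) %*% V %*% gRes))
  se <- c(I1 = sqrt(V[1, 1]), I2 = unname(seI2), Ki = sqrt(V[3, 3]))
  if (bootstrap) {
    res <- resid(fit); pred <- fitted(fit)
    kis <- .withSeed(bootSeed, function() {
      vapply(seq_len(nboot), function(b) {
        yb <- pred + sample(res, replace = TRUE)
        fb <- tryCatch(
          minpack.lm::nlsLM(yb ~ I1 - (f * I1) * d / (Ki + d),
                            data = transform(df, yb = yb),
                            start = as.list(cf),
                            lower = c(1e-12, 0, 1e-9),
                            upper = c(Inf, 1, Inf)),
          error = function(e) NULL)
        if (is.null(fb)) NA_real_ else unname(coef(fb)["Ki"])
      }, 0)
    })
    se <- c(se, Ki.boot = stats::sd(kis, na.rm = TRUE))
  }
  residual <- I1 - I2
  new("DoseResponseFit", I1 = I1, I2 = I2, Ki = Ki,
      residualFraction = residual / I1, se = se,
      partial = is.finite(seRes) && residual > 2 * seRes, status = "ok")
}

#' Fit Michaelis-Menten substrate activation
#'
#' Fits \eqn{I([S]) = I_{max} [S]/(K_m + [S])} with positivity bounds. A
#' warning flag is set when the largest tested concentration is below the
#' Km estimate (non-saturating data).
#'
#' @param concs substrate concentrations (uM), at least 4 values
#' @param currents current amplitudes, same length
#' @return an [MMFit-class]
#' @export
fitMM <- function(concs, currents) {
  if (length(concs) < 4) stop("need at least 4 substrate points")
  df <- data.frame(s = concs, y = currents)
  imax0 <- max(currents)
  km0 <- concs[which.min(abs(currents - imax0 / 2))]
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(concs[concs > 0])
  kmStarts <- km0 * c(0.1, 0.5, 1, 2, 10)
  fits <- lapply(kmStarts, function(k0) {
    tryCatch(minpack.lm::nlsLM(y ~ Imax * s / (Km + s), data = df,
                               start = list(Imax = imax0, Km = k0),
                               lower = c(1e-12, 1e-9),
                               control = minpack.lm::nls.lm.control(maxiter = 300)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("substrate-activation fit failed")
  rss <- vapply(fits, function(f) sum(resid(f)^2), 0)
  fit <- fits[[which.min(rss)]]
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    c(Imax = NA_real_, Km = NA_real_))
  nonSat <- max(concs) < cf[["Km"]]
  if (nonSat) warning("data do not saturate: max concentration below Km")
  new("MMFit", Km = cf[["Km"]], Imax = cf[["Imax"]],
      se = c(Imax = unname(se[1]), Km = unname(se[2])),
      nonSaturating = nonSat)
}

#' Classify the inhibition mechanism from the Ki-versus-substrate pattern
#'
#' Tests how the apparent inhibition constant depends on the substrate
#' concentration. A competitive inhibitor follows
#' \eqn{K_i(S) = K_i(0) (1 + [S]/K_m)}; a non-competitive inhibitor shows a
#' substrate-independent Ki; a mixed inhibitor (apo-state preferring) shows
#' a Ki that rises at low substrate and saturates, modeled here as
#' \eqn{K_i(S) = K_i^\infty - (K_i^\infty - K_i(0)) K_m'/(K_m' + [S])}.
#'
#' Decision rule: the constant model is accepted (non-competitive) when the
#' slope z-statistic of Ki versus \[S\] is within 2 SE of zero; otherwise
#' the fixed-slope competitive line is accepted when its relative residual
#' is below half the constant model's; otherwise the saturating model is
#' accepted (mixed) when its relative residual is below half the constant
#' model's; if nothing fits decisively better than a constant the verdict
#' falls back to non-competitive.
#'
#' @param S substrate concentrations (uM), at least 3 levels
#' @param Ki fitted apparent Ki at each level (uM)
#' @param Km apparent Michaelis constant of the substrate (uM)
#' @return a [MechanismCall-class]
#' @export
kiVsSubstrate <- function(S, Ki, Km) {
  if (length(S) < 3) stop("need Ki at >= 3 substrate levels")
  if (length(S) != length(Ki)) stop("S and Ki must have equal length")

  rel0 <- .relResid(Ki, mean(Ki))
  ## noiseless inputs make lm()'s summary complain about a perfect fit
  sl <- suppressWarnings(summary(lm(Ki ~ S))$coefficients)
  slopeStat <- if (nrow(sl) > 1 && sl[2, 2] > 0) sl[2, 1] / sl[2, 2] else 0

  x <- 1 + S / Km                       # competitive line, slope Ki0/Km
  ki0Line <- sum(x * Ki) / sum(x^2)
  rel1 <- .relResid(Ki, ki0Line * x)

  satFit <- tryCatch(
    minpack.lm::nlsLM(
      Ki ~ KiInf - (KiInf - Ki0) * KmP / (KmP + S),
      data = data.frame(S = S, Ki = Ki),
      start = list(Ki0 = max(min(Ki), 1e-6), KiInf = max(Ki),
                   KmP = stats::median(S)),
      lower = c(1e-9, 1e-9, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  rel2 <- if (is.null(satFit)) Inf else .relResid(Ki, fitted(satFit))

  if (abs(slopeStat) < 2) {
    verdict <- "non-competitive"; ki0 <- mean(Ki)
  } else if (rel1 < 0.5 * rel0) {
    verdict <- "competitive"; ki0 <- ki0Line
  } else if (rel2 < 0.5 * rel0 && !is.null(satFit)) {
    verdict <- "mixed"; ki0 <- unname(coef(satFit)["Ki0"])
  } else {
    verdict <- "non-competitive"; ki0 <- mean(Ki)
  }
  new("MechanismCall", verdict = verdict, Ki0 = ki0,
      slopeStat = unname(slopeStat),
      residuals = c(constant = rel0, line = rel1, saturating = rel2))
}

#' Pre-equilibrium relaxation rate of the translocation equilibrium
#'
#' Under rapid-equilibrium substrate binding and fast inhibitor
#' equilibration, the observed rate constant for the rise or decay of the
#' substrate-induced current is
#' \deqn{k_{obs} = k_f \frac{[S]_o}{[S]_o + K_m} \frac{K_i}{[I] + K_i}
#'              + k_r \frac{[S]_i}{[S]_i + K_m} \frac{K_i}{[I] + K_i}}
#' After rapid substrate removal \eqn{[S]_o = 0} and the reverse
#' translocation rate constant is isolated. Infinite substrate
#' concentrations are treated as the exact saturating limit (factor 1).
#'
#' @param kf,kr forward/reverse translocation rate constants (per s)
#' @param S_out,S_in external/internal substrate concentrations (uM); may
#'   be \code{Inf} for the saturating limit
#' @param Km apparent Michaelis constant (uM)
#' @param I_conc inhibitor concentration (uM)
#' @param Ki apparent inhibition constant (uM); must be > 0
#' @return list with \code{kobs} (per s) and \code{tauMs} (= 1000/kobs)
#' @examples
#' kobsPreEquilibrium(kf = 100, kr = 1000 / 15, S_out = 0, S_in = Inf,
#'                    Km = 280, I_conc = 100, Ki = 100)$tauMs   # 30 ms
#' @export
kobsPreEquilibrium <- function(kf, kr, S_out, S_in, Km, I_conc, Ki) {
  if (Ki <= 0) stop("Ki must be > 0")
  if (kf <= 0 || kr <= 0 || Km <= 0) stop("rates and Km must be > 0")
  if (S_out < 0 || S_in < 0 || I_conc < 0)
    stop("concentrations must be >= 0")
  sat <- function(s) if (is.infinite(s)) 1 else s / (s + Km)
  fI <- Ki / (I_conc + Ki)
  kobs <- kf * sat(S_out) * fI + kr * sat(S_in) * fI
  list(kobs = kobs, tauMs = 1000 / kobs)
}

#' Fit a biexponential transient
#'
#' Fits \eqn{I(t) = I_1 e^{-t/\tau_{rise}} + I_2 e^{-t/\tau_{decay}} + c}
#' (components ordered by time constant, \eqn{\tau_{rise} < \tau_{decay}})
#' with log-spaced multistarts. If the faster component's amplitude is
#' insignificant (below 2 SE, or numerically negligible), the fit collapses
#' to a single exponential and reports \code{tauDecay} only.
#'
#' @param trace a [CurrentTrace-class], or a list/data.frame with elements
#'   \code{times} (ms) and \code{current}
#' @param window \code{c(t0, t1)} fit window (ms) inside the trace; time is
#'   re-zeroed to \code{t0}. Default: the full trace.
#' @return a [BiexpFit-class]
#' @export
fitBiexponential <- function(trace, window = NULL) {
  if (is(trace, "CurrentTrace")) {
    t <- trace@times; y <- trace@current
  } else {
    t <- trace$times; y <- trace$current
  }
  if (!is.null(window)) {
    sel <- t >= window[1] & t <= window[2]
    if (!any(sel)) stop("fit window outside trace")
    t <- t[sel]; y <- y[sel]
  }
  if (length(t) < 20) stop("need at least 20 samples in the fit window")
  t <- t - t[1]
  span <- max(t)
  scl <- max(abs(y - mean(y)))
  noFit <- function() new("BiexpFit", I1 = NA_real_, I2 = NA_real_,
                          tauRise = NA_real_, tauDecay = NA_real_,
                          baseline = NA_real_, rss = NA_real_,
                          se = numeric(), status = "no-fit")
  if (scl == 0) return(noFit())

  c0 <- mean(utils::tail(y, max(3, length(y) %/% 10)))
  a0 <- y[1] - c0
  df <- data.frame(t = t, y = y)
  singleFit <- function(tau0) tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-t / tau) + C, data = df,
                      start = list(A = a0, tau = tau0, C = c0),
                      lower = c(-Inf, span * 1e-5, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  tau0s <- exp(seq(log(span / 100), log(span), length.out = 5))
  sfits <- Filter(Negate(is.null), lapply(tau0s, singleFit))
  sfit <- if (length(sfits))
    sfits[[which.min(vapply(sfits, function(f) sum(resid(f)^2), 0))]]
  else NULL

  tauS <- if (!is.null(sfit)) coef(sfit)[["tau"]] else span / 5
  biFit <- function(r) tryCatch(
    minpack.lm::nlsLM(
      y ~ A1 * exp(-t / tau1) + A2 * exp(-t / tau2) + C, data = df,
      start = list(A1 = a0 / 2, tau1 = tauS / r, A2 = a0 / 2,
                   tau2 = tauS, C = c0),
      lower = c(-Inf, span * 1e-6, -Inf, span * 1e-6, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e) NULL)
  bfits <- Filter(Negate(is.null), lapply(c(2, 5, 10, 30, 100), biFit))
  if (!length(bfits)) {
    if (is.null(sfit)) return(noFit())
    cf <- coef(sfit)
    se <- tryCatch(sqrt(diag(vcov(sfit))), error = function(e) rep(NA, 3))
    return(new("BiexpFit", I1 = NA_real_, I2 = cf[["A"]],
               tauRise = NA_real_, tauDecay = cf[["tau"]],
               baseline = cf[["C"]], rss = sum(resid(sfit)^2),
               se = c(I2 = se[1], tauDecay = se[2]), status = "single-exp"))
  }
  bfit <- bfits[[which.min(vapply(bfits, function(f) sum(resid(f)^2), 0))]]
  cf <- coef(bfit)
  V <- tryCatch(vcov(bfit), error = function(e) matrix(NA, 5, 5))
  ord <- order(c(cf[["tau1"]], cf[["tau2"]]))
  taus <- c(cf[["tau1"]], cf[["tau2"]])[ord]
  amps <- c(cf[["A1"]], cf[["A2"]])[ord]
  ampSe <- sqrt(c(V[1, 1], V[3, 3]))[ord]
  tauSe <- sqrt(c(V[2, 2], V[4, 4]))[ord]

  ## collapse: faster component insignificant or amplitudes negligible, or
  ## the two time constants degenerate
  insignif <- function(a, s) abs(a) < 1e-7 * scl ||
    (is.finite(s) && abs(a) < 2 * s)
  degenerate <- abs(taus[2] - taus[1]) < 1e-3 * taus[2]
  if (!is.null(sfit) &&
      (insignif(amps[1], ampSe[1]) || insignif(amps[2], ampSe[2]) ||
       degenerate)) {
    cfs <- coef(sfit)
    ses <- tryCatch(sqrt(diag(vcov(sfit))), error = function(e) rep(NA, 3))
    return(new("BiexpFit", I1 = NA_real_, I2 = cfs[["A"]],
               tauRise = NA_real_, tauDecay = cfs[["tau"]],
               baseline = cfs[["C"]], rss = sum(resid(sfit)^2),
               se = c(I2 = ses[1], tauDecay = ses[2]),
               status = "single-exp"))
  }
  new("BiexpFit", I1 = amps[1], I2 = amps[2], tauRise = taus[1],
      tauDecay = taus[2], baseline = cf[["C"]], rss = sum(resid(bfit)^2),
      se = c(I1 = ampSe[1], tauRise = tauSe[1], I2 = ampSe[2],
             tauDecay = tauSe[2]), status = "ok")
}

#' Fit a Boltzmann charge-voltage relationship
#'
#' Fits \eqn{Q(V) = Q_{max}/(1 + \exp(z_{app} F (V - V_{1/2})/RT))} (with
#' an optional additive offset for jump-referenced charge data; F/RT at
#' 22 degrees C). A wide-error warning flag is set when the fitted midpoint
#' lies outside the measured voltage range (data saturated on one side).
#'
#' @param Vs membrane voltages (mV), at least 5 values
#' @param Qs measured charges (normalized)
#' @param offset if TRUE, fit an additive offset as well
#' @return a [QVFit-class]
#' @export
fitBoltzmannQV <- function(Vs, Qs, offset = FALSE) {
  if (length(Vs) < 5) stop("need at least 5 voltages")
  df <- data.frame(v = Vs, q = Qs)
  qr_ <- range(Qs)
  qmax0 <- diff(qr_)
  vh0 <- Vs[which.min(abs(Qs - mean(qr_)))]
  form <- if (offset)
    q ~ Qmax / (1 + exp(zApp * .FoRT_mV * (v - Vhalf))) + C
  else q ~ Qmax / (1 + exp(zApp * .FoRT_mV * (v - Vhalf)))
  tryFit <- function(z0, off0) {
    st <- list(Qmax = qmax0, Vhalf = vh0, zApp = z0)
    if (offset) st$C <- off0
    tryCatch(minpack.lm::nlsLM(form, data = df, start = st,
                               control = minpack.lm::nls.lm.control(maxiter = 400)),
             error = function(e) NULL)
  }
  starts <- expand.grid(z = c(-2, -1, -0.5, 0.5, 1, 2),
                        off = if (offset) c(0, min(Qs)) else 0)
  fits <- Filter(Negate(is.null),
                 mapply(tryFit, starts$z, starts$off, SIMPLIFY = FALSE))
  if (!length(fits))
    return(new("QVFit", Qmax = NA_real_, Vhalf = NA_real_, zApp = NA_real_,
               offset = NA_real_, se = numeric(), converged = FALSE,
               saturatedWarning = TRUE))
  fit <- fits[[which.min(vapply(fits, function(f) sum(resid(f)^2), 0))]]
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    rep(NA_real_, length(cf)))
  names(se) <- names(cf)
  satur <- cf[["Vhalf"]] < min(Vs) || cf[["Vhalf"]] > max(Vs)
  if (satur) warning("Q-V data saturated on one side of the midpoint; ",
                     "parameter errors may be wide")
  new("QVFit", Qmax = cf[["Qmax"]], Vhalf = cf[["Vhalf"]],
      zApp = cf[["zApp"]], offset = if (offset) cf[["C"]] else 0,
      se = se, converged = TRUE, saturatedWarning = satur)
}

## ---------------------------------------------------------------------------
## show methods

setMethod("show", "DoseResponseFit", function(object) {
  if (object@status != "ok") {
    cat("DoseResponseFit: <", object@status, ">\n"); return(invisible(object))
  }
  cat(sprintf(
    "DoseResponseFit: Ki = %.4g +/- %.2g uM; I1 = %.3g, I2 = %.3g (%s)\n",
    object@Ki, object@se[["Ki"]], object@I1, object@I2,
    if (isTRUE(object@partial)) "partial inhibition" else "full block"))
  invisible(object)
})

setMethod("show", "MMFit", function(object) {
  cat(sprintf("MMFit: Km = %.4g +/- %.2g uM, Imax = %.3g%s\n", object@Km,
              object@se[["Km"]], object@Imax,
              if (object@nonSaturating) " [non-saturating data]" else ""))
  invisible(object)
})

setMethod("show", "BiexpFit", function(object) {
  if (object@status == "no-fit") {
    cat("BiexpFit: <no-fit>\n"); return(invisible(object))
  }
  if (object@status == "single-exp")
    cat(sprintf("BiexpFit (single): tau = %.4g ms, A = %.3g\n",
                object@tauDecay, object@I2))
  else
    cat(sprintf(
      "BiexpFit: tau_rise = %.4g ms (A %.3g), tau_decay = %.4g ms (A %.3g)\n",
      object@tauRise, object@I1, object@tauDecay, object@I2))
  invisible(object)
})

setMethod("show", "MechanismCall", function(object) {
  cat(sprintf("MechanismCall: %s (Ki0 = %.4g uM, slope z = %.2f)\n",
              object@verdict, object@Ki0, object@slopeStat))
  invisible(object)
})

setMethod("show", "QVFit", function(object) {
  cat(sprintf("QVFit: Qmax = %.4g, Vhalf = %.4g mV, z_app = %.3g%s\n",
              object@Qmax, object@Vhalf, object@zApp,
              if (object@saturatedWarning) " [saturated]" else ""))
  invisible(object)
})
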