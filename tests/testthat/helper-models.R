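## Small hand-built models and protocol shorthands shared across tests.

## 3-state unimolecular ring (no ligands, no voltage)
toyRing3 <- function(kf = c(5, 2, 1), kr = c(3, 4, 2)) {
  cycleModel(
    states = c("A", "B", "C"),
    transitions = data.frame(
      from = c("A", "B", "C"), to = c("B", "C", "A"),
      kf = kf, kr = kr, ligand = "none", zDelta = 0,
      type = c("binding", "translocation", "binding"),
      stringsAsFactors = FALSE))
}

## 4-state ring with one ligand-dependent and one electrogenic step
toyRing4 <- function() {
  cycleModel(
    states = c("A", "B", "C", "D"),
    transitions = data.frame(
      from = c("A", "B", "C", "D"), to = c("B", "C", "D", "A"),
      kf = c(0.8, 30, 12, 4), kr = c(100, 9, 25, 2),
      ligand = c("S_out", "none", "none", "none"),
      zDelta = c(0, 0.5, 0, -0.3),
      type = c("binding", "translocation", "binding", "binding"),
      stringsAsFactors = FALSE),
    conductingWeights = c(B = 1, C = 0.4))
}

## detailed-balance 3-ring: product of forward rates equals product of
## reverse rates, so the V = 0, no-gradient steady state is a true
## equilibrium
toyDetailedBalance <- function() toyRing3(kf = c(2, 3, 4), kr = c(4, 2, 3))

## two-state voltage-dependent charge displacement (closed-form Boltzmann)
toyTwoStateVoltage <- function(k0 = 200, K0 = 1, z = 1) {
  cycleModel(
    states = c("Out", "In"),
    transitions = data.frame(
      from = "Out", to = "In", kf = k0, kr = k0 * K0, ligand = "none",
      zDelta = z, type = "binding", stringsAsFactors = FALSE))
}

eaat1Model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildCycle(defaultModelParams("eaat1"))
    cache
  }
})

asct2Model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildCycle(defaultModelParams("asct2_wt"))
    cache
  }
})

## homo-exchange conditions for ASCT2-style runs
exchangeRest <- function(iConc = 0)
  conditions(sOut = 0, sIn = 10000, naOut = 140, naIn = 130, iConc = iConc)
exchangePulse <- function(iConc = 0, sOut = 1000)
  conditions(sOut = sOut, sIn = 10000, naOut = 140, naIn = 130,
             iConc = iConc)

## forward-transport conditions for EAAT1-style runs
forwardRest <- function(iConc = 0)
  conditions(sOut = 0, sIn = 0, naOut = 140, naIn = 10, iConc = iConc)
forwardPulse <- function(iConc = 0, sOut = 1000)
  conditions(sOut = sOut, sIn = 0, naOut = 140, naIn = 10, iConc = iConc)

## independent dense-eigen steady-state oracle
eigenSteadyState <- function(Q) {
  ev <- eigen(Q)
  k <- which.min(abs(ev$values))
  v <- Re(ev$vectors[, k])
  v / sum(v)
}

## run fun() under a temporary seed without disturbing the session RNG
withSeed <- function(seed, fun) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fun()
}

## composite-Simpson integral for charge measurements in tests
simpsonInt <- function(y, dt) {
  n <- length(y)
  m <- if (n %% 2L == 1L) n else n - 1L
  w <- rep(c(2, 4), length.out = m)
  w[1] <- 1; w[m] <- 1
  q <- sum(w * y[seq_len(m)]) * dt / 3
  if (m < n) q <- q + (y[n - 1] + y[n]) / 2 * dt
  q
}

## independent matrix-exponential propagation oracle
expmPropagate <- function(Q, p0, times) {
  t(vapply(times, function(tt)
    as.numeric(Matrix::expm(Q * tt) %*% p0), numeric(length(p0))))
}
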