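test_that("buildCycle creates the two-row topology with inhibitor edges on every state", {
  params <- defaultModelParams("eaat1")
  m <- buildCycle(params)
  st <- modelStates(m)
  expect_length(st, 12L)
  free <- st[!grepl("\\.U$", st)]
  expect_identical(paste0(free, ".U"), st[7:12])

  ## every state participates in exactly one inhibitor binding transition
  tr <- modelTransitions(m)
  inh <- tr[tr$type == "inhibitor", ]
  expect_equal(nrow(inh), 6L)
  expect_setequal(c(inh$from, inh$to), st)
})

test_that("alpha scales only bound-row translocation rates", {
  params <- defaultModelParams("asct2_wt")

  params$inhibitor$alpha <- 1
  m1 <- buildCycle(params)
  tr <- modelTransitions(m1)
  freeT <- tr[tr$type == "translocation" & !grepl("\\.U$", tr$from), ]
  boundT <- tr[tr$type == "translocation" & grepl("\\.U$", tr$from), ]
  expect_equal(boundT$kf, freeT$kf)
  expect_equal(boundT$kr, freeT$kr)

  params$inhibitor$alpha <- 0
  m0 <- buildCycle(params)
  tr0 <- modelTransitions(m0)
  boundT0 <- tr0[tr0$type == "translocation" & grepl("\\.U$", tr0$from), ]
  expect_true(all(boundT0$kf == 0) && all(boundT0$kr == 0))
  ## binding steps of the bound row are untouched
  boundB0 <- tr0[tr0$type == "binding" & grepl("\\.U$", tr0$from), ]
  freeB0 <- tr0[tr0$type == "binding" & !grepl("\\.U$", tr0$from), ]
  expect_equal(boundB0$kf, freeB0$kf)
})

test_that("buildCycle reports missing parameters by name and rejects bad alpha", {
  params <- defaultModelParams("eaat1")
  p1 <- params; p1$inhibitor$k_off <- NULL
  expect_error(buildCycle(p1), "k_off")
  p2 <- params; p2$transitions[[3]]$z_delta <- NULL
  expect_error(buildCycle(p2), "z_delta")
  p3 <- params; p3$inhibitor$alpha <- 1.5
  expect_error(buildCycle(p3), "alpha")
})

test_that("rate matrix is a conservative generator across a randomized condition grid", {
  set.seed(42)
  m <- asct2Model()
  for (k in 1:20) {
    cond <- conditions(sOut = runif(1, 0, 2000), sIn = runif(1, 0, 20000),
                       naOut = runif(1, 1, 200), naIn = runif(1, 0, 150),
                       iConc = runif(1, 0, 500), voltage = runif(1, -120, 80))
    Q <- rateMatrix(m, cond)
    expect_lt(max(abs(colSums(Q))), 1e-10 * max(abs(Q)))
  }
})

test_that("voltage factors are unity at V = 0 and inhibitor entries scale with [I]", {
  m <- asct2Model()
  tr <- modelTransitions(m)
  cond0 <- conditions(sOut = 100, sIn = 1000, voltage = 0)
  Q0 <- rateMatrix(m, cond0)
  ## at V = 0 every off-diagonal entry equals its intrinsic (concentration-
  ## scaled) rate: check one electrogenic edge explicitly
  e <- which(tr$zDelta != 0 & tr$ligand == "none")[1]
  expect_equal(Q0[tr$to[e], tr$from[e]], tr$kf[e])

  c1 <- conditions(sOut = 100, iConc = 10)
  c2 <- conditions(sOut = 100, iConc = 20)
  Q1 <- rateMatrix(m, c1); Q2 <- rateMatrix(m, c2)
  D <- Q2 - Q1
  diag(D) <- 0
  inh <- tr[tr$type == "inhibitor", ]
  for (k in seq_len(nrow(inh)))
    expect_equal(Q2[inh$to[k], inh$from[k]],
                 2 * Q1[inh$to[k], inh$from[k]])
  ## no other off-diagonal entry changed
  for (k in seq_len(nrow(inh))) D[inh$to[k], inh$from[k]] <- 0
  expect_equal(max(abs(D)), 0)
})

test_that("steady state matches the dense eigen-decomposition oracle", {
  m <- toyRing4()
  cond <- conditions(sOut = 120, voltage = -40)
  p <- steadyState(m, cond)
  Q <- rateMatrix(m, cond)
  expect_lt(max(abs(Q %*% p)), 1e-9)
  pOracle <- eigenSteadyState(Q)
  expect_lt(max(abs(p - pOracle)), 1e-9)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("detailed-balance rates with no gradients and V = 0 give zero net edge flux", {
  m <- toyDetailedBalance()
  cond <- conditions()
  p <- steadyState(m, cond)
  tr <- modelTransitions(m)
  Q <- rateMatrix(m, cond)
  for (e in seq_len(nrow(tr))) {
    net <- Q[tr$to[e], tr$from[e]] * p[tr$from[e]] -
      Q[tr$from[e], tr$to[e]] * p[tr$to[e]]
    gross <- Q[tr$to[e], tr$from[e]] * p[tr$from[e]]
    expect_lt(abs(net), 1e-9 * gross)
  }
})

test_that("saturating full-block inhibitor abolishes steady-state cycle flux", {
  ## forward-transport model: genuine net turnover at zero inhibitor
  m <- eaat1Model()   # alpha = 0
  flux0 <- cycleFlux(m, forwardPulse(iConc = 0))
  fluxSat <- cycleFlux(m, forwardPulse(iConc = 1e7))
  expect_gt(abs(flux0), 1e-2)
  expect_lt(abs(fluxSat), 1e-6 * abs(flux0))
})

test_that("steady-state cycle flux is non-increasing in inhibitor concentration", {
  params <- defaultModelParams("eaat1")
  params$inhibitor$alpha <- 0.3   # partial translocation block
  m <- buildCycle(params)
  doses <- c(0, 10^seq(-2, 2, length.out = 7))
  flux <- vapply(doses, function(d)
    abs(cycleFlux(m, forwardPulse(iConc = d))), 0)
  expect_true(all(diff(flux) <= 1e-12))
})

test_that("disconnected closed classes raise an informative error", {
  m <- cycleModel(
    states = c("A", "B", "C", "D"),
    transitions = data.frame(
      from = c("A", "C"), to = c("B", "D"), kf = c(1, 2), kr = c(1, 2),
      ligand = "none", zDelta = 0, type = "binding",
      stringsAsFactors = FALSE))
  expect_error(steadyState(m, conditions()), "closed components")
})

test_that("states unreachable at zero ligand are pruned to occupancy zero", {
  ## with no inhibitor, the bound row is unreachable but still listed
  p <- steadyState(asct2Model(), exchangePulse(iConc = 0))
  bound <- grepl("\\.U$", names(p))
  expect_true(all(p[bound] == 0))
  expect_equal(sum(p), 1, tolerance = 1e-9)
})

test_that("integration agrees with matrix-exponential propagation", {
  m <- toyRing3()
  cond <- conditions()
  p0 <- c(A = 1, B = 0, C = 0)
  traj <- integrateOccupancy(
    m, list(list(duration_ms = 500, conditions = cond)), p0 = p0, dt = 1)
  Q <- rateMatrix(m, cond)
  oracle <- expmPropagate(Q, p0, sampleTimes(traj))
  expect_lt(max(abs(occupancy(traj) - oracle)), 1e-7)
})

test_that("trajectories conserve probability and stay non-negative", {
  m <- asct2Model()
  traj <- integrateOccupancy(m, list(
    list(duration_ms = 30, conditions = exchangeRest(iConc = 100)),
    list(duration_ms = 50, conditions = exchangePulse(iConc = 100)),
    list(duration_ms = 50, conditions = exchangeRest(iConc = 100))),
    dt = 0.2)
  occ <- occupancy(traj)
  expect_lt(max(abs(rowSums(occ) - 1)), 1e-8)
  expect_gt(min(occ), -1e-10)
})

test_that("starting at the steady state gives a constant trajectory; long runs converge to it", {
  m <- toyRing4()
  cond <- conditions(sOut = 50, voltage = -20)
  pss <- steadyState(m, cond)
  traj <- integrateOccupancy(
    m, list(list(duration_ms = 200, conditions = cond)), p0 = pss, dt = 1)
  expect_lt(max(abs(sweep(occupancy(traj), 2, pss))), 1e-8)

  p0 <- setNames(c(1, 0, 0, 0), modelStates(m))
  traj2 <- integrateOccupancy(
    m, list(list(duration_ms = 2000, conditions = cond)), p0 = p0, dt = 5)
  final <- occupancy(traj2)[nrow(occupancy(traj2)), ]
  expect_lt(max(abs(final - pss)), 1e-6)
})

test_that("anion current is linear in the conducting weights and zero without them", {
  m <- toyRing4()
  cond <- conditions(sOut = 50)
  p0 <- setNames(c(1, 0, 0, 0), modelStates(m))
  traj <- integrateOccupancy(
    m, list(list(duration_ms = 100, conditions = cond)), p0 = p0, dt = 0.5)

  m0 <- m; m0@conductingWeights <- numeric()
  expect_true(all(traceCurrent(anionCurrent(traj, m0)) == 0))

  m2 <- m; m2@conductingWeights <- m@conductingWeights * 2
  expect_equal(traceCurrent(anionCurrent(traj, m2)),
               2 * traceCurrent(anionCurrent(traj, m)))
  ## inward-negative sign convention
  expect_true(all(traceCurrent(anionCurrent(traj, m)) <= 0))
})

test_that("transport current vanishes at equilibrium and is transient in homo-exchange", {
  ## equilibrium occupancy, constant conditions -> zero current
  m <- toyDetailedBalance()
  cond <- conditions()
  pss <- steadyState(m, cond)
  traj <- integrateOccupancy(
    m, list(list(duration_ms = 50, conditions = cond)), p0 = pss, dt = 0.5)
  ## give the ring a charge to probe with
  mz <- m
  mz@transitions$zDelta <- c(0.5, 0.3, -0.8)
  trace <- transportCurrent(traj, mz)
  expect_lt(max(abs(traceCurrent(trace))), 1e-9)

  ## ASCT2 homo-exchange: inward transient on application, outward
  ## transient on removal, no steady-state current
  ma <- asct2Model()
  tr <- runExchange(ma, exchangeProtocol(list(
    list(duration_ms = 50, conditions = exchangeRest()),
    list(duration_ms = 100, conditions = exchangePulse()),
    list(duration_ms = 100, conditions = exchangeRest())),
    mixingTau = 0), observable = "transport", dt = 0.1)
  t <- sampleTimes(tr); i <- traceCurrent(tr)
  peakOn <- min(i[t > 50 & t < 80])      # inward = negative
  peakOff <- max(i[t > 150 & t < 180])   # outward deflection on removal
  steady <- i[which.min(abs(t - 145))]
  expect_lt(peakOn, 0)
  expect_gt(peakOff, 0)
  expect_lt(abs(steady), 1e-6 * abs(peakOn))
})

test_that("anion current steps inward on substrate application and returns on removal", {
  ma <- asct2Model()
  tr <- runExchange(ma, exchangeProtocol(list(
    list(duration_ms = 50, conditions = exchangeRest()),
    list(duration_ms = 100, conditions = exchangePulse()),
    list(duration_ms = 150, conditions = exchangeRest())),
    mixingTau = 0), observable = "anion", dt = 0.1)
  t <- sampleTimes(tr); i <- traceCurrent(tr)
  base <- i[which.min(abs(t - 49))]
  during <- i[which.min(abs(t - 145))]
  after <- i[length(i)]
  expect_lt(during, base - 0.1)          # inward step
  expect_lt(abs(after - base), 0.01)     # returns to baseline
})
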