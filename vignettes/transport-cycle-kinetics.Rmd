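---
title: "Modeling allosteric inhibition kinetics in SLC1 transporters"
author: "slc1kin authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling allosteric inhibition kinetics in SLC1 transporters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slc1kin)
```

## The scientific problem

SLC1 transporters move amino acids across the plasma membrane by an
alternating-access ("elevator") mechanism: a transport domain carrying the
bound substrate and co-transported Na^+^ ions slides across the membrane
relative to a static scaffold domain. Allosteric inhibitors of the
UCPH-101 family bind at the interface between the two domains and obstruct
this movement. Whole-cell patch-clamp recordings under rapid solution
exchange resolve the consequences: reduced steady-state and transient
currents, slowed relaxations, and altered paired-pulse recovery.

Two kinetic regimes of allosteric inhibition are distinguishable in such
recordings, and discriminating them is the core purpose of this package:

* **Slow equilibration** (high-affinity binding, e.g. UCPH-101 on EAAT1):
  binding and unbinding are orders of magnitude slower than the transport
  cycle. Within one recording the bound and unbound pools do not
  interconvert, so the inhibitor simply removes transporters from the
  active pool — current amplitudes shrink in proportion to the unbound
  fraction while the observed rate constants are unchanged.
* **Fast equilibration** (low-affinity binding, e.g. UCPH-101 on ASCT2):
  the bound/unbound equilibrium tracks the transport cycle. Every
  transporter spends a fraction $K_U/([I]+K_U)$ of its time active, so all
  observed rate constants are scaled by the unbound fraction while a
  pre-equilibrium treatment applies.

## The kinetic state model

`buildCycle()` constructs a 12-state Markov model: six transport-cycle
states (outward apo → Na^+^-bound → 2 Na^+^-bound → fully loaded outward →
fully loaded inward → inward apo) and a mirror row of inhibitor-bound
states. Only two Na^+^-binding steps are modeled explicitly; the remaining
site is absorbed into effective rates. The inhibitor can bind *every*
cycle state with the same association/dissociation constants (pure
non-competitive default), and occupancy of the allosteric site scales the
translocation-type transitions — the loaded translocation step and the
empty-carrier relocation, both of which are movements of the transport
domain — by an activity factor $\alpha \in [0,1]$ in both directions.
Ligand binding steps of bound transporters are untouched, which encodes
the finding that these inhibitors act on translocation rather than on
substrate or Na^+^ binding.

Rates assemble into a master-equation generator: ligand-tagged forward
rates are multiplied by the matching concentration, and each electrogenic
step carries a symmetric Eyring voltage split,
$k_f(V) = k_f e^{-z\,FV/2RT}$, $k_r(V) = k_r e^{+z\,FV/2RT}$, with the
apparent charge $z$ per step a model parameter. The symmetric split and
the per-step $z$ values (0.25 per Na^+^ binding, 0.4 for translocation)
are stated conventions, not derived quantities; the relative
electrogenicity of Na^+^ binding versus translocation is not
experimentally resolved.

```{r}
m <- buildCycle(defaultModelParams("asct2_wt"))
m
```

Observables:

* **Anion current** — SLC1 transporters carry an uncoupled anion
  conductance gated by specific cycle states. `anionCurrent()` returns
  $-g\sum_s w_s p_s(t)$ (inward negative, normalized units); the per-state
  weights $w_s$ live in the parameter file.
* **Transport current** — `transportCurrent()` sums
  $z_e(\text{forward} - \text{reverse flux})$ over all electrogenic
  transitions, so an electroneutral homo-exchange steady state produces
  zero time-averaged current while concentration jumps produce transient
  charge movements.

## Calibration of the shipped parameter sets

No rate constants are printed for these transporters; the shipped YAML
files (`inst/params/`) are calibrated so the simulated observables
reproduce the published macroscopic time constants:

| anchor | target | model |
|---|---|---|
| EAAT1 transient decay after glutamate application | ~11 ms | `eaat1` |
| EAAT1 paired-pulse recovery | ~95 ms | `eaat1` |
| ASCT2 exchange-mode recovery after serine removal | ~15 ms | `asct2_wt` |
| ASCT2 apparent serine Km | ~280 µM | `asct2_wt` |
| EAAT1 inhibitor kinetics | k_off ≈ 0.01 s⁻¹, K_U = 0.6 µM | `eaat1` |
| ASCT2 inhibitor kinetics | k_off ≥ 100 s⁻¹, K_U = 77 µM | `asct2_wt` |

Design choices a maintainer should know about:

* **Binding order.** Substrate binds after both modeled Na^+^ steps. This
  matters kinetically: substrate release to the outside then needs no
  intervening Na^+^ dissociation, so external Na^+^ (140 mM, always
  saturating) cannot trap the loaded outward state and the exchange
  recovery stays fast, as observed.
* **Obligate exchange.** ASCT2 models use a near-zero empty-carrier
  relocation rate (10⁻⁴ s⁻¹, kept positive for irreducibility). This is
  what makes homo-exchange electroneutral at steady state; EAAT1 uses a
  relocation rate of ~10 s⁻¹, which is its rate-limiting step and sets the
  95 ms recovery.
* **Partial inhibition.** The wild-type ASCT2/UCPH-101 data show two
  things at once: the transient transport current at 100 µM inhibitor
  retains 50% amplitude with a doubled recovery time constant (pointing to
  full translocation block of the bound fraction), yet the steady-state
  anion dose-response saturates at ~45% inhibition. The model reconciles
  these with two separate couplings: $\alpha = 0$ (a bound transporter
  cannot translocate) and a *bound-state anion-conductance scale*
  $\gamma = 0.55$ (a bound transporter still binds substrate outward and
  gates a reduced anion conductance). Whether bound inhibitor suppresses
  the conductance of conducting states directly or only their population
  is not experimentally settled; $\gamma$ defaults to $\alpha$ and is a
  flagged assumption of the preset, not a measurement.
* **One tension left unmodeled.** The EAAT1 transient decay reportedly
  slows from 11 to ~20 ms at sub-K~i~ inhibitor while recovery is
  unchanged; under a strictly slow-equilibration model the decay should be
  unchanged too. The model does not attempt to reproduce those
  intermediate decay values.

## Protocols

`runExchange()` models piezo-driven solution exchange as a
single-exponential concentration relaxation with time constant
`mixingTau` (default 3 ms, i.e. a 10–90% rise of ≈6.6 ms, matching the
5–10 ms resolution of the technique). Voltage switches instantaneously.

`pairedPulseRecovery()` measures the fractional recovery of the second
peak: peaks are baseline-subtracted maxima of |current| within 50 ms of
each pulse onset, and the ratio-versus-interval curve is fit with
$r(\Delta) = 1 - A e^{-\Delta/\tau}$ (two components on request). Segment
boundaries are snapped to the sampling grid so both pulses are sampled at
the same phase of the fast rising edge — without this the peak ratio
acquires a sampling-phase artifact of several percent. The default
interval series is geometric between ~10 ms and ~2 s, which brackets all
calibrated time constants.

`voltageJumpCharge()` integrates the transport current over each voltage
step (composite Simpson rule) and subtracts a reference simulation in
which all conformational *and* binding transitions are frozen, mimicking
a bound competitive blocker that immobilizes the transporter's charge. A
warning is raised when the step is too short for the transient to settle.

## The inference layer

* `fitDoseResponse()` fits $I([U]) = I_1 - I_2\,[U]/(K_i+[U])$ by bounded
  trust-region least squares ($0 \le I_2 \le I_1$ enforced through an
  $I_2 = f I_1$ parametrization), with five log-spaced multistarts on
  $K_i$. Partial inhibition is flagged when the saturating residual
  $I_1 - I_2$ exceeds twice its (delta-method) standard error. Flat data
  return a `no-fit` status instead of erroring. Least squares is
  unweighted by default; per-point weights can be supplied.
* `fitMM()` fits $I_{max}[S]/(K_m+[S])$ and flags non-saturating designs.
* `kobsPreEquilibrium()` evaluates the pre-equilibrium relaxation rate
  $k_{obs} = \left(k_f\frac{[S]_o}{[S]_o+K_m} +
  k_r\frac{[S]_i}{[S]_i+K_m}\right)\frac{K_i}{[I]+K_i}$. Infinite
  substrate arguments are treated as the exact saturating limit, so
  "saturating internal substrate" contributes a factor of exactly 1.
* `fitBiexponential()` fits two exponentials plus baseline with log-spaced
  multistarts and collapses to a single exponential when either amplitude
  is statistically (2 SE) or numerically negligible, or the two time
  constants degenerate.
* `fitBoltzmannQV()` fits $Q(V) = Q_{max}/(1+e^{z_{app}F(V-V_{1/2})/RT})$
  at 22 °C (the recording temperature is not reported; room temperature is
  assumed). For jump-referenced charges an additive offset can be fit; in
  that case the sign of $z_{app}$ trades off against $Q_{max}$ and only
  its magnitude is identified.
* `kiVsSubstrate()` classifies the inhibition mechanism. Decision rule
  (thresholds fixed a priori): non-competitive when the slope z-statistic
  of $K_i$ vs $[S]$ is within 2 SE of zero; otherwise competitive when the
  fixed-slope line $K_i(0)(1+[S]/K_m)$ halves the constant model's
  relative residual; otherwise mixed when the three-parameter saturating
  form $K_i^{\infty} - (K_i^{\infty}-K_i(0))\,K_m'/(K_m'+[S])$ (the
  minimal saturating curve; no functional form is established for this
  behavior) halves it; otherwise the verdict falls back to
  non-competitive. With ~5 substrate levels the slope t-statistic is
  noticeably heavier-tailed than normal, so the classifier is validated on
  8 log-spaced levels spanning 30–5000 µM, where all three mechanisms are
  recovered in ≥95% of noisy replicates at 5% noise.

Parameter standard errors come from the Jacobian at the optimum; a
seeded residual-resampling bootstrap (500 draws by default) is available
for the dose-response $K_i$.

## Synthetic data and what passing tests mean

`scenarioPreset()` bundles named experimental scenarios — EAAT1 with its
slow inhibitor, wild-type ASCT2 with partial UCPH-101 block, the
binding-site double mutant with restored full block, compound #302 on
both backgrounds — with their complete generating truths (dose-response
$I_1, I_2, K_i$; activation $K_m$; recovery time constants and regime;
Q–V Boltzmann parameters). The generators (`genDoseResponse()`,
`genSubstrateActivation()`, `genPairedPulse()`, `genQV()`) evaluate either
the closed-form truth ("analytic" mode) or the kinetic model ("model"
mode), then add seeded Gaussian noise scaled to the peak (default 3%,
matching the visual quality of published whole-cell records), an optional
baseline offset and linear drift. Identical seeds give bit-identical
datasets.

The noise model emulates stationary Gaussian recording noise only. It does
not emulate seal/leak currents, series-resistance or capacitance
artifacts, solution-exchange irreproducibility, or cell-to-cell expression
variability beyond a scale factor. Passing round-trip tests therefore
demonstrate estimator correctness and calibration consistency — not
robustness to every pathology of real recordings.

Q–V truths (midpoint −30 mV, valence 1, inhibited charge scale 0.5) are
scenario choices on the physiological scale; the source recordings print
no Boltzmann parameters for these constructs.

## Numerical choices

* Stiff integration by `lsoda` with `rtol = 1e-10`, `atol = 1e-12`
  (slightly relaxed under time-varying mixing), validated against dense
  matrix-exponential propagation to <1e-7 on small models.
* Steady states solve $(Q + \mathbf{1}\mathbf{1}')p = \mathbf{1}$ on the
  unique closed communicating class (rate-scaled; SVD null-space
  fallback); unreachable states are pruned and reported with occupancy 0,
  and multiple closed classes raise an error naming the components.
* Charge integrals use the composite Simpson rule.
* Default trace sampling is 0.1 ms; the heavier simulation tests use
  0.2–1 ms, which resolves every calibrated time constant by more than an
  order of magnitude. Monte-Carlo checks use 200 replicates per case and
  the classifier validation 200 per mechanism.
* Fits are trust-region least squares (`minpack.lm`), bounded at physical
  limits, with log-spaced multistarts on scale parameters; the best
  residual sum of squares wins.

## Known limitations

* Currents are in normalized units; absolute pA calibration is
  cell-dependent and out of scope.
* Occupancies are deterministic ensemble averages — no single-molecule
  stochastic gating.
* The third Na^+^ site, K^+^ counter-transport (EAAT1) and proton coupling
  are absorbed into effective rates.
* The mixed-inhibition preset encodes the double mutant's qualitative
  pattern with invented saturation parameters; only its $K_i$ and $K_m$
  anchors are taken from measurements.

## A worked example

```{r}
p <- scenarioPreset("asct2_wt_partial")
ds <- genDoseResponse(p, c(0, 5, 10, 25, 50, 100, 200, 500), noiseModel(0))
fitDoseResponse(ds$data$dose_uM, ds$data$current)

kobsPreEquilibrium(kf = 100, kr = 1000 / 15, S_out = 0, S_in = Inf,
                   Km = 280, I_conc = 100, Ki = 100)$tauMs
```
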