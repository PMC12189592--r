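---
title: "A hybrid PLSR–UKF soft sensor for fed-batch L-phenylalanine production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid PLSR–UKF soft sensor for fed-batch L-phenylalanine production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phesensor)
```

## The estimation problem

Key state variables of a fermentation — biomass, substrate, product and
by-product concentrations — are usually measured offline, sparsely, and
with hours of delay, while the reactor logs cheap online signals
(stirrer speed, aeration, pO2, temperature, pH, off-gas CO2, feed mass
flow, cumulative base addition) every couple of minutes. A *soft sensor*
reconstructs the former from the latter.

`phesensor` implements a hybrid soft sensor for a three-phase fed-batch
L-phenylalanine (L-phe) process with a recombinant, L-tyrosine-auxotrophic
*E. coli* production strain:

1. a **coarse-grained process model** (CGM) with proteome resource
   allocation supplies the state-transition function,
2. **phase-wise PLS regression** (SIMPLS) maps the eight online channels
   to the five measured concentrations (biomass X, glycerol S, L-phe P,
   acetate A, L-tyr Y), and
3. a **constrained unscented Kalman filter** (UKF) fuses the two: the
   model predicts every 60 s, the PLSR estimates correct every 120 s.

Because plant data from such processes are rarely public, the package
also contains a first-class synthetic-process generator that emulates
the study design (three processes differing in induction strength and
seed), so that the complete pipeline is testable end to end.

## The coarse-grained model

The state is 10-dimensional: reactor volume $V$ and the five
concentrations $S, X, P, A, Y$ (g/L), plus four intracellular mass
fractions — the proteome sectors for transport/catabolism $\phi_T$,
ribosomes $\phi_R$, and L-phe production $\phi_{Fp}$, and the metabolite
pool $m$. A fixed housekeeping sector $\phi_Q$ completes the proteome.
Biomass-specific rates are gated by the sector sizes:

$$v_T = k_T\,\phi_T\,\frac{S}{K_S+S},\qquad
  \mu = v_R = k_R\,\phi_R\,\frac{m}{K_{mR}+m}\,\frac{Y}{K_Y+Y},$$
$$v_F = k_F\,\phi_{Fp}\,\frac{m}{K_{mF}+m},\qquad
  v_A = k_A\,\max(0,\,v_T - v_{crit}),\qquad v_Y = c_Y\,\mu .$$

Growth requires L-tyrosine (auxotrophy), and acetate appears as overflow
whenever catabolic flux exceeds the respiratory capacity $v_{crit}$.
Allocation targets $\alpha_i$ (toward which the $\phi_i$ relax at rate
$\mu$) close to one: $\alpha_Q = \phi_Q$ is fixed, $\alpha_{Fp}$
saturates in the inducer (IPTG) concentration with half-saturation
$K_I$, $\alpha_R$ takes a metabolite-dependent share of the remainder,
and $\alpha_T$ gets the rest. The reactor balances are standard
fed-batch equations with feed dilution and no outflow; see
`?cgmDerivatives`.

The process has three phases: a batch that ends when the 4 g/L of
starting glycerol are depleted; a biomass production phase with a
closed-loop exponential feed targeting $\mu_{set} = 0.1\,h^{-1}$
(312.5 g/L glycerol feed, with small L-phe and L-tyr supplements); and,
after at least 21 h of feeding and IPTG induction, a production phase
feeding 800 g/L glycerol at a fixed specific rate
$q_{feed3} = 0.18\ \mathrm{g\,g^{-1}\,h^{-1}}$.

### Parameterization

The kinetic constants and yields (see `?cgmParameters`) are engineering
defaults chosen once to reproduce the qualitative phenotype of the
process — batch end between 13 and 17 h, realized phase-2 growth rate
within 10% of the set point, a production-protein fraction that
plateaus near 0.08, tens of g/L of product after induction, low acetate
— and are **not** estimates from plant data. Two consequences of the
model structure are worth recording:

* **Production is carbon-supply-limited.** Once growth ceases (the
  L-tyr budget accumulated during phase 2 is exhausted), the metabolite
  pool settles where product efflux balances the feed:
  $v_F \to Y_{PM} Y_{MS}\, q_{feed3}$. The catalytic constant $k_F$
  only sets the level of $m$ at which this happens; if $k_F \phi_{Fp}$
  is too small the pool grows without bound instead. The defaults keep
  the balance attainable over the whole horizon.
* **The low-induction paradox is emulated, not explained.** In the
  study design the weakly induced processes show the *higher* titer,
  which a proteome-allocation model cannot produce mechanistically. The
  synthetic low-IPTG scenarios therefore apply a phenomenological
  override, multiplying the truth's $q_{feed3}$ (and hence the true
  production rate) by 1.5 while the filter keeps the nominal value —
  exactly the plant–model mismatch the hybrid filter is supposed to
  absorb. $K_I = 0.002$ mM keeps 0.01 mM IPTG strongly inducing, in
  line with that observed phenotype.

The proteome closure is maintained as
$\phi_T + \phi_R + \phi_{Fp} \le 1 - \phi_Q$; the metabolite fraction
$m$ is a separate (non-protein) pool bounded by its own balance, not by
the protein closure — at proteome steady state the protein sectors
alone exhaust $1-\phi_Q$.

## Phase-wise PLSR

Within each phase the online matrix is offset-centered against the
phase start (`phaseOffsetCenter()`): row $i$ becomes $X_i - X_0$, with
$X_0$ the mean of the first three rows (one row would be the literal
definition; the short average damps sensor noise at the phase
boundary). This removes between-process differences in absolute sensor
levels; predictions on a new process are centered with *that process's
own* phase start. Output variables for training come from the process
model's trajectory, linearly interpolated onto the online time stamps —
offline samples alone are far too sparse to train on.

The regression itself is SIMPLS, implemented directly (successive
dominant singular vectors of the deflated cross-product $X^\top Y$ with
loading-orthogonal deflation). At full rank it reproduces ordinary
least squares; scores are mutually orthogonal. Two numerical guards
matter on process data: channels that are constant within a phase
(controlled setpoints) make the input matrix rank-deficient, so the
latent-variable count is capped by an SVD-based effective rank
(relative tolerance $10^{-7}$), and a component whose score norm
collapses raises an error instead of amplifying noise.

The latent-variable count is selected by five-fold cross-validation on
contiguous time blocks (appropriate for autocorrelated process data;
random folds are available). Per-output mean squared errors are
standardized by the output standard deviations before aggregation so
that biomass (tens of g/L) does not drown out L-tyr (below 0.1 g/L).
Because the CV curve is flat beyond the informative dimension, counts
within 1% of the minimum RMSECV are treated as ties and resolved toward
fewer latent variables — the usual parsimony rule; strict argmin is the
`tie_tol = 0` special case.

## The constrained UKF

The filter is the scaled unscented Kalman filter with additive noise.
Sigma points are generated by Cholesky factorization of
$(n+\lambda)P$ with $\lambda = \alpha^2(n+\kappa) - n$; weights are
$W_m^{(0)} = \lambda/(n+\lambda)$,
$W_m^{(i)} = 1/(2(n+\lambda))$, and
$W_c^{(0)} = W_m^{(0)} + (1-\alpha^2+\beta)$. Defaults
$\alpha = 0.5$, $\beta = 2$, $\kappa = 0$. Each sigma point is
integrated through the process model with the phase-appropriate feed
law (the control input); prediction runs every 60 s, and each 120 s
online row triggers a measurement update with the PLSR estimates as the
measurement vector. The innovation covariance is solved, never
inverted, and covariances are symmetrized after every step.

Nonnegativity is enforced by sigma-point projection: if a posterior
mean violates a lower bound, sigma points are regenerated from the
posterior, violating coordinates are clipped to the bound, and the set
is recombined once (no iteration, no re-integration; re-propagation
through the model would re-introduce the infeasible excursion it is
meant to remove, and the recombination already restores a consistent
mean–covariance pair). Negative PLSR estimates are passed to the update
unclipped — the constraint acts on states, not on measurements. Because
$W_c^{(0)}$ is negative at these settings, clipping can leave the
recombined covariance slightly indefinite; it is projected back onto
the PSD cone by eigenvalue clamping.

### Noise covariances

$R$ is diagonal with the squared per-output RMSEs of the PLSR
estimates on the designated calibration process (`buildR()`), with a
floor of $10^{-3}$ g/L on the RMSE: an output that happens to be near
zero wherever offline samples exist (glycerol, with no batch-phase
samples) would otherwise get an unrealistically small entry and an
overconfident filter. $Q$ is diagonal and calibrated by a generalized
pattern search over $\log_{10} q$ (`estimateQ()`): coordinate polling
with opportunistic acceptance, mesh doubling on success and halving on
failure, box bounds $[10^{-8}, 10^{2}]$, stopping at mesh $10^{-3}$ or
on an evaluation budget. The objective is the mean squared deviation
between posterior estimates (interpolated to the offline sampling
times) and the offline measurements, standardized per output. $Q$ and
$R$ are constant over the run; per-phase variants are deliberately out
of scope.

$P_0$ is diagonal, $(10\%\ \text{of}\ x_0)^2$ floored at $10^{-6}$,
with the glycerol entry inflated tenfold because starting substrate
levels vary between processes.

### Numerical choices

* Ground truth and open-loop comparisons use a stiff ODE solver
  (`deSolve::lsoda`, atol = rtol = $10^{-9}$), with the integration
  restarted at phase boundaries so feed discontinuities are exact.
* Inside the filter, sigma points are propagated with fixed-step RK4
  (three substeps per 60 s step, i.e. 20 s steps), applied to all 21
  points as one matrix operation. The glycerol-uptake term sets the
  fastest scale ($k_T \phi_T X / K_S$ near depletion); 20 s steps keep
  RK4 comfortably inside its stability region at realistic biomass.
  Kinetic terms clamp negative excursions to zero so the right-hand
  side stays defined for slightly infeasible sigma points.
* Cholesky factorizations retry with escalating diagonal jitter
  ($10^{-10}$ to $10^{-6}$ times the mean diagonal) before failing.
* IPTG is a schedule input, not a state; time is handled in hours
  internally, with the 60/120 s cadences converted at the interface.

## The synthetic process generator

`makeScenario()` builds the three study processes: a reference induced
with 0.3 mM IPTG, and two low-IPTG (0.01 mM) processes used for
calibration and held-out testing. The batch end is detected on the
truth run as glycerol dropping below 0.01 g/L — a stand-in for the pO2
spike a real reactor shows at depletion — and induction follows 21 h of
biomass production.

The state-to-sensor map (`generateOnlineSignals()`) is invented (real
sensors were logged in the study), but it is built to preserve the
correlation structure that makes PLSR work on such processes: off-gas
CO2 and the stirrer/aeration cascade track oxygen demand and hence
growth; cumulative base addition carries the product signal (L-phe is
an ampholyte, weak coefficient) and a stronger acetate term; pH and
temperature are controlled setpoints carrying almost no information;
during the constant-specific-feed production phase the cascade channels
go nearly flat, exactly the regime in which base addition becomes the
informative channel. Offline samples get mean-one lognormal noise
(HPLC-like, CV 5%) plus a small additive floor, and none are taken in
the batch phase by default, reproducing the study's sampling gap.

What the generator does *not* emulate: antifoam events, probe drift,
foam excursions, gas-phase mass-transfer dynamics, or any mechanistic
link between induction strength and metabolic burden. Tests passing on
these data therefore demonstrate the estimation machinery — model
mismatch of the prescribed kind, realistic noise and sampling — but not
robustness to unmodeled disturbances of a real plant.

## Problem sizes used by the tests

The test-suite defaults mirror the study layout: 70 h processes at
120 s cadence (2101 online rows), 14 offline samples (0/6/8 per
phase). The filter-equivalence, calibration and determinism tests run
on shorter horizons (15–45 h) and on reduced pattern-search budgets;
the demo ties the Q search to two dials (reactor states, intracellular
states) to stay affordable. These are the package's own choices of
problem size; all of them can be raised through the exported arguments.

## Limitations

* The CGM cannot represent the inducer-strength paradox or acetate
  formation at low growth; the filter inherits whatever the PLSR
  measurements can and cannot see (acetate, in particular, is weakly
  observable from routine channels).
* Q and R are constant over the run; innovation-based or
  parameter-uncertainty-based adaptation is out of scope.
* No joint state–parameter estimation and no square-root filter
  variants; covariance health is maintained by symmetrization, jitter
  and PSD projection instead.
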