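# phesensor

Hybrid soft sensor for fed-batch L-phenylalanine fermentations: a
coarse-grained proteome-allocation process model inside a constrained
unscented Kalman filter (UKF), with phase-wise partial least-squares
regression (PLSR, SIMPLS) turning routine online signals into the
filter's measurements.

## The problem

During process development, the variables one actually cares about —
biomass, glycerol, L-phenylalanine (L-phe), acetate, L-tyrosine (L-tyr)
— are measured offline, sparsely and manually, while the reactor logs
eight cheap online channels every 120 s (stirrer speed, aeration rate,
pO2, temperature, pH, off-gas CO2, substrate feed mass flow, cumulative
base addition). This package estimates the concentration trajectory,
and intracellular proteome fractions besides, in real time from those
online channels. It is written for bioprocess engineers who want a
working hybrid (mechanistic + data-driven) state estimator they can
retrain on their own runs, and it ships with a synthetic three-phase
process generator so everything can be exercised without plant data.

## The method

* **Process model**: a ten-state coarse-grained model — reactor volume,
  the five concentrations, and intracellular fractions
  (φT transport/catabolism, φR ribosomes, φFp production proteins,
  m metabolites). Rates are gated by proteome sectors, e.g. uptake
  `v_T = k_T φT S/(K_S+S)` and growth
  `μ = k_R φR · m/(K_mR+m) · Y/(K_Y+Y)` (the strain is an L-tyr
  auxotroph); acetate is overflow above a capacity threshold. Three
  phases: batch, exponential feeding at μ_set = 0.1 1/h, and induced
  production at 0.18 g glycerol (g biomass)⁻¹ h⁻¹.
* **PLSR**: per phase, online inputs are offset-centered against the
  phase start (X̃ᵢ = Xᵢ − X₀) and regressed on model-interpolated
  concentrations with a from-scratch SIMPLS; the latent-variable count
  comes from five-fold RMSECV with a 1% parsimony tie rule.
* **UKF**: scaled sigma points (α = 0.5, β = 2, κ = 0), Cholesky square
  roots with escalating jitter, predictions every 60 s by matrix RK4
  through the model, updates every 120 s with the PLSR estimates as
  measurements, and nonnegativity enforced by projecting violating
  sigma points onto the bounds. `R = diag(RMSE²)` of the PLSR on a
  calibration process; `diag(Q)` is tuned by a log-space pattern
  search against the offline samples.

## Worked example

The demo reproduces the full three-process workflow on synthetic data:
train PLSR on a reference process (0.3 mM IPTG), calibrate R and Q on a
low-induction process, then run the hybrid filter on a second, held-out
low-induction process whose true production rate exceeds the filter's
model by 50%.

```r
library(phesensor)
demo <- runDemo("demo-out", seed = 1, t_end = 70, q_budget = 30,
                quiet = TRUE)
print(demo)
#> <demo_result> held-out process, RMSE vs offline samples [g/L]:
#>  state cgm_rmse ukf_rmse
#>      X  0.89000  1.00000
#>      S  0.01710  0.01600
#>      P  9.11000  1.83000
#>      A  0.00920  0.00932
#>      Y  0.00885  0.00419
```

Reading the table: the open-loop process model (`cgm_rmse`) underpredicts
the product badly on the held-out process — its parameterization produces
L-phe 50% too slowly, so the error reaches 9.1 g/L at ~48 g/L final
titer. The filter (`ukf_rmse`) absorbs most of that mismatch through the
PLSR measurements (the base-addition channel carries the product signal)
and cuts the L-phe error to 1.8 g/L, a factor ≈ 5, while leaving the
already-accurate glycerol, acetate and L-tyr estimates essentially
unchanged. Biomass is slightly degraded — the filter inherits the PLSR's
biomass bias — which is the expected trade-off when measurements are
themselves model outputs. `demo-out/` contains the three datasets, the
filter trace, the PLSR training report (here 5/2/6 latent variables per
phase) and the calibrated noise specification as plain CSV/JSON.

A thin command-line wrapper with `simulate`, `train-plsr` and `demo`
subcommands is installed at `inst/cli/phesensor.R`.

## Scope notes

Everything here runs on synthetic data shaped like the study design;
the generator's observation model is invented (documented in the
methods vignette, `vignettes/hybrid-soft-sensor.Rmd`), so results
demonstrate the estimation machinery under controlled model mismatch,
not performance on a specific real plant.
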