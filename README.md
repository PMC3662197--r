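# thermolipase

Statistics for thermophilic-lipase bioprospecting: dual-mode screening
classification, p-nitrophenyl palmitate (pNPP) assay conversion, two-step
series thermal-deactivation kinetics, and Arrhenius activation-energy
estimation — plus synthetic-data generators that make every stage testable
without laboratory data.

The package is aimed at enzyme-kinetics and microbial-screening work of the
kind done when a strain collection is screened for extracellular lipase
production and the best producers' enzymes are characterised for thermal
stability. It ships the reference screening table of a 101-strain collection
of thermophilic isolates from the Santorini volcanic habitat and the fitted
deactivation parameters of its nine selected lipases at 70–100 °C, so the
functions can be exercised against real numbers out of the box.

## The model at the core

Thermal deactivation of robust enzymes often fails first-order kinetics.
The series (two-step) deactivation model routes the native enzyme through a
partially active intermediate,

    E0 --k1--> E1 --k2--> E2,

with first-order rate constants `k1`, `k2` (1/min), specific-activity ratio
`α1 = E1/E0 ∈ [0, 1]`, and an inactive final state. The observed residual
activity is the biexponential

    α(t) = [1 + α1·k1/(k2−k1)]·exp(−k1·t) − [α1·k1/(k2−k1)]·exp(−k2·t),

with the analytic limit `(1 + α1·k1·t)·exp(−k1·t)` at `k1 = k2`.
`fit_two_step()` estimates `(α1, k1, k2)` by constrained multistart
Levenberg–Marquardt least squares (`α1` box-constrained to `[0, 1]`, rates
kept positive on the log scale), `compare_models()` tests the model against
plain first-order decay by AIC, and `fit_arrhenius()` regresses `ln k` on
`1/T` to report activation energies `Ea = −slope·R` in kJ/mol.

## Worked example

```r
library(thermolipase)

## 1. screening: classify and summarise the packaged 101-strain table
summarize_screen(santorini_screen())
#> <screen_summary> 101 strains
#>   halo producers:         17 (16.8%)
#>   liquid > 0.05 nkat/mL:  56 (55.4%)
#>   liquid low:             19 (18.8%)
#>   no activity:            26 (25.7%)

select_strains(santorini_screen())
#>  [1] "SP14" "SP22" "SP29" "SP73" "SP75" "SP76" "SP79" "SP83" "SP93" "SP95"

## 2. simulate a triplicate deactivation experiment for the SP14/70 °C
##    parameters and refit it
tr  <- ground_truth(0.647, 2.24e-2, 1.82e-4, "SP14")
tc  <- simulate_timecourse(tr, sim_config(seed = 11,
         time_grid = recovery_design(tr$k1, tr$k2)), temperature = 70)
fit <- fit_two_step(tc, seed = 12)
fit
#> <deact_params> SP14 at 70 C (n = 39)
#>   alpha1 = 0.6514 (se 0.0093)
#>   k1     = 0.02485 /min (se 0.0018)
#>   k2     = 0.0001878 /min (se 5e-06)
#>   SSR = 0.0095, R2 = 0.99736
half_life(fit)
#> [1] 1448.832

compare_models(tc, seed = 12)
#> <fit_comparison> delta AIC (first-order minus two-step) = 178.57 -> two_step preferred

## 3. activation energy from the published SP14 k1 series (70-100 °C)
fit_arrhenius(c(70, 80, 90, 100), c(0.0224, 0.154, 0.230, 0.359))
#> <arrhenius_fit> Ea = 93.72 kJ/mol, ln A = 29.464, R2 = 0.8655 (4 temperatures)
```

The screening summary reproduces the reference partition (17 halo producers;
56 significant, 19 low, 26 inactive strains in liquid culture — 74.3%
detectable). The refit recovers the simulated truth within its linearised
standard errors, the model comparison decisively rejects first-order decay
for the biphasic curve, and the Arrhenius regression on the published SP14
rate constants returns the published 93.72 kJ/mol.

`run_pipeline()` chains all stages from a single YAML/list configuration and
writes per-stage CSVs plus a plain-text report; see the methods vignette
(`vignettes/thermal-deactivation.Rmd`) for the model assumptions, the
identifiability analysis behind `recovery_design()`/`design_se()`, and all
numerical choices.

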