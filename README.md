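# pyrekin

Kinetic analysis of microbial degradation time courses in which a parent
compound decays by first-order kinetics and part of the degraded flux
accumulates transiently as a tracked intermediate metabolite. The motivating
system is bacterial degradation of the four-ring PAH pyrene with
2,2′-diphenic acid (DIPA) as the central intermediate, but any
parent–metabolite pair measured as concentration time courses fits. The
package is aimed at environmental microbiologists and biodegradation
kineticists who have tidy tables of replicate concentrations (and optionally
RT-qPCR Ct tables) and want rate constants with honest uncertainty.

## The model

The branched two-pool first-order system

$$\frac{dS}{dt} = -k_{tot} S, \qquad \frac{dP}{dt} = f k_{tot} S - k_2 P$$

with parent concentration $S$ (mg L⁻¹), intermediate $P$ (mg L⁻¹), total
parent degradation rate constant $k_{tot}$ (d⁻¹), branching fraction
$f \in [0,1]$, intermediate degradation rate constant $k_2$ (d⁻¹), and the
derived formation rate constant $k_a = f\,k_{tot}$. The closed-form
(Bateman) solution is fitted globally to both series by Levenberg–Marquardt
least squares; uncertainty comes from a parametric bootstrap (default 500
resamples, 5–95% percentile intervals), including a robustness summary of
the branching fraction $f$. Molar-yield stoichiometry, the 2^−ΔΔCt method
for RT-qPCR tables, and a seeded synthetic-data generator round out the
pipeline.

## Worked example

```r
library(pyrekin)

truth <- kinetic_params(k_tot = 0.142, f = 0.4437, k2 = 0.150, S0 = 60)
d <- simulate_timecourse(truth, design_spec(noise_sigma_parent = 2,
                                            noise_sigma_intermediate = 1,
                                            seed = 1))
fit <- fit_branched_model(d)
fit
#> Global branched first-order fit (52 observations)
#>   k_tot = 0.1402 1/d (half-life 4.95 d)
#>   f = 0.4816   k_a = 0.0675 1/d   k2 = 0.1612 1/d
#>   S0 = 59.61 mg/L   pooled R^2 = 0.9915   converged: TRUE

parametric_bootstrap(fit, n = 500, seed = 2)
#> Parametric bootstrap: 500 resamples (0 failed), seed 2
#>        lower_5 upper_95
#> k_tot  0.13512  0.14440
#> f      0.43543  0.53913
#> k2     0.13947  0.18650
#> k_a    0.06143  0.07442
#> S0    58.57449 60.60130
```

The fit recovers the generating rate constants from the noisy triplicate
design (`k_tot` 0.140 vs truth 0.142 d⁻¹) and the 5–95% intervals bracket
every generating value. Derived quantities follow directly:

```r
half_life(0.142)                              # 4.881318 days
molar_yield_percent(23.0, "DIPA", 47.3, "pyrene")  # 40.60012 %
intermediate_peak(truth)$peak_time            # 6.85103 days
```

`half_life()` converts a rate constant to a DT50; `molar_yield_percent()`
expresses accumulated intermediate as a mole percentage of degraded parent
(here: 23.0 mg L⁻¹ DIPA against 47.3 mg L⁻¹ pyrene degraded is a 40.6%
molar yield); `intermediate_peak()` gives the time at which the model's
intermediate trajectory turns over. `run_full_analysis()` chains
fit → bootstrap → derived quantities into a JSON report plus CSV tables,
and `inst/scripts/pyrekin-cli.R` exposes each stage as a shell subcommand
(`simulate`, `fit`, `bootstrap`, `yield`, `ddct`, `run`).

The methods vignette (`vignettes/branched-kinetics.Rmd`) documents the
model assumptions, fitting transforms, bootstrap noise law, LOD handling
and the limits of what the synthetic-data generator emulates.

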