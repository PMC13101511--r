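---
title: "Branched first-order kinetics of parent–metabolite degradation"
author: "pyrekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branched first-order kinetics of parent-metabolite degradation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyrekin)
```

## The model

Microbial degradation of a poorly soluble substrate such as pyrene is often
well approximated by first-order kinetics over the time scale of a
shake-flask experiment. When a single intermediate metabolite — here
2,2′-diphenic acid (DIPA) — accumulates transiently, the minimal model is a
branched two-pool system:

$$\frac{dS}{dt} = -k_{tot}\,S, \qquad
  \frac{dP}{dt} = f\,k_{tot}\,S - k_2\,P,$$

with $S$ and $P$ the parent and intermediate concentrations (mg L⁻¹),
$k_{tot}$ the total parent degradation rate constant (d⁻¹), $f \in [0,1]$
the branching fraction of degraded parent flux routed into the tracked
intermediate, and $k_2$ (d⁻¹) its onward degradation rate constant. The
effective formation rate constant is $k_a = f\,k_{tot}$ by definition, so
the package reports it as that exact product, never as a separately
estimated quantity. The solution is the classical Bateman form:
$S(t) = S_0 e^{-k_{tot} t}$ and, for $k_2 \neq k_{tot}$,

$$P(t) = P_0 e^{-k_2 t} +
  \frac{f k_{tot} S_0}{k_2 - k_{tot}}\left(e^{-k_{tot}t} - e^{-k_2 t}\right).$$

Assumptions worth keeping in mind: degradation is not growth-linked (no
Monod term), the intermediate pool is well mixed and fully bioavailable,
and only one intermediate is tracked — any flux through other channels is
absorbed into $1-f$. Multi-intermediate cascades and biphasic or
Michaelis–Menten kinetics are out of scope.

### Numerical choices

The difference $e^{-k_{tot}t} - e^{-k_2 t}$ is rewritten as
$-e^{-k_{tot}t}\,\mathrm{expm1}(-(k_2-k_{tot})t)$, which is stable under
cancellation however close the two rates are. The equal-rate limit formula
$P(t) = f k_{tot} S_0\, t\, e^{-k_{tot} t}$ is therefore only needed to
remove the $0/0$ at $k_2 = k_{tot}$ itself; the switch happens at
$|k_2-k_{tot}| < 10^{-12}$ d⁻¹, where the limit formula's own
$O(|k_2-k_{tot}|\,t^2)$ error is far below every tolerance used in the
package. (A wider switching band would be needed only if the difference of
exponentials were evaluated naively; in that form the band itself becomes
the dominant error source at high $S_0$.) Closed-form and adaptive ODE
evaluation (`solve_numeric`, lsoda with `rtol = atol = 1e-12`) agree to
better than $10^{-8}$ mg L⁻¹ over the whole plausible parameter range, and
this dual route is exercised by the test suite as a property check.
Concentrations in $(-10^{-12}, 0)$ arising from float noise are clipped to
zero; anything more negative raises an error, so genuine bugs are not
silently absorbed.

## Global fitting

`fit_branched_model()` minimises the pooled sum of squared residuals of
both series against the closed form, using Levenberg–Marquardt
(`minpack.lm::nls.lm`, objective tolerance $10^{-10}$, finite-difference
gradients). Rates are optimised on the log scale and $f$ on the logit
scale, which enforces $k_{tot} > 0$, $k_2 > 0$, $0 < f < 1$ without hard
bounds and mirrors the strict positivity of realistic estimates. Starting
values are data-driven and deterministic: $k_{tot}$ from a log-linear
regression of the positive parent observations on time, $f = 0.5$,
$k_2 = k_{tot}$, $S_0$ from the earliest parent mean.

Choices that were genuinely open, and how they were resolved:

* **$S_0$ estimated by default**, with `fix_S0 = TRUE` available. The
  nominal spiked mass of a hydrophobic compound need not equal the
  measurable dissolved concentration at $t=0$, so estimating it is the
  safer default.
* **Unweighted residuals on the raw mg L⁻¹ scale** by default. The two
  series are of comparable magnitude (tens of mg L⁻¹), so neither dominates;
  `weighting = "inv_var"` performs one reweighting pass with per-series
  inverse-variance weights for users whose channels differ strongly.
* **Replicates enter as independent observations** (no replicate
  hierarchy); fitting replicate means instead is possible by averaging
  before `time_course_data()`.
* **Below-LOD observations are excluded** from the objective by default;
  `lod_policy = "half_lod"` substitutes LOD/2 instead. Censored values
  carry information, but without knowing the instrument's censoring
  mechanism, exclusion is the least-assumption default.
* **$R^2$ is pooled** over both series, with the total sum of squares
  measured around each series' own mean — a single global fit warrants a
  single $R^2$, but per-series values are reported alongside
  (`r_squared_by_series`) since a pooled figure can hide a poor
  intermediate fit behind a good parent fit.

Input tables are canonically sorted by (compound, time, replicate) on
entry, so the objective, the fit and every downstream seed-driven
computation are invariant to row order.

## Parametric bootstrap

`parametric_bootstrap()` resamples synthetic datasets as model prediction
plus additive Gaussian noise with the fitted per-series residual SD,
truncated at zero, refits each, and reports empirical 5–95% percentile
intervals (linear-interpolation quantiles). A parametric bootstrap requires
an explicit observation model; additive Gaussian per channel is the
least-structured choice for concentration residuals and is deliberately the
same law the synthetic-data generator uses, so generator and inference are
internally consistent. Non-converged resamples are dropped and counted
rather than retried — retrying would silently bias the resample stream —
and more than 20% failures aborts with an error. One integer seed governs
the whole stream; draws are bit-identical across runs with the same seed
and inputs. `branching_robustness()` summarises the $f$ draws: percentile
interval, the fraction of draws with $f > 0.5$ (the probability that the
tracked intermediate carries the dominant share of parent flux), and the
coefficient of variation.

Interval coverage is a property, not an assumption: the test suite checks
that across 200 seeded simulated experiments the 5–95% interval covers the
generating $k_{tot}$ at a rate in $[0.80, 0.97]$ (200 resamples per
experiment — the bootstrap size is scaled down from the 500 used in single
analyses to keep the nested loop tractable; with 50-odd observations per
fit this is well past the point where interval endpoints stabilise).

## Stoichiometry

Because parent and intermediate differ in molecular weight (202.25 vs
242.23 g mol⁻¹ for pyrene vs DIPA), yields are meaningful only on a mole
basis. `molar_yield_percent()` computes
$100\,(P/\mathrm{MW}_P)/(\Delta S/\mathrm{MW}_S)$; for example 23.0 mg L⁻¹
of DIPA against 47.3 mg L⁻¹ of degraded pyrene is a 40.6% molar yield.
`timecourse_molar_yield()` vectorises this over a time course using
replicate means, flagging time points with non-positive parent depletion
(including $t=0$) as undefined rather than returning infinities. The
mass-flow bound $P(t) \le f\,(S_0 - S(t))$ caps the achievable yield at
$100 f \cdot \mathrm{MW}_S/\mathrm{MW}_P$, which the tests verify. The
compound registry ships as an editable CSV
(`inst/extdata/compounds.csv`); formula weights are ordinary (not
monoisotopic) masses.

## Relative expression (2^−ΔΔCt)

`delta_delta_ct()` implements the Livak convention with a fixed
aggregation order: technical replicates are averaged to one Ct per (gene,
condition, biological replicate); ΔCt is taken against the reference gene
within each stratum; ΔΔCt subtracts the mean control-condition ΔCt; the
per-replicate fold changes $2^{-\Delta\Delta Ct}$ are then averaged over
biological replicates with their SD. The reference gene (default 16S rRNA)
has fold change exactly 1.0 in every condition by construction, and adding
any constant to all Ct values of a stratum cancels — both identities are
tested. The default control condition is growth on glucose, the standard
non-inducing carbon source. Primer-efficiency correction (Pfaffl) and
significance testing are deliberately out of scope;
`expression_call()` provides only the conventional "more than twofold"
flag.

## Synthetic data

`simulate_timecourse()` emulates the degradation study design the package
targets: sampling on days 0, 1, 3, 5, 7, 9, 11, 13, 15 with triplicate
flasks, parent starting at 60 mg L⁻¹, additive Gaussian measurement noise
truncated at zero (defaults 1 mg L⁻¹ parent, 0.5 mg L⁻¹ intermediate —
realistic UPLC repeatability at these concentrations), and an intermediate
LOD of 0.02 mg L⁻¹, a typical instrument detection limit for aromatic
acids on a UPLC-PDA system. A lognormal noise option exists for robustness
experiments. `simulate_ct_table()` generates Ct tables with known fold
changes by offsetting target Ct by $-\log_2(\mathrm{fold})$ under
treatment.

What the generator does *not* emulate — and therefore what passing tests
cannot show about real data: sorption and abiotic losses of the parent,
lag phases and growth-linked kinetics, replicate-level (flask) random
effects, heteroscedastic noise rising with concentration, and correlated
errors between the parent and intermediate channels measured in the same
run. Recovery of generating parameters under the generator's own noise
model demonstrates internal consistency of the estimator, not robustness
to model misspecification.

## Worked example

```{r example}
truth <- kinetic_params(k_tot = 0.142, f = 0.4437, k2 = 0.150, S0 = 60)
half_life(truth$k_tot)
intermediate_peak(truth)

d <- simulate_timecourse(truth, design_spec(noise_sigma_parent = 2,
                                            noise_sigma_intermediate = 1,
                                            seed = 1))
fit <- fit_branched_model(d)
fit
boot <- parametric_bootstrap(fit, n = 500, seed = 2)
boot
branching_robustness(boot)
molar_yield_percent(23.0, "DIPA", 47.3, "pyrene")
```

## Limitations

* The branched model has a single tracked intermediate; flux through
  untracked channels is only visible as $1-f$.
* Percentile intervals are first-order accurate; for very small designs or
  near-boundary $f$ they can under-cover, which is why coverage is checked
  empirically rather than assumed.
* LOD handling is row-wise exclusion or LOD/2 substitution, not a censored
  likelihood; with heavy censoring of the intermediate tail, $k_2$
  estimates will lean on the few quantified points.
* The qPCR module assumes perfect (100%) amplification efficiency, as the
  2^−ΔΔCt method itself does.
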