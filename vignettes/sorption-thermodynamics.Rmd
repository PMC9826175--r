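---
title: "Desorption thermodynamics of starchy products: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desorption thermodynamics of starchy products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorptherm)
```

## The problem

Drying is the dominant energy cost in processing starchy roots such as
cassava into flour or starch. How much energy it takes to remove a kilogram
of water depends on how tightly that water is bound to the solid matrix,
which changes as the product dries: the last water is bound far more
strongly than the first. The quantity that captures this is the **isosteric
heat of desorption** `Qst(M, T)` — the heat required to desorb water at
constant moisture content `M` — and its excess over the latent heat of pure
water, the **net isosteric heat** `qst = Qst − Lv`.

`qst` is not measured directly. It is derived from **desorption isotherms**:
curves of equilibrium moisture content (EMC, kg water per kg dry matter)
against equilibrium relative humidity (ERH, a decimal equal to water
activity) at several temperatures. This package implements the full chain
from isotherm records to dryer energy efficiency:

1. fit the four three-parameter sorption equations of the ASAE D245
   standard (modified Chung–Pfost, Halsey, Henderson, Oswin) to the data;
2. derive `qst(M, T)` analytically from the fitted equation via the
   Clausius–Clapeyron relation, and the differential enthalpy `dH(M)` and
   entropy `dS(M)` via van't Hoff regression;
3. test enthalpy–entropy compensation with the Krug procedure, which
   decides whether the fitted equation's thermodynamic implications are
   statistically meaningful at all;
4. feed `Qst` into a per-interval energy-efficiency profile of a batch
   dryer.

A synthetic-data generator emulates the factorial study design this kind of
analysis assumes, so every stage is testable without access to laboratory
data.

## The sorption equations

All four families express ERH as a closed form in `M` (decimal dry basis)
and temperature `T` (°C), with three parameters `p1, p2, p3`:

| family | ERH = |
|---|---|
| modified Chung–Pfost | `exp(−(p1/(T+p3))·exp(−p2·M))` |
| modified Halsey | `exp(−exp(p1+p2·T)·(100·M)^(−p3))` |
| modified Henderson | `1 − exp(−p1·(T+p2)·M^p3)` |
| modified Oswin | `(1 + ((p1+p2·T)/M)^p3)^(−1)` |

Two conventions deserve a note, because typeset versions of these equations
circulate with ambiguous signs and scalings. We take the Halsey moisture
argument as *percent* dry basis (`100·M`) and the Henderson exponent as
`+p3`. Both choices are validated at run time: with published pooled-fit
parameter sets for cassava products, they produce mid-range sigmoidal ERH
values (e.g. Henderson ERH(0.10, 25 °C) ≈ 0.218), whereas the alternative
readings collapse to ERH ≈ 1 everywhere, which no measured isotherm shows.

Each family has a closed-form inverse (`predict_emc()`), used by the
generator, and a closed-form temperature derivative of `ln ERH`
(`dlnerh_dtemp()`), which is what the Clausius–Clapeyron relation needs:

```
qst(M, T) = R · Tabs² · ∂ln(ERH)/∂T,   Tabs = T + 273.15.
```

Parameter-domain violations (e.g. `T + p3 ≤ 0` for Chung–Pfost) raise
errors rather than returning NaN, so the fitter rejects invalid steps
explicitly. The Celsius–Kelvin offset is fixed at 273.15 K; using 273 would
change `qst` by under 0.1 %.

```{r models}
cp <- reference_spec("chung_pfost")
cp
predict_erh(cp, emc = 0.10, temp_c = 25)
j_mol_to_kj_kg(net_isosteric_heat(cp, emc = c(0.10, 0.25), temp_c = 25))
```

## Fitting

`fit_sorption()` estimates the parameters by nonlinear least squares **on
the ERH scale**: the residual is the observed (set-point) relative humidity
minus the model ERH at the measured moisture and temperature. ERH is the
dependent variable in every family's functional form, and the standard fit
indices (R², MRPE, SEE) are defined on that scale, so the response choice
follows the indices. The alternative (EMC as response) is a non-goal.

Estimation uses the Gauss–Newton algorithm with step halving as implemented
in `stats::nls()` (relative-offset convergence criterion, default `1e-6`).
Published work in this field rarely states starting values; we use a
deterministic multi-start — a family-typical centre for starchy products
plus fixed scale perturbations, tried in a fixed order — and keep the
converged fit with the lowest residual sum of squares, so results are
reproducible without a seed. Standard errors come from the Jacobian at the
optimum (`summary.nls`).

Fit quality is reported as:

* `R² = 1 − RSS/TSS` on ERH;
* `MRPE = (100/N) Σ |obs − pred| / obs` (mean relative percentage error;
  below 10 % is conventionally a good fit);
* `SEE = sqrt(RSS / (N − 3))` (standard error of estimation; heavier weight
  on large errors).

`residual_normality()` adds a Shapiro–Wilk screen at α = 0.05 — the
standard small-sample choice — because a family can fit well by MRPE yet
leave structured residuals, which undermines the thermodynamic derivatives
taken from it. `compare_sorption_models()` fits all four families and ranks
by SEE, then MRPE.

By default fits pool products, temperatures and replicates into one dataset
per family: product effects on the isotherms of milled starchy products are
tiny (η² ≈ 0.001 in the factorial ANOVA below), and pooling matches how
reference parameter sets for cassava are reported. Per-product fits are a
`dplyr::group_split()` away for users who need them.

```{r fit}
d <- simulate_isotherms(study_design(seed = 1))
cm <- compare_sorption_models(d)
cm[, c("family", "r2", "mrpe", "see", "good_fit")]
```

## Thermodynamic analysis: two routes, kept separate

The van't Hoff route regresses `ln ERH` on `1/Tabs` at fixed moisture: the
slope is `−dH/R`, the intercept `dS/R`. It yields one (temperature-averaged)
`dH` and `dS` per moisture level and feeds the compensation analysis. The
analytic route differentiates the fitted equation directly and keeps the
temperature dependence of `qst(M, T)`. `thermo_curves()` carries both —
`tidy(x)` for the enthalpy/entropy curve, `tidy(x, "surface")` for the
`qst` surface — because collapsing them would hide exactly the property
(temperature dependence of the isosteric heat) on which the model families
disagree most.

The regression `dH` always lies inside the min–max envelope of the analytic
`qst` over the same temperature span (the slope is a mean-value
derivative); the test suite asserts this for all four families.

`Qst = qst + Lv(T)` uses a latent heat of pure water interpolated linearly
between 44.200 kJ/mol at 20 °C and 42.030 kJ/mol at 70 °C; linearity of
`Lv` over this span is accurate to well under 0.2 %. Unit conversions
between J/mol and kJ/kg use the molar mass of water, 0.018 kg/mol, exactly.

```{r thermo}
tc <- thermo_curves(cp, emc_grid = seq(0.06, 0.28, 0.01),
                    temps = seq(25, 65, 10))
head(tidy(tc), 3)
```

For Chung–Pfost and Halsey, `dH` and `dS` grow roughly exponentially as the
product dries — the expected behaviour when the remaining water binds to
progressively stronger sorption sites.

## Enthalpy–entropy compensation and the Krug test

Across moisture levels, `(dH, dS)` pairs often fall on a line,
`dH = Tβ·dS + dGβ`: the compensation pattern. The slope `Tβ` is the
isokinetic temperature; the intercept `dGβ` the Gibbs free energy at it.
Krug's objection is that such lines arise spuriously from error
propagation, and his remedy is the comparison implemented here: the
compensation is accepted only when the harmonic mean of the experimental
temperatures, `T_hm = n / Σ(1/Tabs_i)`, falls **outside** the 95 %
confidence interval of `Tβ`. `Tβ > T_hm` means the process is
enthalpy-controlled; `Tβ < T_hm`, entropy-controlled; `T_hm` inside the
interval is inconclusive.

Design choices here: the regression direction is `dH` on `dS` (the form in
which the compensation relation is written; orthogonal regression would
acknowledge that both variables are estimated, but is not the procedure the
field's reports describe); the confidence interval is the standard OLS
slope t-interval at fixed α = 0.05; and the default moisture grid is
0.06–0.28 kg/kg in steps of 0.01, covering the span over which cassava
desorption data are typically measured (about 0.057–0.268 kg/kg). Pairs
derived from a *single* parametric isotherm are near-exactly collinear, so
a near-zero interval width there is expected structure, not a numerical
defect.

```{r comp}
comp <- compensation_analysis(cp)
comp
```

For the reference Chung–Pfost surface, `Tβ ≈ 429 K (≈ 156 °C)` against
`T_hm ≈ 317.5 K (≈ 44.4 °C)`: a clearly enthalpy-controlled desorption, and
a near-zero `dGβ` meaning the system would be at equilibrium at the
isokinetic temperature.

## Factorial ANOVA

`emc_anova()` decomposes EMC variance into main effects of ERH level,
temperature level and product type, each categorical, with
`η² = SS_factor/SS_total`. Replicates are averaged per design cell first,
so the 4 × 5 × 6 factorial analyses 120 values and leaves 107 residual
degrees of freedom. Interactions are excluded — in these data they are
routinely insignificant — and with a balanced complete design the
sequential sums of squares equal the marginal ones, so the term order is
inert (asserted by a test). Empty cells raise an explicit unbalanced-design
error rather than silently switching to a different SS type.

```{r anova}
emc_anova(d)
```

## Dryer energy efficiency

From a moisture time series `X(t)` of a batch with initial weight `W_ini`
and initial moisture `X_ini`, the evaporation rate over an interval is
`m_w = (W_ini/(1+X_ini))·(ΔX/Δt)` and the instantaneous efficiency is

```
η = m_w · (Qst / Ww) / Q_in
```

with `Q_in` the input energy rate (kJ/h). Published forms of this ratio
sometimes multiply by `Ww` instead of dividing; that form is dimensionally
inconsistent, and the division reproduces the energy-efficiency magnitudes
(≈ 41 % for fixed-bed cassava dryers) cited in the applied literature. The
multiplied form remains available behind `as_printed = TRUE` for
auditability. `Qst` is evaluated at the interval-mean moisture — the
within-interval evaluation point is otherwise arbitrary, and the midpoint
keeps the profile exact for linear segments.

```{r dryer}
run <- simulate_drying_run(W_ini = 100, X_ini = 0.87, X_eq = 0.05, k = 0.25,
                           temp_c = 45, Q_in_rate = 33000, n_points = 9)
efficiency_profile(run, cp)
```

## What the synthetic generator does and does not emulate

`simulate_isotherms()` reproduces the statistical structure of a factorial
desorption study: 4 products × 5 temperatures (25–65 °C) × 6 relative
humidity setpoints (0.85 down to 0.10 by 0.15) × 2 replicates; a true
isotherm surface (default: the reference Chung–Pfost parameters for
cassava, whose noise-free EMC span 0.051–0.252 kg/kg matches the measured
range); additive per-product shifts sized so product type explains about
0.1 % of total EMC variance; and Gaussian noise on **EMC** with sd
0.008 kg/kg, the level implied by residual mean squares reported for
gravimetric sorption systems.

Noise is placed on EMC because that is the measured quantity (a load cell
weighs the sample; the humidity is a controlled setpoint), even though the
fitting residual is on ERH. This deliberately exercises the
errors-in-variables gap between how such data are generated and how they
are conventionally fitted. One visible consequence: EMC noise inflates
*relative* ERH error at the dry end of the isotherm, so pooled-fit MRPE
values on synthetic data run a few points higher than those reported for
measured data at the same noise energy (the weakest family, Halsey, sits
near 17 % rather than 11 %). Passing tests on this generator therefore show
that the pipeline recovers structure under realistic noise placement; they
do not certify instrument-specific effects — equilibration kinetics, drift,
hysteresis — which are out of scope.

All randomness flows through a single integer seed (`withr::with_seed`, so
the caller's RNG stream is untouched); negative EMC draws are redrawn, and
zero-noise output lies exactly on the truth surface.

## Numerical choices and problem sizes

* Convergence: `nls` relative-offset criterion `1e-6`, max 50 iterations
  per start, `scaleOffset = 1` so zero-residual (noise-free) data converge
  cleanly.
* Inversion round-trips are exact to 1e-10 relative; analytic derivatives
  are verified against central differences (h = 1e-4 K) to 1e-6 relative on
  a 26 × 5 moisture–temperature grid.
* Degenerate inputs fail loudly: constant residual vectors (normality
  test), zero `dS` variance (isokinetic regression), empty factorial cells
  (ANOVA), re-wetting intervals (dryer profile).
* Simulation-based tests use 30–200 replicate fits and 100–150 seeded
  pipeline runs: large enough for stable rates (binomial se on a 95 % rate
  at n = 100 is about 2 %), small enough to run in seconds.

## Known limitations

* Only the desorption branch is modelled; adsorption and hysteresis are
  not.
* No GAB or other theoretical isotherms, hence no monolayer moisture or
  spreading-pressure analysis; the four empirical families are the point.
* Weighted and Bayesian fitting are not provided; the compensation
  regression ignores the estimation error in `dH` and `dS` (Krug's full
  F-test variant is not implemented).
* The dryer module is an accounting of desorption energetics, not a
  heat/mass-transfer simulation: airflow psychrometrics and costs are out
  of scope.
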