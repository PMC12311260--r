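---
title: "fenflux: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fenflux: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fenflux)
```

`fenflux` turns closed-chamber concentration series from fen paludiculture
trials into annual greenhouse-gas budgets, water-table-stratified emission
factors and nonlinear water-table response curves. This vignette is the
package's account of the science it implements: the models and their
assumptions, the tunable parameters, what the synthetic generator does and
does not emulate, and the numerical decisions that shape the results.
Everywhere the atmospheric sign convention applies: a positive flux or
balance is a release to the atmosphere, a negative one an ecosystem uptake.

## 1. Chamber fluxes

A chamber closure traps a headspace of volume $V$ over a collar of basal
area $A$. If the dry-air mole fraction changes at rate $dX/dt$, the areal
flux is

$$F = \frac{dX}{dt}\,\frac{p\,(V/A)}{R\,T},$$

the slope times the molar column of enclosed air. The slope comes from
ordinary least squares on the concentration-time points after a deadband.

Assumptions: ideal, well-mixed headspace; negligible leakage; a closure
short enough that the linear model holds (saturation from the shrinking
gradient is negligible). An exponential-saturation option exists behind
`flux_config(flux_model = "exponential")` for long closures; it reports the
slope at the start of the usable window.

Tunables (all in `flux_config()`):

* `deadband_frac = 0.10` of elapsed time, at least `deadband_min_s = 10` s —
  discards the pressure-equilibration transient after chamber placement.
* QA: `r2_min_co2 = 0.9`, `r2_min_trace = 0.75`. Fluxes within the
  near-zero bands (`±0.1` µmol m⁻² s⁻¹ CO₂, `±30` µg m⁻² h⁻¹ CH₄/N₂O) are
  exempt from the r² rule (`accepted_near_zero`): when nothing accumulates
  there is no variance for the regression to explain, and rejecting those
  closures would censor genuine near-zero exchange and bias budgets away
  from zero. Implausible magnitudes (`range_max_*`) are rejected outright.
  These thresholds are conventions of chamber practice, not measured
  constants, and are deliberately exposed in the config.
* Gas-law temperature: the chamber-internal air temperature recorded with
  the closure; ambient temperature is the documented fallback.

## 2. CO₂ partitioning

Net ecosystem exchange (NEE) splits into ecosystem respiration
(Reco ≥ 0) and gross primary production (GPP ≤ 0), NEE = Reco + GPP.
Opaque chambers observe Reco, transparent chambers NEE. Models are fitted
per *campaign* — a full measurement day — so that slow seasonal change is
carried by the parameters, not the drivers:

* Respiration (Lloyd–Taylor): $R(T) = R_{ref}\exp\!\big(E_0\,(1/(T_{ref}-T_0)
  - 1/(T-T_0))\big)$ with $T_{ref} = 283.15$ K, $T_0 = 227.13$ K fixed.
  Air temperature is the driver; the campaign needs ≥ 3 accepted opaque
  fluxes spanning ≥ 3 K.
* Light response (rectangular hyperbola):
  $GPP(Q) = -\alpha Q\, GP_{max} / (\alpha Q + GP_{max})$ fitted to
  GPP observations derived as NEE − Reco(T) from the same campaign's
  respiration fit.

These two forms are the standard chamber-modelling choices for temperate
peatland work; both are smooth, monotone in their drivers and have
parameters with direct physiological meaning (µmol m⁻² s⁻¹ for $R_{ref}$
and $GP_{max}$; K for $E_0$; µmol CO₂ per µmol photons for $\alpha$).

Between campaign midpoints each parameter is interpolated piecewise
linearly *on the parameter scale*, with constant extrapolation outside the
first/last campaign. Linearity preserves the nonnegativity bounds and
order; interpolating fluxes instead would entangle the parameter trend with
the weather on the campaign days. The continuous series is then evaluated
on the (≤ 0.5 h) meteorology and integrated with time weights; windows that
deviate from a full year are normalized to a 365.25-day year
(`period_normalize = TRUE`; the raw-window alternative is kept because the
field convention is not universal).

Fit quality is reported as Nash–Sutcliffe efficiency
($NSE = 1 - \sum(o-p)^2/\sum(o-\bar o)^2$; > 0.5 conventionally
"satisfactory"), percent bias and RMSE. Annual uncertainty comes from a
parametric bootstrap over the campaign parameter covariances (draws clipped
to the parameter bounds; singular covariances degrade to point parameters),
summarised as the half-width between the 2.5th and 97.5th percentiles.

Numerical choices: bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`, `ftol = ptol = 1e-10`) with three starts on failure
($E_0 \in \{150, 50, 400\}$; $\alpha \in \{0.03, 0.01, 0.1\}$); bounds
$R_{ref} \ge 0$, $0 \le E_0 \le 1000$ K, $0 \le GP_{max} \le 500$,
$0 \le \alpha \le 5$. Degenerate campaigns behave predictably:
temperature-independent fluxes drive $E_0 \to 0$ with $R_{ref}$ the mean
flux; NEE indistinguishable from Reco gives $GP_{max} = 0$ exactly.

## 3. Budgets, NECB and GHG balance

Weekly CH₄/N₂O fluxes are linearly interpolated between sampling dates,
constant-extrapolated to the period edges, and integrated by the trapezoid
rule (a mean-flux × time alternative sits behind `method = "mean"`). The
trapezoid on weekly sampling is the natural quadrature for a design whose
signal varies on multi-week scales; it is exact for piecewise-linear truth
and its error enters the carbon balance only through the small CH₄-C term.

$$\mathrm{NECB} = \mathrm{NEE\text{-}C} - C_{import} + C_{export} +
\mathrm{CH_4\text{-}C} \quad [\mathrm{t\,C\,ha^{-1}\,yr^{-1}}]$$

$$\mathrm{GHG} = \mathrm{NEE} - 3.66\,C_{import} + 3.66\,C_{export} +
\mathrm{GWP}_{CH_4}\,\mathrm{CH_4} + \mathrm{GWP}_{N_2O}\,\mathrm{N_2O}
\quad [\mathrm{t\,CO_2e\,ha^{-1}\,yr^{-1}}]$$

Gas/element conversions are exact mass ratios (12/44, 12/16, 28/44). The
C→CO₂e factor is deliberately the inventory-table constant 3.66 rather
than 44/12 ≈ 3.667: the reference emission-factor tables this package
reproduces are built with the rounded factor, and using 44/12 would fail
to recompose them. GWP100 sets: AR5 (CH₄ 28, N₂O 265, the current German
inventory convention) and AR4 (25, 298) for comparison with older national
factors. Dissolved organic carbon is not measured; it enters only through
the IPCC defaults at the emission-factor stage. Every budget row is
self-checked: NECB and both GHG balances must be recomputable from the
stored components to 10⁻⁸.

## 4. Emission factors

Balances are stratified by mean annual water table (time-weighted logger
mean): *rewetted* at WT ≥ −0.10 m (boundary inclusive), *moderately
rewetted* at −0.30 m < WT < −0.10 m, deeper means excluded. Reporting
columns add the IPCC off-site defaults: DOC export 0.24 (rewetted) or
0.31 (otherwise) t C ha⁻¹ yr⁻¹, and for the non-rewetted class ditch CH₄
blended by area weighting $(1-f)\,\mathrm{CH_4}_{land} + f \cdot 527$ with
$f = 0.013$. Area weighting (rather than a pure add-on) is the reading
that reproduces the published table arithmetic. Class factors are
arithmetic means with empirical 2.5–97.5 percentile brackets — the
"95th-percentile" bracket convention read as an equal-tailed 95% range,
flagged here because the published tables do not define the construction.
The GHG columns average the unrounded per-balance values; recomposing them
from rounded component means reproduces them only approximately (the
3.66-vs-44/12 discrepancy and rounding), which the tests document.

## 5. Water-table response models

Annual CH₄ is strongly right-skewed and rises steeply once the water table
approaches the surface. It is modelled as a log-link GLM with Tweedie-type
variance $V(\mu) = \mu^p$, default $p = 1.5$ (compound-Poisson territory),
optionally profiled over $\{1.1,\dots,1.9\}$ by extended quasi-likelihood —
the data rarely pin $p$ down, so it is a tunable, not an estimate. Because
annual balances can be slightly negative (small uptake), a documented shift
constant (`ch4_shift`, default 5 kg CH₄ ha⁻¹ yr⁻¹) is added before fitting
and removed on prediction; the shift trades a small low-end slope bias for
a defined likelihood, so recovery tests generate on the shifted scale.
Annual N₂O declines roughly quadratically as the water table rises; a
Gaussian GLM with square-root link captures this with a linear predictor in
WT, genus and a first-year-stand indicator (newly established stands carry
an elevated-N₂O contrast). Negative linear predictors are truncated at zero
with a warning — the fitted mean cannot be negative on the link scale.

NECB and GHG balance get a penalized cubic regression spline in WT
(basis and curvature penalty from `mgcv::smoothCon`, k = 10 knots at WT
quantiles) plus genus and management fixed effects, fitted by penalized
least squares. The smoothing parameter minimizes GCV,
$n\,RSS/(n-\mathrm{edf})^2$, over a log-spaced grid; when an interpolating
fit drives RSS to machine zero GCV is pure round-off, so ties break toward
the smoother fit. Site enters all three models as ridge-penalized dummy
offsets under one shared penalty — a fixed-effect approximation of a random
intercept that keeps the shrinkage behaviour while remaining directly
testable (at ridge 0 and λ = 0 the spline fit reproduces OLS on the basis
exactly); full mixed-model REML is intentionally out of scope.

The mitigation-optimal WT is the argmin of the predicted GHG balance on a
dense grid within the observed WT range; the carbon-sink threshold is the
driest WT at which predicted NECB crosses ≤ 0, refined by bisection.
Both are reported at reference covariate levels (genus *Carex*, one-cut
management, site offset zero) because population-level curves at a defined
reference are reproducible, whereas an unspecified averaging over levels is
not; other levels are selectable, and per-genus thresholds come from
genus-specific predictions. Optima on the range boundary and NECB curves
that never cross zero are flagged rather than reported as numbers.

## 6. The synthetic site

The generator exists so that every stage can be tested against exact
ground truth. It emulates: half-hourly meteorology with a 9 °C annual mean
(annual + diurnal sinusoids, AR(1) noise, solar-geometry PAR under
day-persistent cloudiness); mean-preserving water-table regimes spanning
moderately rewetted to flooded conditions; Lloyd–Taylor/hyperbola CO₂
truth with seasonal base rate and capacity; log-linear-in-WT CH₄ with a
summer peak and a biomass term; quadratic-in-WT N₂O with decaying
fertilization pulses; three-weekly full-day CO₂ campaigns and seven-day
trace-gas intervals; management calendars (winter cut; or summer + winter
cut with 92–143 kg N ha⁻¹ digestate at C:N 5); harvest yields inside the
observed paludiculture span (1.6–15 t DM ha⁻¹ yr⁻¹, wetter regimes
yielding more) with Corg fractions in 44.9–48.3 % DM. Closure traces are
linear ramps through the ideal-gas relation plus additive Gaussian
concentration noise (0.3 ppm CO₂, 5 ppb CH₄, 0.4 ppb N₂O by default), a
lognormal replicate-heterogeneity factor (5 %), and an optional
flux-proportional lognormal term reproducing the positive skew of field
CH₄. Closure durations default to 3 min / 13 samples (CO₂) and 60 min / 4
samples (trace gases) — common manual-chamber practice.

What it does *not* emulate — and hence what passing tests cannot show about
field data: chamber artifacts (pressure perturbations, leaks, ebullition
events), weather extremes and drift, gap-ridden loggers, vegetation
dynamics (harvest effects on GPP, senescence, weed invasion), spatial
microtopography beyond a scalar replicate factor, or between-site soil
differences. Recovery results on the generator certify the estimation
chain, not the field realism of any particular number; the synthetic
emission factors in the acceptance output depend on the configured
treatment mix and are not expected to reproduce field-derived factors.

Determinism: all draws derive from one seed through R's default
Mersenne-Twister; a fixed seed reproduces the dataset exactly, and the seed
is recorded in the truth record.

## 7. Problem sizes and defaults used in validation

The shipped validation runs use one synthetic year (17,520 half-hour
steps), four treatments × three replicates, 17 CO₂ campaigns × 9 closure
hours and 52 weekly trace-gas days per replicate; parameter-recovery
properties use 100 seeded campaigns, the response-model recoveries 50
seeded datasets of 105 balances, and the bootstraps 20–50 resamples.
These sizes make the whole suite reproducible on a single CPU in a few
minutes while keeping Monte-Carlo error well inside the asserted margins.

## 8. Known limitations

* The meteorology gap policy (linear interpolation up to `max_gap_hours =
  24`, error beyond) is a package convention; field conventions vary.
* Campaign-based reconstruction carries an irreducible interpolation bias
  when parameters change nonlinearly between campaigns (about 1–2 % of
  annual NEE at three-weekly spacing on smooth seasonal truth).
* The Tweedie fit is quasi-likelihood with fixed (or coarsely profiled)
  power, not a full likelihood; dispersion is moment-estimated.
* Ridge site offsets approximate, but are not, random intercepts; their
  shared penalty is chosen on a coarse grid jointly with the smoother's GCV.
* Soil temperature at depth, VPD, DOC fluxes and lateral carbon transport
  are not modelled; multi-year stand dynamics are outside the generator.
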