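---
title: "Modelling the temperature response of soil microbial respiration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the temperature response of soil microbial respiration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoresp)
```

## The scientific problem

Heterotrophic soil respiration — the microbial decomposition of soil
organic matter — responds strongly to temperature, and how that response
will shift under long-term warming is a central uncertainty in
carbon-cycle projections. Natural geothermal gradients offer decades- to
centuries-long warming "experiments": soil communities a few metres from
a steam-heated feature have lived at much higher temperatures than those
30 m away. A typical study design samples replicate transects running
away from the heat source, in two vegetation types (biomes) and at two
soil depths, incubates each soil at a ladder of temperatures in sealed
vials, and asks whether the *shape* of the temperature response — not
just its magnitude — has adapted to the local thermal environment.

`thermoresp` implements that full analysis chain: headspace CO2 to
respiration rates, per-sample curve fitting under two competing models,
derived thermal traits with uncertainties, and the treatment-level
statistics, together with a synthetic-study generator so the whole chain
can be validated by parameter recovery.

## The models

### Macromolecular rate theory (MMRT)

MMRT extends transition-state theory with a non-zero activation heat
capacity $\Delta C_P^\ddagger$, which makes the Arrhenius plot curved
and gives enzyme-driven rates a temperature optimum:

$$\ln R = \ln\frac{k_B T}{h}
 - \frac{\Delta H_{T_0}^\ddagger + \Delta C_P^\ddagger (T - T_0)}{R\,T}
 + \frac{\Delta S_{T_0}^\ddagger + \Delta C_P^\ddagger \ln (T/T_0)}{R}.$$

The three parameters are the activation enthalpy
$\Delta H_{T_0}^\ddagger$ (J mol$^{-1}$), entropy
$\Delta S_{T_0}^\ddagger$ (J mol$^{-1}$ K$^{-1}$) at the reference
temperature $T_0$, and the heat-capacity change $\Delta C_P^\ddagger$
(J mol$^{-1}$ K$^{-1}$), negative for enzymes. Derived traits:

- $T_{opt} = (\Delta H_{T_0}^\ddagger - \Delta C_P^\ddagger T_0)/(-\Delta C_P^\ddagger - R)$,
  the rate maximum, defined for $\Delta C_P^\ddagger < -R$;
- $T_{inf} = (\Delta H_{T_0}^\ddagger - \Delta C_P^\ddagger T_0)/(-\Delta C_P^\ddagger + \sqrt{-\Delta C_P^\ddagger R})$,
  where the absolute sensitivity $dR/dT$ peaks; always below $T_{opt}$;
- $R_{25} = \exp(\ln(k_B T_0/h) - \Delta G_{T_0}^\ddagger / R T_0)$, the
  rate at 25°C, identically the rate curve evaluated at $T_0$.

Relative temperature sensitivity is reported as
$Q_{10} = \exp\{10\,[\Delta H^\ddagger(T) - 5\Delta C_P^\ddagger]/(R T^2)\}$
with $\Delta H^\ddagger(T) = \Delta H_{T_0}^\ddagger + \Delta C_P^\ddagger (T - T_0)$.
This printed form is a local approximation whose grouping cannot be
pinned down unambiguously from typeset sources; we therefore also expose
`q10_exact()`, the literal forward rate ratio
$\exp[\ln R(T{+}10) - \ln R(T)]$, and test that the two agree within 15%
over 283–313 K for field-plausible parameters. The relative sensitivity
$d\ln R/dT$ (`relative_sensitivity()`) is the pool-size-free alternative.

### Lloyd & Taylor

The empirical comparator is
$\ln R = \ln R_{10} + E_0\,(1/56.02 - 1/(T - 227.13))$, with
$R_{10}$ the basal rate at 10°C and $E_0$ (K) the sensitivity
parameter, and $Q_{10} = \exp[10 E_0/(T - 227.13)^2]$. The constants
227.13 K and 56.02 K are the canonical zero-rate offset and reference
span; with them the bracket vanishes at exactly 283.15 K, so $R_{10}$
really is the 10°C rate. Published renderings of these constants are
frequently garbled by typesetting; both are configurable in
`thermo_constants()`.

### Units and temperature conventions

All internal computation is SI (J mol$^{-1}$, K); reporting converts to
kJ mol$^{-1}$ and °C, matching field-table conventions. The data layer
(CSV columns, curves, fits) speaks °C throughout and converts once; the
low-level model functions take Kelvin, because they are the physics
layer. $T_0$ = 298.15 K so the °C↔K conversion is exact; the 0.15 K
difference from a rounded "298 K" is far below fit noise. Table
conventions elsewhere sometimes print heat-capacity values in J rather
than kJ; we treat kJ mol$^{-1}$ K$^{-1}$ as authoritative for
field-scale values since only kJ-scale inputs give plausible optima
through the $T_{opt}$ formula.

## From vial readings to rates

One incubation seals soil of known dry mass in a 12 mL vial and records
headspace CO2 (ppm) at the start and end. `respiration_rate()` converts
the concentration rise to moles by the ideal gas law at the incubation
temperature and divides by soil mass and duration, yielding
µmol CO2 g$^{-1}$ min$^{-1}$. Two choices are deliberate:

- **Headspace volume.** Protocols rarely report the gas volume; by
  default it is modelled as vial volume minus soil volume at a bulk
  density of 0.9 g cm$^{-3}$ (appropriate for pumice soils), and an
  explicit `headspace_volume` column overrides the model. Pressure
  defaults to 101325 Pa; both are configurable.
- **Negative rates** (final below initial reading) are kept in the rates
  table as data but excluded point-wise from log-scale fitting.

Soil mass follows the protocol's temperature bands (4 g below 20°C, 3 g
for 20–30°C, 2 g for 30–38°C, 1 g at and above 38°C), with the bands
closed on the left since the printed ranges overlap at their edges.

A curve enters fitting only with at least 5 positive-rate points
(`build_curves()`): one more than the largest parameter count plus the
residual variance, so AICc is defined for every kept curve. A fully dead
sample — no CO2 at any temperature — is the canonical discard.

## Fitting and model comparison

Both models are exactly linear in their parameters on the log-rate
scale, so both fits are closed-form ordinary least squares — no starting
values, no convergence failures. The MMRT response is
$y = \ln(\text{rate}) - \ln(k_B T/h)$ against the three basis columns
for $\Delta H_{T_0}^\ddagger$, $\Delta C_P^\ddagger$ and
$\Delta S_{T_0}^\ddagger$. Fitting Lloyd & Taylor on the same log scale
is a deliberate choice: it makes the residual variances, and hence the
AICc values, directly comparable. AICc counts the residual variance as a
parameter ($k = 4$ for MMRT, $k = 3$ for Lloyd & Taylor); conventions
differ between software, so ours is stated. Errors are assumed
homoscedastic on the log scale (no weights), consistent with
multiplicative lognormal measurement noise on positive rates.

Trait standard errors use the delta method: the analytic gradient of
each trait's closed form with respect to the parameters, propagated
through the OLS covariance. $T_{opt}$ and $T_{inf}$ have zero partial
derivative with respect to $\Delta S_{T_0}^\ddagger$, and $R_{25}$ with
respect to $\Delta C_P^\ddagger$; tests confirm the delta-method errors
against a parametric bootstrap within 15%. When a fitted
$\Delta C_P^\ddagger \ge -R$ the optimum does not exist; the fit is
retained with `NA` traits and a warning rather than failing, since noisy
curves without an in-range optimum are data. A fitted $T_{opt}$ above
the highest measured temperature is an extrapolation and carries a wide
standard error; it is reported as is.

Treatment-level $Q_{10}$ envelopes (`q10_envelope()`) evaluate each
replicate fit's $Q_{10}$ on a 5–45°C grid (1°C steps) and report the
across-replicate mean ± SE at each temperature.

## The synthetic-study generator

The generator exists so that every downstream stage can be tested
against known truth. Its defaults emulate a realistic geothermal-gradient
study, fixed once and not revisited:

- **Design**: 3 transects × 3 distances (2, 10, 30 m) × 2 biomes
  (grassland, kānuka shrub) × 2 depths (0–50, 50–100 mm) = 36 points;
  22 incubation temperatures, 4–46°C in 2°C steps. (Field protocols
  quoting "22 temperatures, ~4–48°C in 2°C increments" enumerate 23
  values; 4–46 keeps the count at 22 and is overridable.)
- **Environment**: mean environmental temperature (MET) anchored to
  field cell means spanning 16.9–48.3°C, decreasing with distance from
  the heat source within every transect (enforced by ordering),
  transect-level offsets (SD 1.5°C) plus point noise (SD 1°C); pH
  declining with MET (−0.03 pH/°C) around biome references 4.58
  (grassland) and 3.40 (kānuka); carbon lognormal (sdlog 0.35) around
  biome-by-depth medians (11.1, 4.3, 22.2, 5.4 %); nitrogen tied to
  carbon through biome C:N (13.7, 21.8); water content uniform on
  0.20–0.42 m³ m$^{-3}$, independent of everything. All covariates are
  truncated to the observed field envelope, so simulated soils stay
  within realistic ranges by construction.
- **Traits**: $T_{opt} = 50 + 1.3\,C\; (+\,0 \cdot \text{MET}) +
  \mathcal N(0, 5^2)$ °C — a carbon effect of 1.3 °C per %C and a null
  MET effect, the structure the recovery tests probe;
  $\Delta C_P^\ddagger \sim U[-3.4, -1.1]$ kJ mol$^{-1}$ K$^{-1}$;
  $R_{25} = (2 + 1.5\,C)\cdot e^{\mathcal N(0, 0.25^2)}$, reproducing
  the observed 4–54 µmol g$^{-1}$ min$^{-1}$ span over the carbon range.
  Traits convert to parameters through the exact algebraic inversion
  `invert_traits()`, so the planted optimum is recovered identically by
  the closed form.
- **Incubations**: measured temperature = target + $\mathcal N(0,
  0.25^2)$ (a ±0.5°C thermostat); per-reading rate noise is
  multiplicative lognormal with $\sigma_{\log} = 0.15$; ambient starting
  CO2 $\mathcal N(410, 10^2)$ ppm; durations aim at a measurable
  headspace rise and are clipped to the protocol window 52–169 min.
  With rates on the µmol g$^{-1}$ min$^{-1}$ scale a fixed ppm target
  and that window cannot both bind, so the window wins and the ppm rise
  floats; what matters for validation is that final readings are the
  *exact inverse* of `respiration_rate()`, giving machine-precision
  recovery when all noise is zero.
- **Determinism**: one global seed drives a hierarchical stream (design
  → environment → traits → incubations → dead-sample choice), so stages
  are reproducible in isolation and a study is byte-for-byte identical
  across runs.

What the generator does *not* emulate: instrument drift, non-linear
headspace accumulation, spatial autocorrelation beyond the transect
intercept, seasonal MET dynamics, or any community-composition data.
Passing recovery tests therefore demonstrate the correctness of the
estimation chain under the stated noise model, not robustness to every
feature of real field data.

## Treatment statistics

- `summarize_treatments()` / `marginal_means()`: cell means ± SE
  (sd/√n), with marginals as *unweighted means of cell means* — the
  appropriate convention for a (near-)balanced design, and the one under
  which published marginal summaries reproduce from their printed cells.
- `three_way_anova()`: sequential (Type I) sums of squares in the fixed
  order biome, depth, distance, then interactions. On balanced data the
  order is immaterial (tested); one discarded sample unbalances the
  design slightly, so the order is fixed and stated.
- `backwards_stepwise()`: starts from the full three-way-interaction
  model of MET, water content and carbon (pH, N and C:N are excluded
  from the default full model because they are collinear with MET and
  C), and repeatedly drops the least-significant droppable term by
  per-term F-test at α = 0.05, respecting marginality via
  `stats::drop1()`. The full elimination trace is returned so either
  stopping convention can be audited. A caution we quantify in the
  tests: backward elimination retains the best-looking of ~7 null terms,
  so its familywise null retention is roughly 25–30%, not α — a single
  run's retained set should be read accordingly, and the elimination
  trace consulted. When interactions survive, a covariate's main-effect
  coefficient is its slope at zero of the interacting covariates — far
  outside the data — so effect sizes should be summarised with
  `marginal_slope()`, the model-implied slope averaged over the
  observed data.
- `lmm_random_intercept()` / `lmm_compare_random()`: transect
  random-intercept model fitted by ML (not REML, so AICc is comparable
  across fixed-effect structures) via `nlme::lme`, with $k$ = fixed
  effects + 2 variances; compared against the fixed-only OLS fit.

## Problem sizes and numerical choices

The validation suite works at the study's native scale: 36 samples × 22
temperatures per replicate study; 20 replicate studies for the recovery
checks; 200 replicates for interval-coverage checks; 1000 random
parameter sets for the closed-form-versus-brute-force trait checks
(coarse 0.5 K scan then 0.001 K refinement). Closed-form OLS makes each
fit microseconds, so the whole chain validates in seconds. Degenerate
inputs fail loudly: all-equal temperatures (singular design), fewer than
5 positive rates, temperatures at or below the Lloyd & Taylor offset,
AICc with $n \le k + 1$.

## A worked run

```{r example}
cfg <- pipeline_config(seed = 1)
res <- suppressMessages(pipeline_all(cfg, out_dir = tempdir()))
nrow(res$fit$fits)                      # fitted curves (one dead sample)
head(res$fit$fits[, c("sample_id", "dCp_kJ", "t_opt_C", "t_opt_C_se")])
sw <- res$stats$t_opt_C$stepwise
sw$retained
```

The recovered carbon slope on fitted $T_{opt}$ can be compared to the
generator's configured 1.3 °C per %C; across 20 seeded replicates the
mean recovered slope is unbiased (the repository's
`scripts/acceptance.R` recomputes it from scratch).

## Known limitations

- Fitted optima far above the measured temperature range are
  extrapolations; their heavy-tailed errors propagate into the
  environment regressions, and occasionally promote spurious interaction
  terms in backward elimination.
- The AICc margin between MMRT and Lloyd & Taylor depends on where the
  true optimum sits relative to the measured range: with the optimum
  well inside it, MMRT wins essentially always; with optima far above
  the range the two models are locally similar and the comparison is
  noise-dominated at realistic measurement error.
- No hierarchical (multi-curve) fitting: each sample is fit
  independently, as in standard practice.
- The stepwise procedure is the field's convention, with the selection-
  inflation caveat above; it is a description tool, not a guarded
  inference procedure.
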