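---
title: "Chamber fluxes and community metabolism: models, conventions, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chamber fluxes and community metabolism: models, conventions, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benthicflux)
```

## The measurement model

A static benthic chamber traps a known water volume and a small air
pocket over a known sediment area. Two largely independent measurements
come out of one deployment.

**Gas accumulation.** If the sediment–water system emits a gas at a
constant areal rate, the headspace mixing ratio grows linearly in time.
`fit_slope()` estimates that growth by ordinary least squares (with two
samples the slope degenerates to the difference quotient and r² = 1 by
construction), and `compute_flux()` converts it with the ideal gas law:
the headspace holds n = PV/(RT) moles of air, a mixing-ratio slope of
1 ppmv h⁻¹ therefore means n µmol of gas gained per hour, and dividing
by the basal area gives the areal flux in µmol m⁻² h⁻¹. The assumptions
are the usual chamber ones: a well-mixed headspace, negligible leakage,
constant pressure, and a flux that does not saturate over the
deployment. The r² on the whole-series fit is the diagnostic for the
linearity assumption; per-interval two-point fluxes
(`flux_by_interval()`) localise departures to a sampling interval.

**Dissolved-oxygen metabolism.** With samples at chamber closure (dusk,
t0), after the dark period (dawn, t1) and after some daylight (midday,
t2), the DO change per hour, scaled by water volume over area and by
the 32 g mol⁻¹ molar mass of O₂, gives areal oxygen rates
(`hourly_rate()`). The dark interval measures community respiration CR;
the light interval measures net community production NCP (production
minus respiration); gross primary production is GPP = CR + NCP. Daily
budgets (`daily_metabolism()`) scale hourly GPP by the photoperiod,
hourly CR by 24 h, and close with NCP_daily = GPP_daily − CR_daily.

## Sign conventions — an explicit choice

CR is carried as a **negative** number (oxygen consumption), exactly as
such values are reported in the chamber literature this package follows
(e.g. a daily CR of −3.50 mmol C m⁻² d⁻¹). Under that convention the
two budget identities

* GPP = CR + NCP (hourly), and
* NCP = GPP − CR (daily)

are plain signed arithmetic, and the daily identity yields
NCP = GPP + |CR|. Note this differs from the textbook formulation
NCP = GPP − |R|: with signed CR, daily NCP exceeds daily GPP whenever
respiration is nonzero. We keep the signed-arithmetic form because it
is internally consistent and reproduces published worked numbers
exactly (see `test-acceptance.R`); users wanting the textbook quantity
can compute `gpp_daily + cr_daily` themselves. A related consequence
for synthetic data: if a generator encodes a dark DO slope r (< 0) and
a light slope p + r, the recovered triple is CR = r, NCP = p + r and,
via the identity, GPP = p + 2r — not p. Our recovery tests assert
exactly that.

The time denominators in the rate equations are positive elapsed times
(t_later − t_earlier); any notation suggesting otherwise would flip
every sign and contradict the reported values.

## Tunable parameters

| parameter | units | default | why |
|---|---|---|---|
| `R_gas` | atm m³ K⁻¹ mol⁻¹ | 8.205746e−5 | standard value; the atm/L/µmol unit chain needs it in m³ |
| `P_atm` | atm | 1 | sea-level deployments |
| `PQ`, `RQ` | mol/mol | 1 | widely used in seagrass work; makes O₂ rates equal C rates |
| `SGWP_CH4` | — | 45 | conservative low end of the 45–96 literature range |
| trophic `threshold` | mmol C m⁻² d⁻¹ | 0 | standard metabolic-balance boundary; a stricter NCP > 1 criterion appears in the literature and is available via `threshold = 1` — neither is asserted as correct |
| `alpha` | — | 0.05 | conventional test level, configurable |
| dark/light mapping | labels | t0→t1 dark, t1→t2 light | dusk/dawn/noon schedule; configurable for other schedules |

Geometry (basal area, headspace volume), water volume and photoperiod
are required inputs, not inferences: the air-pocket volume cannot be
derived from tube length, and the water phase used for metabolism is
physically distinct from the gas headspace used for fluxes — conflating
the two volumes would be dimensionally legal and physically wrong.

## What the simulator emulates — and what it does not

`simulate_study()` generates a three-area (one bare, two vegetated),
three-chambers-per-area, 18-h deployment sampled at 0, 12 and 18 h,
with:

* linear headspace accumulation whose slope is the exact inverse of
  the flux equation, plus additive i.i.d. Gaussian noise (0.5 ppmv by
  default) — the simplest error model consistent with OLS slope
  estimation;
* DO following a piecewise-linear dark/light trajectory implied by a
  true respiration r (−0.14 mmol O₂ m⁻² h⁻¹ by default) and gross
  production p (0.35), plus Gaussian noise (0.05 mg L⁻¹, Winkler-level
  precision), floored at 0;
* a diel temperature sinusoid spanning 24.2–33.6 °C, the range typical
  of shallow tropical intertidal water;
* CH₄ non-detection: a sample whose measured concentration does not
  exceed the detection limit (3 ppmv by default) is reported `ND`.
  With ambient CH₄ at 2 ppmv and zero true flux, bare-sand chambers
  stay below the limit; vegetated chambers accumulate past it by the
  second sample. Detection is a per-sample property of the measured
  value, so at high noise an occasional bare-sand sample can cross the
  limit — tests that assert a *sub-detection* world therefore use a
  noise level at which the limit sits many standard deviations above
  ambient.

Defaults not printed in any source were fixed once at field-plausible
values: a 30-cm-diameter tube (0.0707 m²), a 1-L air pocket, 50 L of
enclosed water, 12-h tropical photoperiod, 420 ppmv ambient CO₂ /
2 ppmv CH₄, 7 mg L⁻¹ DO at closure; r and p were back-computed from
published daily rates of the system the defaults emulate. With
Winkler-level DO noise and this geometry, *single-chamber* hourly rates
are noise-dominated (the 12-h dark DO change is ~0.08 mg L⁻¹ against
0.05 mg L⁻¹ sample noise); recovery is therefore a statement about
replicate means, which is exactly how the tests phrase it (200-seed
means within 2 SE of truth). A green simulation test establishes that
the estimators invert the generator — it does not establish chamber
linearity, leak-tightness or any other property of real field data.

## Numerical and statistical choices

* Whole-series fluxes use the OLS slope over all (≥3) detected points,
  not the mean of interval slopes; the temperature average uses the
  fitted span, per-interval fluxes use per-interval windows, and an
  empty window falls back to the nearest reading.
* Negative slopes are reported as negative fluxes (uptake), never
  clipped; clipping would bias group means upward.
* Non-detects and insufficient-point series yield a `status` field, not
  an exception, and are excluded from group means (`n_excluded` is
  reported) — never imputed as zero.
* ANOVA is the classical sums-of-squares decomposition; Tukey HSD uses
  the Tukey–Kramer statistic with `ptukey`, matching
  `stats::TukeyHSD`. The post-hoc procedure is a package choice (the
  standard all-pairs follow-up); MANOVA on (GPP, CR, NCP) is
  deliberately not provided — per-metric one-way ANOVAs are reported
  instead.
* The normality screen is Shapiro–Wilk with a single log-transform
  fallback, available only when all values are positive; the transform
  actually applied is part of the output.
* Worked-example tolerances follow printed precision: values published
  to 3 decimals are checked to ±0.002, values published to 2 decimals
  to ±0.015 (three half-ulps: two rounded inputs and one rounded
  reference).

## Known limitations

* No water–air gas-exchange (k600) modeling, no carbonate-system
  chemistry, no DIC/alkalinity metabolism, no P–I curve fitting, no
  mixed-effects or repeated-measures structure, no sediment
  carbon-stock or burial-offset accounting.
* An 18-h deployment under-samples the full diel cycle; daily budgets
  extrapolate the dark rate to 24 h.
* The simulator has no mechanistic sediment chemistry and no
  tide-driven exchange; its noise is i.i.d. Gaussian by construction.
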