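---
title: "Methods: biometric carbon budgets, age trends and rotation calculus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biometric carbon budgets, age trends and rotation calculus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`standflux` implements a biometric/chamber-based estimate of the annual net
ecosystem production (NEP) of managed boreal forest stands, the aggregation
of a stand chronosequence into age trends, and the carbon calculus of
rotation forestry. This vignette documents the model, its assumptions, the
parameters that matter, the numerical choices, and what the synthetic test
landscape does and does not demonstrate.

## The budget model and its assumptions

NEP is computed as `NPP − RH`, with both presented as positive fluxes and
NEP positive for a net C sink. NPP splits into tree (`NPP_t`) and understory
(`NPP_u`) production; RH into soil (`RH_s`) and dead-wood (`RH_dw`)
heterotrophic respiration. These identities are enforced exactly on every
budget the package emits (`check_budget_identities()`), and all component
fluxes are constrained non-negative — only NEP may change sign.

The biometric approach carries assumptions worth stating:

* **Allometry.** Single-tree biomass follows the DBH-only family
  `ln B = a + b·d/(d+c)` per species and component (stem, branches, foliage,
  coarse roots). Height terms are omitted; coefficients are configuration,
  and the shipped YAML values are synthetic placeholders in realistic ranges
  — users must substitute regional equations before interpreting absolute
  pools.
* **Production accounting.** Trees that die between inventories contribute
  their biomass at death to NPP (the growth happened) while simultaneously
  entering the dead-wood pool. Trees that disappear between inventories are
  treated as harvest removals and excluded entirely — their removal-year
  growth is unknown, and counting the pool loss as negative production would
  conflate harvest with mortality. Recruits entering the ≥3 cm inventory
  threshold are counted at full biomass, a small overestimate of their
  production in the recruitment year.
* **Carbon fractions.** Live biomass and litter are 50% C by dry mass; dead
  wood uses decay-class-specific density ratios and C fractions. Losses to
  herbivory, volatile organics and root exudation are assumed negligible.
* **Understory.** Herb production equals August peak biomass; shrub, moss
  and lichen production equals the June→August pool increase, floored at
  zero per functional type (a seasonal decrease is not negative
  production). The floor introduces a small positive bias under measurement
  noise — intrinsic to the pool-difference convention, not a bug.
* **Fine-root partitioning.** Ingrowth cores integrate total fine-root
  production. In recent clear-cuts (≤ ~7 yr after harvest) tree fine roots
  are assumed negligible, so the clear-cut ratio `r_u = BNPP_fr / ANPP_u`
  is pure understory; holding `r_u` constant across the landscape then
  splits `BNPP_fr` everywhere, with `BNPP_u` capped at `BNPP_fr` so the
  tree share is never negative. Mass is conserved exactly in the split.
* **Soil respiration.** Trenched-plot chamber fluxes are assumed to be
  heterotrophic only; negative chamber slopes are clamped to zero. The
  temperature response is fitted to soil temperature alone — no moisture
  term — and one response per plot is fitted to all of that plot's
  campaigns across the study years.
* **Dead wood.** Annual mass loss of a pool with rate constant `k` is
  `pool·(1 − e^(−k))` (the exact one-year solution of single-exponential
  decay); a `linear` config switch gives plain `pool·k`, which differs by
  <2% for the small k typical of boreal dead wood. All decomposed mass is
  treated as respired (no fragmentation/leaching split).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| plot radius | 10 | m | inventory plot geometry; scales pools to area |
| min inventory DBH | 3 | cm | census threshold; smaller trees enter via imputation/understory |
| litter trap area × count | 0.25 × 3 | m² | trap-to-ground scaling of litterfall |
| ingrowth core diameter / span | 10 cm / 1.33 yr | — | per-core area and annualization of the ~16-month installation |
| chamber height (V/A) | 0.20 | m | converts ppm s⁻¹ to µmol m⁻² s⁻¹ via the ideal gas law |
| chamber deadband | 10 | s | discards the post-closure pressure transient |
| Lloyd–Taylor T0, T_ref | 227.13, 283.15 | K | fixed by convention; only `R_ref`, `E0` are fitted — a 2-parameter fit is stable for ~10–30 campaign points |
| soil-temp gap tolerance | 5% | — | beyond this, annual extrapolation refuses rather than interpolating blindly |
| rotation horizon / step | 220 / 0.1 | yr | integration domain and trapezoid resolution for the NEP trend |

The ingrowth annualization divides by the exact installation span; the
original field protocol (installed early summer, extracted the next autumn)
does not state its annualization, so the span is configurable
(1.25–1.33 yr are both defensible).

## Numerical choices

* **Lloyd–Taylor fitting** is deterministic: closed-form optimal `R_ref`
  along a fixed `E0` grid (the model is linear in `R_ref`), plus a
  log-space linear pre-fit (the model is linear in `E0` after the
  `1/(T−T0)` transform), then Levenberg–Marquardt refinement from the best
  candidate. If refinement diverges the best grid candidate is kept; if
  everything degenerates the constant model `E0 = 0` is returned with a
  warning. The fit is validated against a brute-force grid-search oracle.
* **Age-trend fitting** minimizes squared error on the natural scale of
  `exp(b0 + b1·ln a + b2·ln a²)` by Marquardt iteration, initialized from
  the exact log-space OLS solve. Natural-scale residuals weight productive
  stands more than the log-space solve does, which matters for
  heteroscedastic flux data; the log-space solution is the deterministic
  fallback. RH and RH_s use an ordinary quadratic in age (a config switch
  allows ln-age), with flux predictions floored at zero.
* **The NEP trend** is never fitted directly — it is the lazily evaluated
  difference of the NPP and RH curves, so its uncertainty is inherited, not
  re-estimated.
* **Rotation calculus.** Cumulative NEP is a trapezoidal integral
  (O(step²)); because the log-quadratic curve is undefined at age 0, the
  pipeline integrates from 0 while clamping the evaluation age at 1 (NEP on
  [0,1) is treated as NEP(1)). The optimum rotation age is located where
  current NEP crosses the cumulative mean from above, on a 0.01-yr grid
  with linear root refinement; by the mean-annual-increment culmination
  identity this equals the argmax of `C(a)/a`, which the tests verify
  against a dense-grid oracle on random hump-shaped curves. The long-term
  sequestration rate defaults to half the end-of-rotation cumulative NEP —
  the time average of an idealized sawtooth of repeated rotations; the
  exact time average of the non-linear trajectory is available as
  `lcsr_mode = "sawtooth"`. The steady-state harvest rate is reported as
  `100/optimum_age` % yr⁻¹.
* **PCA** uses the correlation matrix (drivers have heterogeneous units),
  varimax rotation with Kaiser normalization (tolerance 1e-8), and a
  deterministic sign convention (largest-magnitude loading positive). Two
  components are retained by default — the biplot-ready choice; NEP and its
  components enter the primary PCA as active variables.
* **Degenerate inputs.** Age-class assignment uses midpoints between the
  observed class age ranges, so gap ages map to the nearest class;
  single-stand classes report an undefined CI rather than zero; apparent
  DBH shrinkage within tolerance is clamped to zero with a warning;
  constant-column PCA input and zero-variance correlations are refused or
  marked not-computed by name.

## The synthetic landscape: what it emulates, and what it does not

`generate_landscape()` works backwards from known truth: per-stand true
fluxes are drawn from smooth age curves — a hump-shaped tree-NPP curve and
a declining understory curve (both in the log-quadratic family), a shallow
quadratic for RH, and a small increasing dead-wood term — then every raw
measurement table is constructed so that noise-free processing reproduces
the truth exactly. Tree growth increments are solved by root-finding so the
allometric pool change hits the target; litter, clip, core and dead-wood
masses are exact inversions; chamber campaigns lie on the plot's true
Lloyd–Taylor curve evaluated at the stand's half-hourly soil-temperature
series (a seasonal + diurnal sinusoid around a 2.4 °C annual mean with
white weather noise). Defaults emulate a 50-stand design — class counts
8/9/13/14/6 from initiation (ages 5–27) to old (131–211), 28 pine / 22
spruce, 35 till / 15 sediment, three clear-cuts, one thinned stand, eight
chamber campaigns per snow-free season over three study years — with curve
levels calibrated so class means land at magnitudes typical of managed
boreal landscapes (peak NPP ≈ 390, peak NEP ≈ 175, RH ≈ 205–230
g C m⁻² yr⁻¹, dead wood < 5% of RH). The thinned stand carries the one
methodological wrinkle worth knowing: its fine-root scaling ratio comes
from the post-thinning core year, so its truth is defined as the estimand
of the method, not the pre-thinning curve.

For the thinned stand and the shrub-increment index the generator adds one
table beyond the classic field set (`shrub_index`: stand, year, relative
shoot increment) because carrying a single clip-harvest year across the
study period requires it.

What passing tests on this landscape show: the pipeline's algebra, scaling
and fitting recover a known signal exactly in the noise-free limit
(≤0.5% required, ~1e-9 achieved) and remain unbiased enough under
realistic measurement noise (10% chamber flux, 10–20% biomass channels)
that class means stay inside their propagated sampling intervals. What they
do not show: robustness to structural error — real allometry
misspecification, non-Lloyd–Taylor respiration behaviour (moisture
limitation, snow-season fluxes), spatial heterogeneity within plots,
ingrowth-core disturbance artifacts, or interannual weather far outside the
±0.3 °C year offsets simulated here. The generator has no individual-tree
competition, no spatially explicit terrain, and its driver table is only
weakly structured (biomass–LAI saturation, a negative C:N–NEP association),
so the driver analysis is exercised for correctness, not for ecological
realism.

Problem sizes were chosen to keep a full generate + analyse cycle around
15 s: 50 stands × 3 years, half-hourly soil temperature (17,520 records per
stand-year), 24 campaign fits per plot, and a 0.01-yr rotation grid; the
statistical recovery suites use 100 seeds for the chamber channel and 100
random curves for the rotation identity.

## Known limitations

* Coefficient tables ship as labelled synthetic placeholders; absolute
  budgets from the default config are internally consistent but not
  regionally calibrated.
* Interannual variability in NPP rides on a single shrub-increment index
  and a fixed fine-root ratio; year-specific allocation shifts are not
  modelled.
* No uncertainty propagation beyond class-level t-intervals: trend curves
  and rotation quantities are point estimates (no bootstrap).
* The rotation calculus values only in-forest carbon — no product pools,
  substitution, discounting, or non-CO₂ forcing.
* The printed steady-state harvest rate of such analyses is sometimes
  derived from biomass-pool bookkeeping rather than `100/rotation`; both
  conventions exist, and the package reports `100/optimum_age` while the
  sawtooth alternative covers the other reading of the long-term rate.
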