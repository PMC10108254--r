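# standflux default configuration.
#
# Literature-derived constant tables (allometric coefficients, decay-class
# wood density and carbon-fraction factors, dead-wood decomposition rate
# constants) are SYNTHETIC placeholders chosen to lie in realistic ranges for
# Fennoscandian conifer forests; replace them with values from the biomass
# equation and dead-wood literature for your region before applying the
# pipeline to real data.

carbon:
  live_c_fraction: 0.50          # g C per g dry mass, live biomass and litter

# ln(B_kg) = a + b * d/(d + c), d = DBH in cm
# components: stem, branches, foliage, coarse_roots
allometry:
  pine:
    stem:         {a: -2.30, b: 11.30, c: 14.0}
    branches:     {a: -2.90, b: 10.50, c: 12.0}
    foliage:      {a: -3.80, b:  9.50, c: 10.0}
    coarse_roots: {a: -3.20, b: 11.00, c: 15.0}
  spruce:
    stem:         {a: -2.20, b: 11.00, c: 13.0}
    branches:     {a: -2.70, b: 10.20, c: 11.0}
    foliage:      {a: -3.30, b:  9.80, c: 10.0}
    coarse_roots: {a: -3.00, b: 10.80, c: 14.0}
  birch:
    stem:         {a: -2.40, b: 11.10, c: 13.5}
    branches:     {a: -3.10, b: 10.30, c: 12.0}
    foliage:      {a: -4.00, b:  9.20, c: 10.0}
    coarse_roots: {a: -3.30, b: 10.90, c: 15.0}
  other_deciduous:
    stem:         {a: -2.50, b: 11.00, c: 13.5}
    branches:     {a: -3.20, b: 10.20, c: 12.0}
    foliage:      {a: -4.10, b:  9.10, c: 10.0}
    coarse_roots: {a: -3.40, b: 10.80, c: 15.0}

# decay-class specific factors for dead trees (classes 1-5):
# density_ratio scales live-equivalent allometric mass, c_fraction replaces
# the live 50% carbon concentration.
dead_wood:
  density_ratio: {"1": 0.95, "2": 0.80, "3": 0.60, "4": 0.40, "5": 0.25}
  c_fraction:    {"1": 0.50, "2": 0.50, "3": 0.49, "4": 0.48, "5": 0.47}

# annual decomposition rate constants k (1/yr) by species, decay class and
# position (standing / downed); downed wood decomposes faster.
decay_constants:
  pine:
    standing: {"1": 0.010, "2": 0.020, "3": 0.035, "4": 0.050, "5": 0.060}
    downed:   {"1": 0.025, "2": 0.040, "3": 0.060, "4": 0.080, "5": 0.090}
  spruce:
    standing: {"1": 0.012, "2": 0.022, "3": 0.038, "4": 0.055, "5": 0.065}
    downed:   {"1": 0.028, "2": 0.045, "3": 0.065, "4": 0.085, "5": 0.095}
  birch:
    standing: {"1": 0.020, "2": 0.035, "3": 0.055, "4": 0.075, "5": 0.090}
    downed:   {"1": 0.040, "2": 0.060, "3": 0.085, "4": 0.110, "5": 0.130}
  other_deciduous:
    standing: {"1": 0.020, "2": 0.035, "3": 0.055, "4": 0.075, "5": 0.090}
    downed:   {"1": 0.040, "2": 0.060, "3": 0.085, "4": 0.110, "5": 0.130}
# mode for annual dead-wood respiration from pool C and k:
#   one_exp  -> pool * (1 - exp(-k))   (exact one-year exponential mass loss)
#   linear   -> pool * k
rh_dw_mode: one_exp

age_classes:
  # observed age ranges per class; breaks used for classification are the
  # midpoints between consecutive ranges
  ranges:
    initiation:  [5, 27]
    young:       [31, 58]
    middle_aged: [61, 78]
    mature:      [80, 105]
    old:         [131, 211]

inventory:
  plot_radius_m: 10
  min_dbh_cm: 3
  shrink_tolerance_cm: 0.1

litter:
  trap_area_m2: 0.25
  n_traps: 3

ingrowth:
  core_diameter_cm: 10
  core_depth_cm: 30
  installation_span_yr: 1.33

chamber:
  base_m: 0.45          # square base side
  height_m: 0.20
  deadband_s: 10
  pressure_kpa: 101.325
  min_points: 5

lloyd_taylor:
  t0_k: 227.13
  tref_k: 283.15
  e0_grid: [0, 50, 100, 150, 200, 250, 300, 350, 400, 500, 600]

soil_temp:
  max_gap_fraction: 0.05

trend:
  rh_poly_in_log_age: false   # quadratic in age (default) or in ln(age)
  include_thinned: true

rotation:
  horizon_yr: 220
  step_yr: 0.1
  min_age_yr: 1
  lcsr_mode: half             # half of end-of-rotation cumulative NEP
                              # (alternative: sawtooth time-average)

# ---------------------------------------------------------------------------
# synthetic landscape design (the emulated field campaign)
# ---------------------------------------------------------------------------
design:
  years: [2016, 2017, 2018]
  baseline_year: 2015         # inventory baseline for first annual increment
  class_counts: {initiation: 8, young: 9, middle_aged: 13, mature: 14, old: 6}
  n_pine: 28
  n_spruce: 22
  n_till: 35
  n_sediment: 15
  n_clearcuts: 3              # youngest initiation stands, no trees >= 3 cm
  n_additional_old: 7         # extra old stands budgeted from BA relations
  additional_old_age_range: [169, 202]
  thin_stand: true            # one thinned initiation stand (sign handling)
  campaigns_per_year: 8
  # true age curves, exp(b0 + b1*ln(a) + b2*ln(a)^2) for NPP_t, NPP_u, RH_dw;
  # RH is quadratic in age. Calibrated so class means fall at magnitudes
  # typical of managed boreal landscapes (peak NPP ~ 390, peak NEP ~ 175,
  # RH ~ 205-230 g C m-2 yr-1).
  curves:
    npp_t:  {b0: 1.038, b1: 2.19,  b2: -0.25}
    npp_u:  {b0: 5.80,  b1: -0.45, b2: -0.01}
    rh_dw:  {b0: 0.20,  b1: 0.55,  b2: -0.03}
    rh:     {b0: 230.0, b1: -0.50, b2: 0.0025}
  splits:
    delta_b_frac: 0.45        # live aboveground biomass change / NPP_t
    litter_frac: 0.25         # litterfall / NPP_t
    fr_frac: 0.18             # tree fine-root production / NPP_t
    r_u: 0.5                  # understory below/aboveground production ratio
  year_factors: {"2016": 0.95, "2017": 1.0, "2018": 1.05}
  e0_range: [260, 360]        # true Lloyd-Taylor E0 (K) across plots
  soil_temp:
    annual_mean_c: 2.4
    seasonal_amplitude_c: 9.0
    diurnal_amplitude_c: 2.0
    noise_sd_c: 0.3
    year_offsets_c: {"2016": -0.3, "2017": 0.0, "2018": 0.3}
  noise:
    litter_cv: 0.10
    clip_cv: 0.15
    ingrowth_cv: 0.20
    flux_cv: 0.10
    dbh_sd_cm: 0.0
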