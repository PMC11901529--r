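---
title: "Model and methods: soil-water-crop-nitrogen simulation for barley yield-gap analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the governing equations, the assumptions behind them, the parameters that
matter and their defaults, the numerical choices, what the synthetic data
emulate, and the known limitations. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The problem

Spring barley on a marginal sandy soil (a five-horizon Arenosol profile
with very low water and nutrient retention) loses a large share of its
attainable yield to water and nitrogen stress. The workflow quantifies
that loss mechanistically: simulate the cropping season with a coupled
soil-water-crop-nitrogen model, then rerun it with the crop's stress
responses selectively disabled (potential, water-limited, N-limited,
actual) and read the gaps off the four yields. A fertilization sweep
(0-200 kg N ha^-1 in steps of 10, split 50/50 over the two application
dates) locates the rate beyond which yield no longer responds and prices
that response in nitrate leached below 120 cm.

## Soil water

Vertical flow solves the mixed-form Richards equation on a 1-D
cell-centered grid (150 cm domain, 1 cm cells by default, depth positive
downward, heads in cm, time in days):

$$\frac{\partial \theta(h)}{\partial t} =
  \frac{\partial}{\partial z}\Bigl[K(h)\Bigl(\frac{\partial h}{\partial z}
  - 1\Bigr)\Bigr] - S(z)$$

with van Genuchten retention and Mualem conductivity (tortuosity 0.5,
$m = 1 - 1/n$):

$$S_e = \bigl(1 + (\alpha |h|)^n\bigr)^{-m}, \qquad
  K = K_s\,S_e^{1/2}\bigl(1 - (1 - S_e^{1/m})^m\bigr)^2 .$$

The five horizons carry the laboratory parameter sets (the deepest
extends from 120 to 150 cm). The measured wilting-point water contents
are stored as an independent laboratory datum (`pwp_measured`): they are
*not* reproduced by evaluating the retention curve at pF 4.2 (for the
second horizon the curve gives roughly 0.027 against a measured 0.043),
so the package never derives one from the other.

Numerics: modified-Picard iteration (Celia-type) with a lagged-K
tridiagonal solve, dual convergence test (water-content change below
1e-4 while unsaturated, head change below 0.05 cm when saturated),
adaptive sub-daily stepping — the step is halved when the iteration
fails, when any cell moves more than 0.05 in water content, or when the
substep's column closure defect exceeds 2e-4 cm; it floors at 1e-4 d.
Internal flux-lag errors telescope out of the column balance, so the
reported daily `balance_error` (checked below 0.1 mm in the tests) is a
genuine residual, not a bookkeeping identity.

Boundaries: atmospheric flux demand (rain minus potential soil
evaporation) on top, switching to a ponded-head (h = 0) control when the
infiltration capacity is exceeded — the excess is runoff — and to a
dry-surface control (h = -1e5 cm) when exfiltration cannot sustain the
evaporative demand; free drainage (unit gradient, q = K(h)) at the
bottom. Interception is not modelled.

Root uptake is a Feddes sink: full extraction between -25 and -300 cm,
linear ramps to zero at -10 cm (anaerobiosis) and -15000 cm (wilting),
applied to a triangular root-density profile that deepens with thermal
time to at most 110 cm. The daily water-availability index is
$\alpha = T_a/T_p$ (1 when there is no demand), and the season index
`alpha_avg` is its mean over sowing to harvest.

## Weather and evaporative demand

Reference evapotranspiration is daily FAO-56 Penman-Monteith (grass
reference, albedo 0.23, soil heat flux zero at the daily step; actual
vapour pressure from mean relative humidity). The canopy splits
$ET_0$ by Beer's law with extinction 0.6:
$T_p = k_c\,ET_0\,(1 - e^{-0.6\,LAI})$ and the complement to soil
evaporation, so $E_p + T_p = k_c\,ET_0$ exactly. The crop coefficient
defaults to 1.15 (the FAO-56 mid-season value for barley): with
$k_c = 1$ the simulated season water stress all but disappeared
(`alpha_avg` near 0.95) and surplus summer percolation dominated the
leaching seasonality, neither of which survives contact with a sandy
profile under a 390-400 mm seasonal evaporative demand.

The synthetic generator produces full calendar years (the winter
leaching season must exist): a harmonic annual temperature cycle
(7.2 °C mean, 11.5 °C amplitude, July peak) plus AR(1) noise; a
two-state precipitation occurrence chain whose wet-day probability is
high in winter (frequent frontal rain that recharges and flushes the
profile) and low in summer, with heavy-tailed gamma amounts (a few large
convective events that drain straight through the sand are what create
the within-season stress pattern); solar radiation as a clear-sky
envelope damped on wet days, with a per-archetype clear-sky anomaly (hot
summers are sunnier); bounded AR(1) humidity and wind. After generation
the season window is shifted/rescaled so each archetype hits its
season-mean temperature (±0.3 °C) and precipitation total (±5 mm)
exactly-ish: the archetype contrast is the object of study, not weather
realism. What the generator does *not* emulate: observed day-to-day
sequences of 2020-2022, snow and frozen-soil hydrology, heat waves
decoupled from the seasonal cycle. Passing tests therefore demonstrate
internal physical consistency and the response *structure* across
contrasting seasons, not site-specific prediction skill.

## Crop

Development is thermal time on the DVS scale with base 0 °C and an
optimum cap at 15 °C (daily degree days = min(T, 15)); sums of
100 / 760 / 500 °C·d for sowing-emergence (with a 7-day minimum),
emergence-flowering and flowering-maturity. The cap matters: without it
the hot archetype raced to maturity in ~82 days and became the smallest
crop of the three, inverting the observed ranking of the seasons.
Defaults were chosen once so that the simulated stages fall in the
reported windows (emergence 7-10 d; flowering 56-68 d; maturity
92-104 d for the normal archetype) — the same role the phenology
calibration step plays in the original study. Development is
N-independent; the few-day stage differences reported between
fertilization treatments are not represented.

Growth is radiation-use efficiency applied to intercepted PAR
(0.5 × global radiation), 2.8 g DM MJ^-1, with a linear temperature
factor ramping from 0 at 3 °C to 1 at 17 °C, multiplied by the Liebig
minimum of the water and N availability indices (each switchable — the
switches disable only the growth response; water flow, transpiration and
N transport always run, so even a potential run reports drainage and
leaching). Maintenance respiration is folded into the efficiency. Organ
partitioning interpolates a DVS-indexed table (grain receives nothing
before DVS 1 by construction); leaves senesce first-order (0.04 d^-1)
from DVS 1.3; LAI is specific leaf area (20 m² kg^-1) times the green
leaf pool.

Organ N targets decline with DVS (leaf 3.0→1.2 %, stem 1.5→0.4 %, grain
constant 2.36 % — the measured calibration-period grain concentration);
the daily demand relaxes the total deficit over 3 days. After anthesis,
grain N demand not met by soil uptake is retranslocated from the canopy
(up to 10 %/d of the N above each organ's structural maturity
concentration). This remobilization is essential: most cereal grain N
comes from the canopy, and without it grain filling demands fresh soil N
exactly when the profile is empty, collapsing yield. A kill switch
(death after 14 consecutive days at $\alpha = 0$) exists but is off by
default.

## Soil nitrogen

The nitrogen module is a deliberately simple first-order system standing
in for a full soil-organic-matter model (the original model's N module
is described elsewhere and is not reproduced here): one mineralizable
organic pool — initialized from the plough layer's total Kjeldahl N,
0.103 % of 1.47 g cm^-3 × 30 cm ≈ 4540 kg N ha^-1 — releases NH4 at
8e-5 d^-1 at 20 °C, modified by a Q10 = 2 temperature factor and a
trapezoidal moisture factor (zero below Se 0.1, optimal 0.5-0.9, halved
at saturation). NH4 nitrifies to NO3 first-order (0.05 d^-1 at
reference conditions — slow enough that the ammonium half of a
fertilizer dose is not instantly exposed to a storm); topsoil mineral N
is immobilized back into the organic pool at 0.008 d^-1, the microbial
competition that keeps apparent fertilizer recovery well below one.
Denitrification is available but off by default (sandy, aerobic
profile). Fertilizer events split 50/50 into NH4 and NO3 (ammonium
nitrate) over the top 10 cm; the initial mineral N (71.3 kg N ha^-1)
sits in the top 30 cm split 70/30 NO3/NH4.

Crop uptake is demand-driven and supply-capped: each rooted node offers
at most 8 %/d of its mineral N; realized uptake is min(demand, supply),
removed in proportion to nodal availability. The N availability index is
uptake/demand (plus remobilization after anthesis), 1 when demand is
zero.

NH4 is treated as sorbed and immobile; NO3 advects with the Richards
interface fluxes by explicit upwind finite volumes, sub-stepped to the
Courant limit (factor 2 safety: a cell can lose water through both
faces). Leaching is recorded at 120 cm as mass flux and flow-weighted
concentration (100 × kg ha^-1 / mm = mg N L^-1; × 62/14 converts to mg
NO3 L^-1). The daily profile audit (inputs minus outputs against the
pool change) closes to machine precision and is asserted below
1e-6 kg ha^-1 in the tests.

On leaching seasonality: the acceptance-level check compares *seasonal
leached mass* (December-February against June-August) over the study
protocol (spin-up, then the three archetype years continuously). The
flow-weighted winter concentration also exceeds the summer one in most
weather realizations, but a single summer cloudburst can flush the
travelling fertilizer slug at high concentration in an unlucky year, so
mass — which expresses the mechanism, winter percolation under a bare,
uptake-free profile — is the robust statement.

## Calibration

The Shuffled Complex Evolution (SCE-UA) optimizer is implemented in
full: random initial population on the bounded box, ranked partition
into complexes (systematic assignment), competitive complex evolution by
simplex reflection/contraction with random replacement of persistent
failures, triangular rank-selection of sub-complexes, periodic
shuffling, and convergence on relative stagnation of the best objective
over five shuffles. Defaults: max(2, d) complexes, 2d+1 points per
complex and evolution steps per shuffle; a seed is mandatory and the
trace is bit-reproducible.

The protocol is two-stage, in this order: (1) phenology — thermal sums
against stage dates (emergence/flowering/maturity, day-RMSE objective)
for the two most climate-contrasting seasons; (2) hydraulics — only the
per-horizon saturated conductivity, searched in log10 over
[0.1, 1000] cm d^-1 with every other hydraulic parameter held at its
laboratory value, against the pooled RMSE of water content at the five
sensor depths (15/40/60/90/110 cm, equal weight per observation). Crop
parameters are held fixed during stage 2: the full model runs once at
the reference conductivities to record the season's surface forcing
(infiltration, evaporation and transpiration demand, root profiles), and
each objective evaluation reruns only the water column under that
forcing with a coarser step floor — this makes an evaluation cost
milliseconds, and at the generating parameters the objective is exact by
construction. Identifiability, measured by parameter recovery from
synthetic observations: the two upper horizons' conductivities come back
within a few hundredths in log10 even with 0.02 cm³ cm^-3 observation
noise; the deep horizons are weakly identifiable (the water-content
signal at depth barely responds). The emergence thermal sum is
identified only to a wide interval — emergence spans ~10 days, dates are
integer and a minimum-duration gate binds — so the recovery tests hold
the season-scale sums (flowering, maturity) to 10 % under ±2-day date
noise and the emergence sum to a wider documented band.

## Scenarios

Runs spin up by looping the archetypes (normal, hot, wet, ...) with the
same management and rate for the configured number of years; the
acceptance workflow uses 1-3 years (the state that matters — profile
moisture and the travelling nitrate slug — equilibrates in 2-3 annual
cycles; the tests verify that doubling the initial mineral N moves the
post-spin-up yield by under 5 %). The yield-gap decomposition runs the
four switch configurations per archetype; the decomposition requires
potential ≥ water-limited ≥ actual, which holds on every archetype and
seed tested. The N-limited vs actual pair is *not* ordered by
construction: an N-stressed actual crop stays small, transpires less and
can finish above the N-limited run — an emergent compensation worth
knowing about when reading the reports. Sweeps rerun the spin-up at each
rate (the soil N state must be consistent with the scenario), extend
each run ~300 days past harvest so the following winter's leaching is
counted, and define the optimal rate as plateau entry: the smallest rate
within 1 % of the sweep's yield maximum.

Problem sizes used by the tests and the acceptance script: 1 cm cells
(2 cm in unit tests), daily steps with adaptive sub-stepping, seasons of
365-516 days, sweeps of 11-21 rates, SCE-UA budgets of 0.5-2k
evaluations — chosen as the smallest sizes at which the checked
invariants are meaningful.

## Known limitations

No photoperiod or vernalization (spring barley), no pests or diseases,
no soil temperature (air temperature drives the rate modifiers), no
hysteresis or macropores, no 2-D flow, no snow; P and K are assumed
non-limiting as applied; the N module is a first-order sketch, not a
multi-pool SOM model; the economic optimum rate is out of scope. The
synthetic weather hits season means and totals by construction, so any
agreement in *means* with reported field seasons is built in — only the
simulated responses (stress indices, gaps, optima, leaching) are model
output.
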