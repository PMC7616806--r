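---
title: "Methods: climate-sensitive health indicators at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate-sensitive health indicators at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`climind` computes a stack of climate-sensitive health indicators from
daily gridded climate fields, gridded age-stratified population, a static
per-cell region table, and a country–year panel. This vignette is the
package's account of the science: the models and their assumptions, the
parameters that matter, the numerical choices, what the synthetic-data
generator does and does not emulate, and the known limitations.

## Data model and conventions

A `climate_field` is one physical variable on a regular latitude–longitude
grid with a strictly daily time axis. Internally cells are enumerated with
latitude varying fastest; all per-cell vectors (weights, region
attributes, population) follow that order. Two calendars are supported: a
365-day no-leap calendar (used by the generator — it makes calendar-day
climatology indexing trivial) and the proleptic Gregorian calendar on
load, where 29 February is mapped to calendar day 59 for threshold lookup
so that climatologies always index days 1–365. Loaders validate rather
than coerce: undeclared units, non-daily time steps and mismatched grids
are errors. Longitudes supplied in [0°, 360°) are rewrapped to
[−180°, 180°) with values permuted accordingly. Relative cell area on a
regular grid is proportional to cos(latitude); all "area-weighted"
aggregations use those weights, all "population-weighted" ones use the
relevant population counts, and any aggregation drops missing cells from
numerator and denominator alike — a region with no usable weight is
reported missing, never zero.

## Percentile climatologies

Heatwave and mortality thresholds are empirical percentiles, per grid cell
and calendar day, of all baseline-period (default 1986–2005) values whose
calendar day falls within a centred window. Two choices here were
genuinely open:

* **Percentile definition.** Linear interpolation between order statistics
  (the "type 7" convention), because it is deterministic, ubiquitous, and
  exactly reproducible by any brute-force re-implementation; the test
  suite checks bit-level equality against a pooled-sample oracle.
* **Windowing.** The default `window_days = 1` pools only the exact
  calendar day across baseline years (20 values per cell-day for a 20-year
  baseline); a 31-day window is the conventional alternative and is a
  single argument away. The choice matters mostly for threshold noise, not
  for trends, and both options are first-class.

## Heat indicators

**Summer exposure anomaly.** Summer is fixed as JJA north of the equator
and DJF south of it, using the calendar year's own January, February and
December for DJF. This is the simplest reproducible definition; a
meteorological definition tied to the local warm season would differ at
the margins but not in the anomaly logic.

**Heatwaves.** A candidate day has both Tmin and Tmax *strictly above*
their thresholds ("higher than" is read as strict); a heatwave day is any
day inside a maximal run of at least `min_duration_days` (default 2)
consecutive candidates. Runs are evaluated on the continuous time axis, so
a heatwave may span a year boundary. The run-length filter is shared with
the coastal *Vibrio* rule and is tested against exhaustive enumeration of
all candidate series up to length 12 plus seeded series up to length 50.
Exposure is reported as person-days (population × heatwave-day count,
summed over cells), its anomaly against the baseline annual mean, and
days per person.

**Heat-stress risk hours.** Hourly temperature is reconstructed from the
daily extrema with a deterministic piecewise sinusoid — Tmin at 06:00,
Tmax at 15:00, a quarter-sine rise between them and a slower sine fall
back to the next morning's minimum; no sunrise modelling. WBGT uses the
simplified outdoor approximation `0.567·T + 0.393·e + 3.94` °C with vapour
pressure `e = RH/100 · 6.105 · exp(17.27·T/(237.7+T))` hPa. This form
needs only temperature and humidity, which is all the data model carries —
a full radiative WBGT requires wind and solar radiation fields that are
out of scope. Risk cut-points default to 23 °C (moderate) and 28 °C
(high) WBGT; no single published standard fixes these for general
physical activity, so they are configuration, not assertion.

**Labour capacity loss.** Work ability follows the logistic
`WA = 0.1 + 0.9/(1 + (WBGT/α₁)^α₂)`, so the lost fraction `1 − WA` runs
from 0 to an asymptote of 0.9 and is exactly 0.45 at `WBGT = α₁`. The
shipped (α₁, α₂) per sector — (34.64, 22.72) for 200 W services,
(33.49, 22.81) for 300 W manufacturing, (32.98, 17.81) for 400 W
agriculture and construction — are the reference parameterisation for
those workloads and are fully overridable. Outdoor sectors (agriculture,
construction) add a +3 °C sun offset to WBGT, reflecting work in full sun.
The working day is 07:00–19:00 (12 hours). Hours lost are
`Σ (1 − WA) × workers` over work hours, days and cells.

**Heat-attributable mortality.** The exposure–response is the simplest
member of the generalised family: a single log-linear slope above the
percentile threshold, `RR = exp(β·max(0, T − T₉₅))`, attributable fraction
`AF = 1 − 1/RR`, with daily baseline deaths taken as annual deaths / 365
when only annual counts exist, AF population-weighted over a country's
cells, and YLL = deaths × residual life expectancy. The default
`β = 0.05` per °C for the 65+ group is labelled configuration: it is a
plausible magnitude, not an estimated value, and every downstream quantity
is linear in the chosen baseline deaths.

## Drought and agriculture

**PET.** Thornthwaite's temperature-only scheme: annual heat index
`I = Σ (max(T,0)/5)^1.514`, exponent `a` from the standard cubic, monthly
`PET = 16·(10·T/I)^a · C` mm with `C = (L/12)(N/30)` the day-length and
month-length correction (day length from solar declination at the
mid-month day). PET is zero at or below 0 °C. Temperature-only PET is the
only option the data model supports; a config hook accepts externally
computed PET for anything richer.

**SPEI.** The climatic water balance `D = P − PET` is accumulated over 6
months (SPEI6); per calendar month and cell a three-parameter log-logistic
distribution is fitted to the calibration sample by unbiased
probability-weighted moments (shape = λ₂/λ₃ in L-moment terms), and fitted
probabilities are mapped through the Abramowitz–Stegun rational
approximation of the normal quantile, the convention in the SPEI
literature (absolute error < 4.5×10⁻⁴, irrelevant at the index's working
precision). Numerical edge cases, decided once:

* a zero-variance or too-short calibration sample yields missing SPEI for
  that cell-month;
* a calibration sample with non-positive L-skewness cannot carry a
  right-skewed log-logistic; the fit is then performed on the reflected
  sample and the probability complemented, which preserves the
  standardisation (six-month sums are close to symmetric, so this branch
  is exercised in practice);
* months before the first full accumulation window are missing;
* fitted probabilities are clamped to [10⁻⁶, 1 − 10⁻⁶] before the quantile
  map.

Calibration defaults to the full record; a fixed window is configurable
because a historical comparison decade need not be the calibration window.
On 50-year synthetic calibrations the per-cell index comes out with mean
within ±0.05 of 0 and sd within ±0.1 of 1, and the calibration tail mass
below −1.6 matches Φ(−1.6) ≈ 0.0548 — these are properties of the
probability-integral transform and are what the acceptance tests assert.
One identifiability note: the (scale, shape, location) triple of a
three-parameter fit is weakly identified at typical calibration sizes —
the parameters trade off along a ridge while the fitted *distribution* is
stable. The meaningful recovery check, and the one the tests run, is
therefore distribution-level (quantile-function agreement within 5% at
n = 600), not element-wise parameter agreement.

**Extreme drought area.** A cell-year is affected if any month has
SPEI ≤ −1.6; the affected share of land area is cos-latitude-weighted,
decadal values are means of annual fractions, and changes are reported in
percentage points and relative percent.

**Crop seasons.** Daily growing-degree-days are
`clip(T, t_base, t_cap) − t_base`; the season runs from a fixed
hemisphere-specific sowing day until cumulative GDD reaches the crop's
requirement (sowing day inclusive), censored at 365 days with a flag.
Censored cell-years are excluded from reported means and counted in the
returned censored fraction — an error would make cold cells fatal, and
silently using 365 would bias the means. Sowing days and thermal
parameters are documented placeholders (real crop calendars are external
data) and the closed form `ceil(GDDreq/(T − t_base))` under constant
temperature, including the capped branch, is tested exactly.

## Disease suitability

**Arbovirus R₀.** The vectorial-capacity form
`R₀ = √( m·a²·b·c·exp(−μ·EIP) / (μ·r) )` with Brière temperature responses
for biting rate, the two transmission probabilities (clipped to [0, 1])
and parasite development rate (EIP = 1/PDR), a concave quadratic for adult
lifespan (μ = 1/lifespan, floored at 0.01 days so mortality stays finite
outside the viable range), human recovery r = 0.2/day, and relative vector
density `m = m₀·min(P/P_half, 1)` saturating in monthly rainfall
(P_half = 80 mm) — monotone and bounded by construction. The coefficients
ship as a plain CSV (`function, term, value`) so other species are a file
swap; outputs are method-faithful suitability indices, not predictions of
case counts. The temperature response is unimodal with an interior
maximum, verified against a 0.1 °C grid search of an independent
re-evaluation of the closed form.

**Malaria.** A month is suitable when 18 °C ≤ T < 32 °C (lower bound
inclusive, upper exclusive — a convention, fixed once), monthly rainfall
≥ 80 mm, relative humidity ≥ 60%, and optionally the land class is in a
suitable set. No consecutive-month requirement is imposed. The highland
aggregate restricts to cells at or above 1500 m.

**Vibrio.** A coastal cell-day is suitable at SST ≥ 18 °C and salinity
≤ 28 psu (brackish); a cell-year counts as suitable only with at least 5
consecutive suitable days, reusing the heatwave run machinery, so a single
noisy day cannot flip a cell. The reported quantity is the
cos-latitude-weighted suitable fraction of coastal cells, optionally
restricted to a latitude band such as 40–70°N.

## Food insecurity

Exposure is the count of heatwave days inside the crop-calendar windows
(May–September in the north, November–March wrapping the year boundary in
the south, per-country overrides possible), area-weighted over each
country's cropland cells, as an anomaly against the baseline mean. The
panel model is
`prevalence = α_country + γ_year + β·anomaly + ε`, estimated by the
two-way within transformation — on the balanced panels produced here a
single country-then-year demeaning pass is exact, and the estimate equals
the full dummy-variable least squares, which the tests verify exactly.
Coefficients are reported in percentage points of prevalence per
heatwave-day. "Time-varying" effects are available as per-year
coefficients (exposure × year indicators); the constant-β mode is the
default because it is the minimal interpretable summary. Standard errors
default to country-clustered (the exposure is serially correlated within
country); classical errors are available for exact small-sample oracles.
Prevalence is modelled in levels, not logit — transparency and exact
algebraic test oracles outweigh the boundary behaviour here, and clipping
is handled at generation. A zero-variance exposure after demeaning is a
rank-deficiency error naming the collinear term, not a silent NA.
Attribution is the linear map `Δprev = β̂·anomaly` per country,
people-equivalents `Δprev/100 × population`, population-weighted globally.

## Economics

All three stages are deliberately exact arithmetic on inputs: monetised
mortality = YLL × VSLY (VSLY is an input — deriving it is out of scope —
and synthetic scenarios set it as a multiple of average income); lost
earnings = hours lost × sectoral wage, with a hard error when a sector has
hours but no wage; net carbon revenue = carbon revenue − fossil subsidies,
net price = net revenue / CO₂ emissions, and the net-negative flag is
invariant to uniform currency rescaling. Income-equivalents divide by
average income per person per year. No currency conversion or deflation
happens inside the package; inputs are assumed to share one currency-year.

## Static overlays

Urban greenness is the population-weighted mean NDVI per urban centre;
centres with zero population are missing, not zero. The "moderately green"
cut is NDVI ≥ 0.4 (inclusive at the cut), a documented placeholder.
Population below an elevation threshold uses a strict "less than", and is
monotone non-decreasing in the threshold.

## The synthetic generator: what it emulates, and what it does not

Daily mean temperature is a latitude-dependent mean state plus a
hemisphere-phased seasonal cycle (peak day 196 north / 15 south), a linear
warming trend (default 0.3 °C/decade), and stationary AR(1) daily noise
(coefficient 0.7, sd 2 °C). The AR(1) choice is load-bearing: with white
noise the ≥ 2-day heatwave criterion would almost never bind, so
persistence is required to exercise the indicator at all. Tmax/Tmin are
Tmean ± half the diurnal range (4 °C) — exact, so the extrema ordering
invariant holds identically. Precipitation is i.i.d. gamma by month; RH is
clipped Gaussian; SST follows a colder latitude profile with the same
trend; salinity is a static spatial pattern (sd 4 psu about 30 psu, so a
realistic share of cells is brackish) plus small daily noise. Population
is log-normal across land cells, rescaled to exact age-group totals;
countries are contiguous blocks cycling through the four HDI groups;
coastal cells get a low-lying elevation band and a share of the interior
is highland. The panel generator embeds a known linear effect of heatwave
anomalies on food-insecurity prevalence (default 0.5 pp per heatwave day
about a 20% baseline) with country effects, year effects and observation
noise, clipped to [0, 1].

Deliberately not emulated: spatially correlated noise fields, orographic
precipitation, realistic coastlines, ENSO-like interannual modes,
demographic change over time, and humidity–temperature covariance.
Passing tests therefore demonstrate that the *methods* are implemented
correctly and behave as their mathematics dictates — standardisation,
monotonicity, closed forms, estimator recovery — not that the package
reproduces any published global magnitude: the shipped scenario is far
smaller and its warming deliberately strong, so its indicator magnitudes
are internally consistent rather than comparable to reanalysis-scale
results.

Seeding: one master seed; per-variable child seeds by fixed offsets (+101
temperature, +202 precipitation, +303 humidity, +404 SST, +505 salinity,
+606 population/regions, +707 panel), so adding a variable never perturbs
the others and identical configurations are bit-reproducible.

## Problem sizes

The default scenario is a 12 × 24 grid over 50 years (1980–2029) with six
countries — chosen so the full pipeline, including hourly WBGT
reconstruction, completes in well under a minute on one CPU while still
containing two decades on either side of the climatology baseline. The
test suite uses a 6 × 8 × 30-year variant for module tests, 3 × 3 × 50
years for the SPEI calibration checks, and 50 countries × 10 years × 200
replicates for the regression-recovery sweep.

## Known limitations

* The CSV dialect is the only on-disk format; no NetCDF reader/writer is
  bundled, and no regridding or projections beyond the regular lat–lon
  grid are supported.
* The mortality exposure–response is a one-parameter placeholder; serious
  use requires location-specific response functions and minimum-mortality
  temperatures supplied as configuration.
* The WBGT approximation omits wind and radiation; the sun offset is a
  constant, not a radiative transfer result.
* Arbovirus coefficients ship for one species; the malaria land-class list
  and crop calendars are injectable inputs with placeholder defaults.
* The fixed-effects design identifies an association under the usual
  strict-exogeneity assumptions; no further causal identification is
  attempted.
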