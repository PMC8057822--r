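---
title: "Methods: attributable burden of ambient PM2.5 and ozone exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attributable burden of ambient PM2.5 and ozone exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Ambient fine particulate matter (PM2.5) and tropospheric ozone (O3) are the
two dominant air-pollution risk factors for premature mortality. Given
gridded annual concentration fields for a control run and a set of
emission-reduction scenarios, together with gridded population counts, an
adult age structure and cause-specific baseline mortality/morbidity rates,
`airburden` estimates the disease burden attributable to each pollutant and
the burden *avoided* by each scenario, aggregated over administrative
regions with full uncertainty envelopes.

# Exposure metrics

**PM2.5** exposure is the per-cell arithmetic annual mean of the (hourly or
daily) concentration series, in μg m⁻³ (`annual_mean()`).

**O3** exposure is the 6-monthly mean daily maximum 8-hour metric, 6mDM8h,
in ppb (`six_m_dm8h()`): for each start hour the forward-looking 8-hour
mean is formed; each day's value is the maximum over the up-to-24 window
means starting that day; candidate means of the daily values are taken over
6 consecutive calendar months starting at each month; the metric is the
largest candidate. Two edge rules are deliberate:

* 8-hour windows running past the end of the year are *dropped*, not
  padded — padding would fabricate data. Only the last day of the year is
  affected (it has 17 valid windows instead of 24).
* The 6-month windows *wrap within the single simulated year* by default
  (e.g. the August window covers Aug–Dec plus the same year's January),
  because only one calendar year is simulated. `wrap = FALSE` restricts to
  the 7 non-wrapping windows; for northern-hemisphere-summer ozone peaks
  the two modes almost always coincide.

Candidate means are computed over *days* (month lengths weight the
months), not as means of monthly means.

**Population weighting.** Regional exposure summaries are
`Σ(value·P·w)/Σ(P·w)` with `P` the cell population and `w` the region-mask
weight (`population_weighted_mean()`). Counts, not rates, are aggregated
first throughout the package.

# Exposure–response models

**PM2.5 (GEMM).** Relative risk for the non-accidental outcome
(non-communicable disease plus lower respiratory infection) uses the Global
Exposure Mortality Model hazard function

$$RR(z) = \exp\!\left[\frac{\theta \,\log(1 + z/\alpha)}{1 +
e^{(\mu - z)/\nu}}\right], \qquad z = \max(0,\; \text{PM}_{2.5} - cf),$$

with counterfactual `cf = 2.4` μg m⁻³, below which no excess risk is
assumed. θ varies by 5-year adult age bracket (25–29 … 80+) and carries a
95% interval; α, μ, ν are shape parameters in μg m⁻³. The parameter set is
a packaged, editable CSV (`inst/extdata/gemm_ncd_lri.csv`, the
China-cohort-inclusive values with α = 1.6, μ = 15.5, ν = 36.8) — loaded at
run time by `gemm_params()`, never hard-coded in logic, so contested
constants stay separate from the algorithm. RR(0) = 1 exactly and RR is
strictly increasing in z for θ > 0; both are property-tested.

**O3 (log-linear hazard ratio).** The COPD hazard ratio per 10 ppb of
6mDM8h is 1.06 (95UI 1.02–1.10), with counterfactual `cf = 35.7` ppb. The
attributable fraction is

$$AF(z) = 1 - e^{-z \ln(HR)/10}, \qquad z = \max(0,\; \text{O}_3^{6mDM8h} - cf).$$

The exponent is negative: the positive-sign variant would make the
fraction negative for z > 0, contradicting the definition of the
counterfactual as the level of no excess risk. At z = 10 ppb the fraction
is exactly 1 − 1/HR, the identity used as a test oracle.

**Attributable counts and burden.** The population attributable count is
`P·(1 − 1/RR)` (PM2.5) or `P·AF(z)` (O3) per cell and age bracket, with
`P` the cell population times the bracket's age fraction. Burden follows
as `MORT = PAF·I_MORT`, `YLL = PAF·I_YLL`, `YLD = PAF·I_YLD` and
`DALY = YLL + YLD` (exact, enforced and tested). Baseline rates are
supplied per 100,000 and divided by 100,000 exactly once, at ingestion;
all internal arithmetic is per-person. Under-25 population carries no risk
parameters and contributes zero burden via zero age fractions.

# Uncertainty

Three sources carry intervals: θ (or HR), baseline rates, and age
fractions. The default 95% envelope evaluates all three simultaneously at
their lower, mid and upper bounds (`burden_pipeline()`); because the chain
is monotone in each source, this equals the min/max over all 3³ = 27
variant combinations — verified against a brute-force enumeration in the
tests. This is a conservative convention; the combination rule is a design
choice, since simultaneous bounds overstate the width relative to
independent errors. `burden_montecarlo()` provides the sampling
alternative (normal θ, log-normal HR, truncated-normal rates and
fractions, sd = width/3.92) with a required seed. Scenario-difference
intervals subtract bound-to-bound (lower − lower, upper − upper), matching
the envelope construction.

# Model evaluation and bias adjustment

Simulated fields are compared with station observations via the normalized
mean bias factor and normalized mean absolute error factor, the symmetric
and scale-invariant pair

$$NMBF = \begin{cases}\Sigma M/\Sigma O - 1 & \bar M \ge \bar O\\
1 - \Sigma O/\Sigma M & \bar M < \bar O\end{cases}
\qquad
NMAEF = \frac{\Sigma|M - O|}{\Sigma O \text{ or } \Sigma M \text{ (same rule)}}$$

A model overestimating by a factor F gives NMBF = F − 1; underestimating
gives 1 − F. Stations are matched to their nearest grid cell by
great-circle distance (ties to the lower `[lat, lon]` index); evaluation
uses annual means of paired values by default, with an hourly mode
available — the matching rule and averaging period are configurable because
published evaluations rarely state them.

Bias adjustment of a simulated exposure uses `adjusted = S·(1 − NMBF)`,
the single linear form consistent with adjusting an overestimate (positive
NMBF) downward and an underestimate upward; reported values are rounded
half-up to integers. Percent changes between scenarios are likewise
reported rounded half-up to the nearest integer, and aggregate counts to
the nearest hundred — the conventions that reproduce every printed pairing
of absolute and relative change we use as test fixtures.

# The synthetic world

`synth_config()` + `gen_world()` / `gen_concentrations()` /
`gen_scenario()` / `gen_stations()` generate every input deterministically
from a seed (sub-seeds are derived per component, so e.g. adding stations
never perturbs the concentration noise). The generator emulates:

* a regular 1° lat/lon grid, default 24 × 36 cells over a China-like
  domain, with a small "GBA-like" focal rectangle so inside/outside-domain
  scenario logic is exercised;
* population as a smooth rural surface plus Gaussian urban peaks
  (default 1.39 × 10⁹ persons, 62% urban share, 18 centers), normalized
  exactly to the configured total;
* hourly concentrations as
  `background + Σ_sector map_s(cell) · mod_s(hour) + AR(1) noise`,
  clipped at zero (clip events counted). Sector spatial maps are scaled so
  the population-weighted sum of components equals a configured target
  (55 μg m⁻³ PM2.5 excess over a 12 μg m⁻³ background; 25 ppb O3 over
  40 ppb) — chosen to land national exposures in the range real Chinese
  assessments report. Diurnal/seasonal modulations have mean 1, so the
  annual mean of each component equals its spatial map exactly — the
  bookkeeping identity the tests verify;
* scenarios as a *linear source surrogate*: removing `scaling` × a
  sector's component inside a spatial domain. For ozone, a signed regime
  map sends precursor cuts the other way in a configured fraction
  (default 35%, the most-populated cells) of "VOC-limited" urban cells,
  emulating the NOx-/VOC-limited dichotomy of ozone chemistry. The default
  archetypes mirror four policy levers: residential solid-fuel transition
  (50% outside the focal region), agricultural NH3 cut (30%, outside),
  land-transport NOx cut (80%, nationwide, regime-signed), industrial VOC
  cut (10%, nationwide);
* sector shares with residential the largest national PM2.5 contributor
  (0.35), so the residential archetype produces the largest avoided
  burden — asserted in the tests as an ordering only, never a magnitude;
* monitoring stations at population-weighted random cells observing the
  true cell series with a configurable multiplicative bias, additive noise
  and missingness (explicit sentinels, excluded pairwise).

What the generator does *not* emulate: meteorology and transport
direction, nonlinear chemistry, seasonal inside/outside contrasts beyond
the domain mask, or correlated observation error. Passing tests therefore
demonstrate the correctness of the assessment arithmetic and its
invariances, not the realism of any particular atmospheric simulation.

# Numerical choices and degenerate inputs

* Spatial indexing is 1-based `[lat, lon]` (the R convention); NetCDF I/O
  round-trips by coordinate value and is bit-identical.
* Unit strings are validated on read; `ppm` ozone converts ×1000,
  `mg m-3` PM2.5 ×1000; unknown units are format errors naming the
  attribute.
* Region masks may be fractional; a mask set declared a partition must sum
  to 1 per cell within 1e-9. Fractional-overlap rasterization is
  approximated by an 8 × 8 subsample lattice per cell.
* Zero weighted population, empty time axes, nonpositive evaluation sums,
  NMBF ≤ −1 and bracket mismatches are explicit errors, not NaNs.
* Nearest-cell ties (equidistant centers) resolve to the lower
  lexicographic `[lat, lon]` index with a millimetre tolerance.

# Problem sizes

The test suite exercises single-cell and 4 × 6 toy grids for oracles and
hand computations, 20 single-cell random years for the 6mDM8h brute-force
comparison, and one full end-to-end year at 24 × 36 × 8760 with all four
scenario archetypes — sizes chosen so the whole suite completes in well
under a minute on one CPU while still covering every code path at full
annual resolution.

# Known limitations

* The linear source surrogate cannot reproduce nonlinear aerosol or ozone
  chemistry; scenario responses are exact by construction rather than
  emergent.
* The conservative envelope overstates uncertainty relative to
  Monte-Carlo combination of independent sources.
* Only the GEMM NCD+LRI outcome (PM2.5) and COPD (O3) are implemented; no
  IER or log-linear PM2.5 alternatives, no morbidity-only outcomes beyond
  YLD, no economic valuation.
* Shapefile input is not supported; region geometries are GeoJSON
  (`Polygon`/`MultiPolygon`).
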