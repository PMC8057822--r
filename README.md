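# airburden

Health impact assessment of ambient air pollution: given gridded PM2.5 and
ozone concentration fields for a control run and a set of emission-reduction
scenarios, `airburden` estimates the attributable disease burden — premature
deaths (MORT), years of life lost (YLL), years lived with disability (YLD)
and DALYs — per grid cell, age bracket and region, with 95% uncertainty
envelopes, and the burden each scenario avoids. It is written for air
quality and environmental-health researchers who have concentration fields
(from a chemical-transport model or otherwise) and want a tested,
reproducible burden pipeline; a seeded synthetic-data generator stands in
for model output, population and health data so the whole pipeline can be
exercised at desk scale.

## The models at the core

**PM2.5** uses the Global Exposure Mortality Model (GEMM) for
non-communicable disease plus lower respiratory infection, with age-specific
risk coefficients:

    z   = max(0, PM2.5 − 2.4 μg m⁻³)
    RR  = exp[ θ·ln(1 + z/α) / (1 + e^((μ−z)/ν)) ]
    PAF = P · (1 − 1/RR)

**Ozone** uses a log-linear COPD hazard ratio of 1.06 (95UI 1.02–1.10) per
10 ppb of the 6mDM8h metric (maximum over seasonal 6-month windows of the
mean daily-maximum 8-hour concentration):

    z   = max(0, O3(6mDM8h) − 35.7 ppb)
    PAF = P · (1 − e^(−z·ln(HR)/10))

Burden follows as `MORT = PAF·I_MORT`, `YLL = PAF·I_YLL`,
`YLD = PAF·I_YLD`, `DALY = YLL + YLD`, with baseline rates per 100,000 per
age bracket. Model evaluation against station observations uses the
normalized mean bias factor (NMBF) and normalized mean absolute error
factor (NMAEF), and simulated exposures can be bias-adjusted by
`S·(1 − NMBF)`. See `vignettes/methods.Rmd` for the full account.

## Worked example

```r
library(airburden)

cfg   <- synth_config(seed = 42, n_lat = 8, n_lon = 12,
                      total_population = 2e8, n_urban = 8L, n_stations = 15L)
world <- gen_world(cfg)                 # population, ages, rates, regions
truth <- gen_concentrations(cfg, world) # hourly control fields, both pollutants

pm <- annual_mean(truth$pm25$control)
o3 <- six_m_dm8h(truth$o3$control)
population_weighted_mean(pm, world$pop)  # 67.0 ug m-3
population_weighted_mean(o3, world$pop)  # 75.8 ppb

b <- burden_pipeline(pm, world$pop, world$ages, world$rates, gemm_params())
round(burden_total(b))
#>        lower     mid   upper
#> MORT  265796  360403  467354
#> YLL  4341365 5871954 7596982
#> YLD  1085341 1467988 1899245
#> DALY 5426706 7339942 9496227

flds <- gen_scenario(truth, world, cfg$scenarios$RES, "RES")
d <- scenario_delta(pm, annual_mean(flds$pm25), world$pop)
#> RES: pm25 exposure falls 9.6 ug m-3 (14%)

st <- gen_stations(truth, world, cfg, "pm25", every = 24L)
evaluate_model(pm, st)
#>   pollutant domain n_stations        nmbf      nmaef
#> 1      pm25    all         15 -0.09431871 0.09431871
```

Reading the numbers: the synthetic population-weighted annual-mean PM2.5
exposure is 67 μg m⁻³; at that exposure the GEMM chain attributes ~360,000
deaths (95% envelope 266,000–467,000) among the 200 million synthetic
inhabitants. The residential-sector scenario (a 50% emission cut outside
the focal region) lowers population-weighted exposure by 9.6 μg m⁻³
(14%). The stations were generated with a +10% observation bias, so the
model underestimates the observations by a factor of about 1.1; the
evaluation recovers NMBF ≈ −0.094, close to the noise-free value
1 − 1.1 = −0.1 of the factor definition.

A thin command-line wrapper over the same functions is installed at
`inst/cli/airburden.R`
(`Rscript airburden.R generate|exposure|evaluate|hia|aggregate|report
--config cfg.yaml --seed N --out dir`).

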