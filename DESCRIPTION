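Package: airburden
Title: Health Impact Assessment of Ambient PM2.5 and Ozone Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the disease burden attributable to ambient fine
    particulate matter (PM2.5) and ozone (O3) exposure from gridded
    concentration fields. Implements the Global Exposure Mortality Model
    (GEMM) relative-risk function and population attributable fractions for
    PM2.5, a log-linear hazard-ratio model for the 6-monthly mean of daily
    maximum 8-hour ozone (6mDM8h), burden accounting in premature deaths,
    years of life lost, years lived with disability and DALYs, normalized
    mean bias/absolute error factor model evaluation against station
    observations, bias adjustment of simulated exposures, regional
    aggregation with population weighting, scenario comparison (avoided
    burden) and conservative 95 percent uncertainty envelopes. A seeded
    synthetic-data generator emulates chemical-transport-model output,
    gridded population, age structure, baseline rates, region geometries and
    noisy monitoring observations so the full pipeline can be exercised and
    tested at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ncdf4,
    jsonlite,
    yaml,
    mgcv,
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
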