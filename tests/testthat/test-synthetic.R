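test_that("the generated world is normalized, deterministic and partitioned", {
  cfg <- tiny_config(seed = 21)
  w <- gen_world(cfg)
  expect_equal(sum(w$pop$counts), cfg$total_population,
               tolerance = 1e-6)
  expect_true(is_partition(w$masks))
  expect_true(all(w$gba_mask$weights %in% c(0, 1)))
  # same seed twice: bit-identical
  w2 <- gen_world(tiny_config(seed = 21))
  expect_identical(w$pop$counts, w2$pop$counts)
  expect_identical(w$urban_centers, w2$urban_centers)
  # different seed moves the urban centers
  w3 <- gen_world(tiny_config(seed = 22))
  expect_false(identical(w$pop$counts, w3$pop$counts))
  # zero urban share gives a spatially smooth field
  ws <- gen_world(tiny_config(seed = 21, urban_share = 0, n_urban = 0L))
  expect_lt(max(ws$pop$counts) / mean(ws$pop$counts), 4)
})

test_that("infeasible configurations are rejected", {
  expect_error(tiny_config(sector_shares = list(
    pm25 = c(residential = 0.9, industry = 0.9, transport = 0,
             agriculture = 0, other = 0),
    o3 = c(residential = 0.2, industry = 0.2, transport = 0.2,
           agriculture = 0.2, other = 0.2))), "sum to 1")
  expect_error(tiny_config(urban_share = 1.4), "urban share")
  expect_error(synth_config(scenarios = list(
    X = list(sector = "residential", scaling = 1.7, domain = "all",
             o3_mode = "monotonic"))), "scaling")
})

test_that("control fields honour the component bookkeeping identity", {
  cfg <- tiny_config(seed = 31)
  w <- gen_world(cfg)
  tr <- gen_concentrations(cfg, w)
  for (p in c("pm25", "o3")) {
    tp <- tr[[p]]
    residual <- tp$preclip - tp$maps %*% t(tp$mods) - tp$noise
    expect_equal(max(abs(residual - tp$background)), 0, tolerance = 1e-9)
    expect_identical(tp$control$values,
                     array(pmax(tp$preclip, 0),
                           dim = dim(tp$control$values)))
    expect_gte(tp$clip_count, 0)
  }
  # determinism of the whole truth object
  tr2 <- gen_concentrations(cfg, gen_world(cfg))
  expect_identical(tr$pm25$preclip, tr2$pm25$preclip)
  expect_identical(tr$regime_sign, tr2$regime_sign)
})

test_that("zero amplitudes and zero noise give time-constant fields", {
  cfg <- flat_config(seed = 31)
  w <- gen_world(cfg)
  tr <- gen_concentrations(cfg, w)
  v <- tr$pm25$control$values
  expect_equal(max(abs(sweep(v, c(1, 2), v[, , 1]))), 0, tolerance = 1e-9)
  # annual mean equals background + summed sector components exactly
  am <- annual_mean(tr$pm25$control)$values
  want <- matrix(12 + rowSums(tr$pm25$maps), nrow(am), ncol(am))
  expect_equal(am, want, tolerance = 1e-9)
  # population-weighted excess hits the configured target
  pw <- population_weighted_mean(annual_mean(tr$pm25$control), w$pop)
  expect_equal(pw, 12 + 55, tolerance = 1e-6)
})

test_that("scenario derivation is linear, monotone and domain-limited", {
  cfg <- flat_config(seed = 41)
  w <- gen_world(cfg)
  tr <- gen_concentrations(cfg, w)
  ctrl_am <- annual_mean(tr$pm25$control)$values

  # scaling 0 leaves the control untouched
  s0 <- gen_scenario(tr, w, list(sector = "residential", scaling = 0,
                                 domain = "all", o3_mode = "monotonic"))
  expect_equal(s0$pm25$values, tr$pm25$control$values, tolerance = 1e-12)

  # scaling 0.5 removes exactly half the sector's annual-mean component
  s5 <- gen_scenario(tr, w, list(sector = "residential", scaling = 0.5,
                                 domain = "all", o3_mode = "monotonic"))
  drop5 <- ctrl_am - annual_mean(s5$pm25)$values
  want <- matrix(0.5 * tr$pm25$maps[, "residential"],
                 nrow(ctrl_am), ncol(ctrl_am))
  expect_equal(drop5, want, tolerance = 1e-9)

  # full removal of one sector leaves background plus the other sectors
  s1 <- gen_scenario(tr, w, list(sector = "industry", scaling = 1,
                                 domain = "all", o3_mode = "monotonic"))
  rest <- rowSums(tr$pm25$maps[, setdiff(colnames(tr$pm25$maps),
                                         "industry")])
  expect_equal(annual_mean(s1$pm25)$values,
               matrix(12 + rest, nrow(ctrl_am), ncol(ctrl_am)),
               tolerance = 1e-9)

  # larger scaling never increases PM2.5 anywhere
  s8 <- gen_scenario(tr, w, list(sector = "residential", scaling = 0.8,
                                 domain = "all", o3_mode = "monotonic"))
  expect_true(all(s8$pm25$values <= s5$pm25$values + 1e-12))

  # outside-GBA scenarios leave the focal region untouched
  so <- gen_scenario(tr, w, list(sector = "residential", scaling = 0.5,
                                 domain = "outside_gba",
                                 o3_mode = "monotonic"))
  gba <- w$gba_mask$weights == 1
  d <- ctrl_am - annual_mean(so$pm25)$values
  expect_true(all(abs(d[gba]) < 1e-12))
  expect_true(any(d[!gba] > 0))

  # regime mode raises ozone in VOC-limited cells, lowers it elsewhere
  sr <- gen_scenario(tr, w, list(sector = "transport", scaling = 0.8,
                                 domain = "all", o3_mode = "regime"))
  d_o3 <- apply(tr$o3$control$values, c(1, 2), mean) -
    apply(sr$o3$values, c(1, 2), mean)
  voc <- tr$regime_sign == -1
  expect_true(all(d_o3[voc] < 1e-12))
  expect_true(all(d_o3[!voc] > -1e-12))

  expect_error(gen_scenario(tr, w, list(sector = "shipping", scaling = 0.5,
                                        domain = "all",
                                        o3_mode = "monotonic")),
               "sector")
})

test_that("synthetic stations recover the configured observation bias", {
  # perfect observations: NMBF and NMAEF are exactly zero
  cfg0 <- flat_config(seed = 51)
  w <- gen_world(cfg0)
  tr <- gen_concentrations(cfg0, w)
  st0 <- gen_stations(tr, w, cfg0, "pm25", every = 24L)
  ev0 <- evaluate_model(annual_mean(tr$pm25$control), st0)
  expect_equal(ev0$nmbf, 0, tolerance = 1e-12)
  expect_equal(ev0$nmaef, 0, tolerance = 1e-12)

  # multiplicative bias +0.3, no noise: observations exceed the model, so
  # NMBF = 1 - sum(O)/sum(M) = -0.3 exactly on paired annual means
  cfg3 <- flat_config(seed = 51, obs_bias = 0.3)
  st3 <- gen_stations(tr, w, cfg3, "pm25", every = 24L)
  ev3 <- evaluate_model(annual_mean(tr$pm25$control), st3)
  expect_equal(ev3$nmbf, -0.3, tolerance = 1e-9)

  # same seed, same stations
  st3b <- gen_stations(tr, w, cfg3, "pm25", every = 24L)
  expect_identical(st3, st3b)
})

test_that("the input bundle writes a readable file set", {
  cfg <- tiny_config(seed = 61, n_stations = 3L)
  dir <- withr::local_tempdir()
  write_input_bundle(cfg, dir, scenarios = FALSE)
  ctrl <- read_concentration_field(file.path(dir, "pm25_control.nc"), "pm25")
  expect_s3_class(ctrl, "ab_conc_field")
  expect_false(ctrl$annual)
  pop <- read_population(file.path(dir, "population.nc"))
  expect_equal(sum(pop$counts), cfg$total_population, tolerance = 1e-6)
  masks <- rasterize_regions(file.path(dir, "regions.geojson"),
                             ctrl$grid)
  expect_true("gba" %in% names(masks))
  st <- read_stations(file.path(dir, "stations_pm25.csv"))
  expect_s3_class(st, "ab_stations")
  ages <- age_structure(read.csv(file.path(dir, "age_structure.csv")))
  rates <- baseline_rates(read.csv(file.path(dir, "baseline_rates.csv")))
  expect_s3_class(rates, "ab_baseline_rates")
})
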