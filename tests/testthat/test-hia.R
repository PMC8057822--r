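gp <- gemm_params()
orisk <- ozone_risk()

test_that("excess exposure floors at the counterfactual", {
  expect_equal(hazard_z(2.4, 2.4), 0)
  expect_equal(hazard_z(1.0, 2.4), 0)
  expect_equal(hazard_z(72.8, 2.4), 70.4)
  expect_equal(hazard_z(35.7, 35.7), 0)
  expect_equal(hazard_z(20, 35.7), 0)
  expect_equal(hazard_z(61.3, 35.7), 25.6)
})

test_that("GEMM relative risk matches its closed form and is monotone", {
  # RR(0) = 1 for any parameters (including every packaged bracket)
  for (b in age_brackets())
    expect_identical(gemm_rr_bracket(0, gp, b), 1)
  # frozen high-precision evaluation of the hazard function
  expect_equal(gemm_rr(70.4, 0.1430, 1.6, 15.5, 36.8), 1.55953130061,
               tolerance = 1e-10)
  # doubling theta doubles log(RR) at fixed z
  z <- c(5, 20, 80)
  expect_equal(log(gemm_rr(z, 0.286, 1.6, 15.5, 36.8)),
               2 * log(gemm_rr(z, 0.143, 1.6, 15.5, 36.8)),
               tolerance = 1e-12)
  # strictly increasing in z on a grid, for every bracket
  zg <- seq(0, 150, by = 0.5)
  for (b in c("25-29", "60-64", "80+")) {
    rr <- gemm_rr_bracket(zg, gp, b)
    expect_true(all(diff(rr) > 0))
    expect_true(all(rr >= 1))
  }
  expect_error(gemm_rr_bracket(1, gp, "18-24"), "bracket")
})

test_that("PM2.5 attributable counts follow 1 - 1/RR", {
  # null risk at z = 0
  expect_equal(pm25_paf(0, gp, "60-64", 1000), 0)
  # frozen oracle value: z = 70.4 with the spec-level parameter set
  custom <- gp
  custom$table$theta <- 0.1430
  expect_equal(pm25_paf(70.4, custom, "60-64", 1e5), 35878.1706,
               tolerance = 1e-7)
  # attributable fraction in [0, 1); counts below the population
  z <- seq(0, 300, 10)
  for (b in age_brackets()) {
    frac <- 1 - 1 / gemm_rr_bracket(z, gp, b)
    expect_true(all(frac >= 0 & frac < 1))
    expect_true(all(pm25_paf(z, gp, b, 777) < 777))
  }
})

test_that("ozone attributable counts follow the log-linear hazard model", {
  expect_equal(o3_paf(0, orisk, 1000), 0)
  # at z = 10 ppb the fraction is exactly 1 - 1/HR
  expect_equal(o3_paf(10, orisk, 1), 1 - 1 / 1.06, tolerance = 1e-12)
  # frozen direct evaluation at the GBA excess exposure
  expect_equal(o3_paf(25.6, orisk, 1e5), 13857.5965, tolerance = 1e-4)
  # small-z linearization: fraction ~ z*ln(HR)/10 within 1% at z <= 1
  for (z in c(0.1, 0.5, 1)) {
    lin <- z * log(1.06) / 10
    expect_equal(o3_paf(z, orisk, 1), lin, tolerance = 0.01)
  }
  expect_error(ozone_risk(hr = 1.0, hr_lower = 0.9, hr_upper = 1.1), "bounds")
})

test_that("burden equations multiply per-person rates and add DALYs", {
  rates <- flat_rates(mort = 2000, yll = 30000, yld = 5000)
  expect_equal(attributable_burden(0, rates, "NCD_LRI", "60-64", "MORT"), 0)
  # hand multiplication: 17,938.5 x 2,000 / 100,000
  expect_equal(attributable_burden(17938.5, rates, "NCD_LRI", "60-64", "MORT"),
               358.77)
  yll <- attributable_burden(100, rates, "NCD_LRI", "60-64", "YLL")
  yld <- attributable_burden(100, rates, "NCD_LRI", "60-64", "YLD")
  expect_equal(attributable_burden(100, rates, "NCD_LRI", "60-64", "DALY"),
               yll + yld)
  expect_error(attributable_burden(1, rates, "COPD", "60-64", "MORT"),
               "COPD")
})

toy_setup <- function() {
  g <- ab_grid(c(20.5), c(110.5))
  list(grid = g,
       pop = pop_grid(g, matrix(1e5)),
       ages = one_bracket_ages("60-64", 1),
       rates = flat_rates(spread = 0.1))
}

test_that("the single-cell burden chain matches a hand computation", {
  s <- toy_setup()
  ex <- uniform_exposure(72.8, s$grid)
  b <- burden_pipeline(ex, s$pop, s$ages, s$rates, gp)
  # hand chain: z = 70.4; RR from the 60-64 row; PAF = P(1 - 1/RR);
  # MORT = PAF * 2000/1e5, YLL/YLD likewise, DALY = YLL + YLD
  row <- gp$table[gp$table$age_bracket == "60-64", ]
  rr <- exp(row$theta * log(1 + 70.4 / 1.6) /
              (1 + exp((15.5 - 70.4) / 36.8)))
  paf <- 1e5 * (1 - 1 / rr)
  tot <- burden_total(b)
  expect_equal(tot["MORT", "mid"], paf * 2000 / 1e5, tolerance = 1e-12)
  expect_equal(tot["YLL", "mid"], paf * 30000 / 1e5, tolerance = 1e-12)
  expect_equal(tot["YLD", "mid"], paf * 5000 / 1e5, tolerance = 1e-12)
  expect_equal(tot["DALY", "mid"], tot["YLL", "mid"] + tot["YLD", "mid"])
  # lower variant uses theta_lower and 0.9x rates simultaneously
  rr_lo <- exp(row$theta_lower * log(1 + 70.4 / 1.6) /
                 (1 + exp((15.5 - 70.4) / 36.8)))
  expect_equal(tot["MORT", "lower"],
               1e5 * (1 - 1 / rr_lo) * 0.9 * 2000 / 1e5, tolerance = 1e-12)
})

test_that("burden vanishes at the counterfactual and scales with population and rates", {
  s <- toy_setup()
  at_cf <- uniform_exposure(2.4, s$grid)
  expect_true(all(burden_total(
    burden_pipeline(at_cf, s$pop, s$ages, s$rates, gp)) == 0))

  ex <- uniform_exposure(60, s$grid)
  b1 <- burden_total(burden_pipeline(ex, s$pop, s$ages, s$rates, gp))
  pop2 <- pop_grid(s$grid, s$pop$counts * 2)
  b2 <- burden_total(burden_pipeline(ex, pop2, s$ages, s$rates, gp))
  expect_equal(b2, 2 * b1, tolerance = 1e-12)

  rates3 <- s$rates
  for (v in c("lower", "mid", "upper")) rates3[[v]] <- rates3[[v]] * 3
  b3 <- burden_total(burden_pipeline(ex, s$pop, s$ages,
                                     baseline_rates(rates3), gp))
  expect_equal(b3, 3 * b1, tolerance = 1e-12)
})

test_that("the uncertainty envelope brackets all 27 variant combinations", {
  g <- ab_grid(c(20.5), c(110.5))
  pop <- pop_grid(g, matrix(1e5))
  mid <- ifelse(age_brackets() == "60-64", 0.4, 0)
  ages <- age_structure(data.frame(bracket = age_brackets(),
                                   lower = mid * 0.9, mid = mid,
                                   upper = mid * 1.1))
  rates <- flat_rates(spread = 0.15)
  ex <- uniform_exposure(60, g)
  b <- burden_total(burden_pipeline(ex, pop, ages, rates, gp))

  # independent brute force over {lower, mid, upper}^3
  row <- gp$table[gp$table$age_bracket == "60-64", ]
  thetas <- c(row$theta_lower, row$theta, row$theta_upper)
  fracs <- c(0.36, 0.4, 0.44)
  rmults <- c(0.85, 1, 1.15)
  z <- 60 - 2.4
  combos <- expand.grid(th = thetas, fr = fracs, rm = rmults)
  mort <- with(combos, {
    rr <- exp(th * log(1 + z / 1.6) / (1 + exp((15.5 - z) / 36.8)))
    1e5 * fr * (1 - 1 / rr) * rm * 2000 / 1e5
  })
  expect_equal(b["MORT", "lower"], min(mort), tolerance = 1e-12)
  expect_equal(b["MORT", "upper"], max(mort), tolerance = 1e-12)
  expect_true(all(b[, "lower"] <= b[, "mid"] & b[, "mid"] <= b[, "upper"]))

  # degenerate intervals collapse the envelope
  ages0 <- one_bracket_ages("60-64", 0.4)
  rates0 <- flat_rates(spread = 0)
  gp0 <- gp
  gp0$table$theta_lower <- gp0$table$theta
  gp0$table$theta_upper <- gp0$table$theta
  b0 <- burden_total(burden_pipeline(ex, pop, ages0, rates0, gp0))
  expect_equal(b0[, "lower"], b0[, "mid"])
  expect_equal(b0[, "upper"], b0[, "mid"])

  # widening only theta's interval widens the envelope monotonically
  gpw <- gp0
  gpw$table$theta_lower <- gpw$table$theta - 0.02
  gpw$table$theta_upper <- gpw$table$theta + 0.02
  bw <- burden_total(burden_pipeline(ex, pop, ages0, rates0, gpw))
  expect_true(all(bw[, "lower"] < b0[, "lower"]))
  expect_true(all(bw[, "upper"] > b0[, "upper"]))
})

test_that("Monte-Carlo envelopes are ordered and reproducible", {
  s <- toy_setup()
  ex <- uniform_exposure(60, s$grid)
  mc1 <- burden_montecarlo(ex, s$pop, s$ages, s$rates, gp, n_draws = 40,
                           seed = 3)
  mc2 <- burden_montecarlo(ex, s$pop, s$ages, s$rates, gp, n_draws = 40,
                           seed = 3)
  expect_identical(mc1, mc2)
  expect_true(all(mc1[, "lower"] <= mc1[, "mid"]))
  expect_true(all(mc1[, "mid"] <= mc1[, "upper"]))
  mco <- burden_montecarlo(uniform_exposure(60, s$grid, "o3"), s$pop,
                           s$ages, flat_rates("COPD"), orisk,
                           n_draws = 40, seed = 3)
  expect_true(all(mco[, "lower"] <= mco[, "upper"]))
})

test_that("ozone burden pipeline uses the hazard-ratio fraction uniformly", {
  s <- toy_setup()
  ex <- uniform_exposure(61.3, s$grid, "o3")
  b <- burden_pipeline(ex, s$pop, s$ages, flat_rates("COPD", 500, 6000, 3000),
                       orisk)
  frac <- 1 - exp(-25.6 * log(1.06) / 10)
  expect_equal(burden_total(b)["MORT", "mid"], 1e5 * frac * 500 / 1e5,
               tolerance = 1e-12)
  # mismatched risk object is rejected
  expect_error(burden_pipeline(ex, s$pop, s$ages, flat_rates("COPD"), gp),
               "ozone|O3")
})
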