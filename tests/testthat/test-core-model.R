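# Cumulative-incidence engine: rates, hazard ratios, horizon partition,
# within-band CIF and the chained 10-year risks.

test_that("band_rates divides cause-specific deaths by population", {
  grid <- expand.grid(sex = c("female", "male"),
                      age_band_start = seq(40, 70, 5),
                      stringsAsFactors = FALSE)
  tab <- mortality_table(data.frame(grid, deaths_cvd = 50,
                                    deaths_noncvd = 150, population = 1e5))
  expect_equal(unname(band_rates(tab, "male", 40)), c(5e-4, 1.5e-3))
  zero <- mortality_table(data.frame(grid, deaths_cvd = 0,
                                     deaths_noncvd = 150, population = 1e5))
  expect_identical(band_rates(zero, "female", 55)[["m_cvd"]], 0)
  expect_error(band_rates(tab, "male", 35), class = "cvdrecal_validation_error")
  expect_error(band_rates(tab, "other", 40),
               class = "cvdrecal_validation_error")
})

test_that("mortality table construction enforces its invariants", {
  grid <- expand.grid(sex = c("female", "male"),
                      age_band_start = seq(40, 70, 5),
                      stringsAsFactors = FALSE)
  base <- data.frame(grid, deaths_cvd = 50, deaths_noncvd = 150,
                     population = 1e5)
  expect_s3_class(mortality_table(base), "mortality_table")
  expect_error(mortality_table(base[base$sex == "male", ]),
               "both sexes", class = "cvdrecal_validation_error")
  expect_error(mortality_table(transform(base, population = 0)),
               class = "cvdrecal_validation_error")
  expect_error(mortality_table(transform(base, deaths_cvd = -1)),
               class = "cvdrecal_validation_error")
  expect_error(mortality_table(base[base$age_band_start != 70, ]),
               "70-74", class = "cvdrecal_validation_error")
  expect_error(mortality_table(rbind(base, base[1, ])),
               "duplicate", class = "cvdrecal_validation_error")
})

test_that("hazard ratio is exp(beta'(x - xbar)) with prevalence-centred smoking", {
  means <- flat_means(sbp = 140, tc = 5.5, smoking = 0.30)
  cf <- coefficients_set(beta_sbp = 0.015, beta_tc = 0.25, beta_smoke = 0.71)
  p <- risk_profile("male", 50, 160, 6.5, "TC", smoker = TRUE)
  # frozen from an independent high-precision evaluation of the closed form
  expect_equal(hazard_ratio(p, means, cf, 50), 2.84909101128921434,
               tolerance = 1e-12)

  # identity case: profile at the band means with neutral smoking term
  at_means <- risk_profile("male", 50, 140, 5.5, "TC", smoker = FALSE)
  cf0smoke <- coefficients_set(beta_sbp = 0.015, beta_tc = 0.25,
                               beta_smoke = 0)
  expect_equal(hazard_ratio(at_means, means, cf0smoke, 50), 1)
  # null coefficients: HR 1 for any profile
  expect_equal(hazard_ratio(p, means, null_coefs(), 50), 1)
})

test_that("hazard ratio honours measure-specific betas and per-sex overrides", {
  means <- flat_means(ratio = 4)
  cf <- coefficients_set(beta_sbp = 0, beta_ratio = 0.2, beta_smoke = 0,
                         sex = list(female = list(beta_ratio = 0.1)))
  pm <- risk_profile("male", 50, 140, 5, "RATIO")
  pf <- risk_profile("female", 50, 140, 5, "RATIO")
  expect_equal(hazard_ratio(pm, means, cf, 50), exp(0.2))
  expect_equal(hazard_ratio(pf, means, cf, 50), exp(0.1))
  # TC profile with no beta_tc configured -> configuration error
  ptc <- risk_profile("male", 50, 140, 5, "TC")
  expect_error(hazard_ratio(ptc, means, cf, 50), "cholesterol",
               class = "cvdrecal_validation_error")
})

test_that("horizon partition tiles [age, age+10) on the 5-year grid", {
  hb40 <- horizon_bands(40)
  expect_equal(hb40$band_start, c(40, 45))
  expect_equal(hb40$exposure, c(5, 5))
  hb65 <- horizon_bands(65)
  expect_equal(hb65$band_start, c(65, 70))
  hb43 <- horizon_bands(43)
  expect_equal(hb43$band_start, c(40, 45, 50))
  expect_equal(hb43$exposure, c(2, 5, 3))
  # fractional entry ages partition exactly too
  for (age in c(40.25, 47.8, 55.5, 63.999, 65)) {
    hb <- horizon_bands(age)
    expect_equal(sum(hb$exposure), 10, tolerance = 1e-9)
    expect_true(all(hb$exposure > 0 & hb$exposure <= 5))
  }
  expect_error(horizon_bands(39), class = "cvdrecal_validation_error")
  expect_error(horizon_bands(66), class = "cvdrecal_validation_error")
})

test_that("within-band CIF matches the competing-exponential closed form", {
  expect_identical(cif_band(0, 0.01, 5), 0)
  expect_identical(cif_band(0, 0, 5), 0)
  expect_equal(cif_band(0.002, 0, 5), 1 - exp(-0.01), tolerance = 1e-12)
  # frozen from an independent high-precision evaluation
  expect_equal(cif_band(0.002, 0.008, 5), 0.0097541150998571982,
               tolerance = 1e-12)
  expect_error(cif_band(-0.001, 0.01, 5),
               class = "cvdrecal_validation_error")
  expect_error(cif_band(0.001, 0.01, 0),
               class = "cvdrecal_validation_error")
})

test_that("two-band worked example reproduces the chained closed form", {
  tab <- two_band_table()
  p <- mean_profile("male", 40)
  # frozen: 0.25(1-e^-0.01) + e^-0.01 * 0.25(1-e^-0.02), high precision
  expect_equal(ten_year_risk_constant(p, tab, flat_means(), null_coefs()),
               0.0073886166128729558, tolerance = 1e-9)
  # smoking raises risk when beta_smoke > 0
  cf <- coefficients_set(beta_sbp = 0, beta_tc = 0, beta_smoke = 0.7)
  smoker <- risk_profile("male", 40, 140, 5.5, "TC", smoker = TRUE)
  expect_gt(ten_year_risk_constant(smoker, tab, flat_means(smoking = 0), cf),
            0.0073886166128729558)
})

test_that("zero mortality gives zero risk; risk is zero iff CVD hazard is zero", {
  grid <- expand.grid(sex = c("female", "male"),
                      age_band_start = seq(40, 70, 5),
                      stringsAsFactors = FALSE)
  zero <- mortality_table(data.frame(grid, deaths_cvd = 0,
                                     deaths_noncvd = 0, population = 1e5))
  p <- mean_profile("female", 52)
  expect_identical(ten_year_risk_constant(p, zero, flat_means(),
                                          null_coefs()), 0)
  # competing-only mortality: still zero CVD risk
  nc <- mortality_table(data.frame(grid, deaths_cvd = 0,
                                   deaths_noncvd = 300, population = 1e5))
  expect_identical(ten_year_risk_constant(p, nc, flat_means(),
                                          null_coefs()), 0)
  expect_gt(ten_year_risk_constant(p, flat_table(), flat_means(),
                                   null_coefs()), 0)
})

test_that("CIFs and survival conserve probability across random inputs", {
  set.seed(42)
  for (rep in 1:20) {
    params <- sim_params(seed = rep, m0_cvd = runif(1, 1e-4, 2e-3),
                         gamma_cvd = runif(1, 0, 0.12),
                         m0_noncvd = runif(1, 5e-4, 5e-3),
                         gamma_noncvd = runif(1, 0, 0.12))
    tab <- synth_mortality(params)
    p <- risk_profile(sample(c("female", "male"), 1), runif(1, 40, 65),
                      runif(1, 100, 200), runif(1, 3, 9), "TC",
                      sample(c(TRUE, FALSE), 1))
    o <- ten_year_outcomes_constant(p, tab, default_means(params),
                                    demo_coefs())
    expect_equal(o$cif_cvd + o$cif_noncvd + o$survival, 1,
                 tolerance = 1e-12)
    expect_true(o$cif_cvd >= 0 && o$cif_cvd <= 1)
  }
})

test_that("with no competing hazard the risk is the pure-exponential closed form", {
  grid <- expand.grid(sex = c("female", "male"),
                      age_band_start = seq(40, 70, 5),
                      stringsAsFactors = FALSE)
  deaths <- 20 + 10 * (grid$age_band_start - 40) / 5
  tab <- mortality_table(data.frame(grid, deaths_cvd = deaths,
                                    deaths_noncvd = 0, population = 1e5))
  for (age in c(40, 43, 57.5, 65)) {
    p <- mean_profile("male", age)
    hb <- horizon_bands(age)
    cum <- sum(vapply(seq_len(nrow(hb)), function(i)
      band_rates(tab, "male", hb$band_start[i])[["m_cvd"]] * hb$exposure[i],
      numeric(1)))
    expect_equal(ten_year_risk_constant(p, tab, flat_means(), null_coefs()),
                 1 - exp(-cum), tolerance = 1e-12)
  }
})

test_that("risk is monotone in each factor under the sign of its beta", {
  tab <- synth_mortality(sim_params(seed = 3))
  means <- default_means(sim_params(seed = 3))
  cf <- demo_coefs()
  set.seed(99)
  for (rep in 1:15) {
    sex <- sample(c("female", "male"), 1)
    age <- runif(1, 40, 65)
    sbp <- runif(1, 110, 190)
    tc <- runif(1, 4, 8)
    base <- ten_year_risk_constant(
      risk_profile(sex, age, sbp, tc, "TC", FALSE), tab, means, cf)
    up_sbp <- ten_year_risk_constant(
      risk_profile(sex, age, sbp + 10, tc, "TC", FALSE), tab, means, cf)
    up_tc <- ten_year_risk_constant(
      risk_profile(sex, age, sbp, tc + 1, "TC", FALSE), tab, means, cf)
    up_smoke <- ten_year_risk_constant(
      risk_profile(sex, age, sbp, tc, "TC", TRUE), tab, means, cf)
    expect_gte(up_sbp, base)
    expect_gte(up_tc, base)
    expect_gte(up_smoke, base)
  }
  # negative beta flips the direction
  cf_neg <- coefficients_set(beta_sbp = -0.01, beta_tc = 0, beta_smoke = 0)
  lo <- ten_year_risk_constant(risk_profile("male", 50, 120, 5, "TC"),
                               tab, means, cf_neg)
  hi <- ten_year_risk_constant(risk_profile("male", 50, 180, 5, "TC"),
                               tab, means, cf_neg)
  expect_lte(hi, lo)
})

test_that("vanishing rates approach the first-order cumulative-hazard limit", {
  eps <- 1e-6
  grid <- expand.grid(sex = c("female", "male"),
                      age_band_start = seq(40, 70, 5),
                      stringsAsFactors = FALSE)
  d_cvd <- (50 + 5 * (grid$age_band_start - 40)) * eps
  d_non <- (150 + 15 * (grid$age_band_start - 40)) * eps
  tab <- mortality_table(data.frame(grid, deaths_cvd = d_cvd,
                                    deaths_noncvd = d_non, population = 1e5))
  p <- mean_profile("male", 48)
  hb <- horizon_bands(48)
  cumhaz <- sum(vapply(seq_len(nrow(hb)), function(i)
    band_rates(tab, "male", hb$band_start[i])[["m_cvd"]] * hb$exposure[i],
    numeric(1)))
  risk <- ten_year_risk_constant(p, tab, flat_means(), null_coefs())
  expect_equal(risk / cumhaz, 1, tolerance = 1e-3)
})

test_that("interpolated and constant methods coincide for flat rates", {
  tab <- flat_table()
  means <- flat_means()
  cf <- demo_coefs()
  for (age in c(40, 47, 55, 61.3, 65)) {
    p <- risk_profile("female", age, 150, 6, "TC", TRUE)
    expect_equal(ten_year_risk_interpolated(p, tab, means, cf),
                 ten_year_risk_constant(p, tab, means, cf),
                 tolerance = 1e-9)
  }
})

test_that("interpolated method matches an independent year-by-year oracle", {
  params <- sim_params(seed = 11)
  tab <- synth_mortality(params)
  means <- default_means(params)
  cf <- demo_coefs()
  for (age in c(40, 52, 58.5, 65)) {
    p <- risk_profile("male", age, 160, 6.5, "TC", TRUE)
    hr <- sapply(seq(40, 70, 5), function(b)
      hazard_ratio(p, means, cf, b))
    names(hr) <- seq(40, 70, 5)
    expect_equal(ten_year_risk_interpolated(p, tab, means, cf),
                 interp_oracle(age, tab, "male", as.list(hr)),
                 tolerance = 1e-12)
  }
  # profile at the band means, null coefficients: oracle with HR = 1
  p0 <- mean_profile("male", 45)
  hr1 <- as.list(setNames(rep(1, 7), seq(40, 70, 5)))
  expect_equal(ten_year_risk_interpolated(p0, tab, flat_means(),
                                          null_coefs()),
               interp_oracle(45, tab, "male", hr1), tolerance = 1e-12)
})

test_that("strict hazard conversion uses -log(1-m) and stays close for small rates", {
  tab <- flat_table(m_cvd = 1e-3, m_noncvd = 3e-3)
  p <- mean_profile("male", 40)
  lax <- ten_year_risk_constant(p, tab, flat_means(), null_coefs())
  strict <- ten_year_risk_constant(p, tab, flat_means(), null_coefs(),
                                   strict_hazard = TRUE)
  expect_gt(strict, lax)        # -log(1-m) > m
  expect_equal(strict, lax, tolerance = 1e-2)
  h <- -log1p(-1e-3) * 10       # flat: exact closed form available
  hn <- -log1p(-3e-3) * 10
  expect_equal(strict, h / (h + hn) * (1 - exp(-(h + hn))),
               tolerance = 1e-12)
})
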