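# Shared fixture builders.  Everything is constructed in code; no files.

# A mortality table with the same rates in every band (per 100,000).
flat_table <- function(m_cvd = 1e-3, m_noncvd = 3e-3, population = 1e5) {
  grid <- expand.grid(sex = c("female", "male"),
                      age_band_start = seq(40, 70, 5),
                      stringsAsFactors = FALSE)
  mortality_table(data.frame(
    grid,
    deaths_cvd = m_cvd * population,
    deaths_noncvd = m_noncvd * population,
    population = population))
}

# The worked two-band example: band 40-44 rates (5e-4, 1.5e-3)/y, band
# 45-49 (1e-3, 3e-3)/y; later bands keep the 45-49 rates (unused for an
# age-40 entry).
two_band_table <- function() {
  grid <- expand.grid(sex = c("female", "male"),
                      age_band_start = seq(40, 70, 5),
                      stringsAsFactors = FALSE)
  first <- grid$age_band_start == 40
  mortality_table(data.frame(
    grid,
    deaths_cvd = ifelse(first, 50, 100),
    deaths_noncvd = ifelse(first, 150, 300),
    population = 1e5))
}

# Means constant across sex and band, so any profile can be placed exactly
# at the reference point.
flat_means <- function(sbp = 140, tc = 5.5, ratio = 4, smoking = 0.3) {
  grid <- expand.grid(sex = c("female", "male"),
                      age_band_start = seq(40, 70, 5),
                      stringsAsFactors = FALSE)
  risk_factor_means(data.frame(grid, mean_sbp = sbp, mean_tc = tc,
                               mean_ratio = ratio, smoking_prev = smoking))
}

null_coefs <- function() {
  coefficients_set(beta_sbp = 0, beta_tc = 0, beta_ratio = 0, beta_smoke = 0)
}

demo_coefs <- function() {
  coefficients_set(beta_sbp = 0.015, beta_tc = 0.25, beta_ratio = 0.35,
                   beta_smoke = 0.7, provenance = "test fixture")
}

# A profile sitting exactly at flat_means() (non-smoker handled via
# beta_smoke = 0 where HR = 1 is needed with smoking prevalence != 0).
mean_profile <- function(sex = "male", age = 40, chol_measure = "TC") {
  risk_profile(sex, age, 140, if (chol_measure == "TC") 5.5 else 4,
               chol_measure, smoker = FALSE)
}

# Independent year-by-year chaining oracle for the interpolated method:
# spreadsheet-style survival bookkeeping over 1-year steps, written without
# reference to the package's chaining code.
interp_oracle <- function(age, table, sex, hr_by_band) {
  e <- table$entries[table$entries$sex == sex, ]
  e <- e[order(e$age_band_start), ]
  mid <- e$age_band_start + 2.5
  m_cvd <- e$deaths_cvd / e$population
  m_non <- e$deaths_noncvd / e$population
  lin <- function(y, x) stats::approx(mid, y, xout = x, rule = 2)$y
  surv <- 1
  risk <- 0
  for (k in 0:9) {
    a <- age + k + 0.5
    hr <- hr_by_band[[as.character(5 * floor(a / 5))]]
    h1 <- lin(m_cvd, a) * hr
    h2 <- lin(m_non, a)
    h <- h1 + h2
    risk <- risk + surv * (if (h == 0) 0 else h1 / h * (1 - exp(-h)))
    surv <- surv * exp(-h)
  }
  risk
}
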