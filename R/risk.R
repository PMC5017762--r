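#' Hazard ratio of a profile against band-specific population means
#'
#' The proportional-hazards relative risk
#' \deqn{\mathrm{HR} = \exp\{\beta_{sbp}(x_{sbp}-\bar x_{sbp}) +
#'   \beta_{chol}(x_{chol}-\bar x_{chol}) +
#'   \beta_{smoke}(x_{smoke}-\bar x_{smoke})\}}
#' where the reference \eqn{\bar x} is the population mean vector of the
#' given 5-year band for the profile's sex, and smoking enters as the 0/1
#' indicator centred on the band's smoking prevalence.  A profile sitting
#' exactly at the band means therefore has HR = 1 and receives the observed
#' population rate unchanged.
#'
#' @param profile a [risk_profile()].
#' @param means a [risk_factor_means()].
#' @param coefs a [coefficients_set()].
#' @param band band start age.
#' @return a strictly positive scalar hazard ratio.
#' @export
hazard_ratio <- function(profile, means, coefs, band) {
  stopifnot(inherits(profile, "risk_profile"))
  b <- resolve_coefs(coefs, profile$sex, profile$chol_measure)
  xb <- band_means(means, profile$sex, band)
  mean_chol <- if (profile$chol_measure == "TC") xb$mean_tc else xb$mean_ratio
  lp <- b$beta_sbp * (profile$sbp - xb$mean_sbp) +
    b$beta_chol * (profile$chol_value - mean_chol) +
    b$beta_smoke * (as.numeric(profile$smoker) - xb$smoking_prev)
  exp(lp)
}

#' Within-band cumulative incidence under competing exponential hazards
#'
#' Probability of dying from the cause of interest within a band of length
#' `exposure` years, given constant cause-specific hazards and survival to
#' the band start:
#' \deqn{\frac{h_{cvd}}{h}\,(1 - e^{-h\,t}), \quad h = h_{cvd}+h_{noncvd}.}
#' Returns 0 when both hazards are zero.
#'
#' @param h_cvd annual cause-of-interest hazard, >= 0.
#' @param h_noncvd annual competing hazard, >= 0.
#' @param exposure years at risk in the band, > 0.
#' @return a probability in \[0, 1).
#' @export
cif_band <- function(h_cvd, h_noncvd, exposure) {
  if (!is.finite(h_cvd) || h_cvd < 0 || !is.finite(h_noncvd) || h_noncvd < 0)
    stop_validation("hazards must be finite and non-negative")
  check_number(exposure, "exposure", lo = 0, strict_lo = TRUE)
  h <- h_cvd + h_noncvd
  if (h == 0) return(0)
  (h_cvd / h) * (1 - exp(-h * exposure))
}

# Per-band hazards over a profile's 10-year horizon.  HR is recomputed in
# every band against that band's means; the competing (non-CVD) hazard is
# never modified by risk factors.  `strict_hazard` switches the rate-to-
# hazard conversion from the identity m ~ h to h = -log(1 - m).
profile_band_hazards <- function(profile, table, means, coefs,
                                 strict_hazard = FALSE) {
  hb <- horizon_bands(profile$age, table, profile$sex)
  conv <- if (strict_hazard) function(m) -log1p(-m) else identity
  hb$h_cvd <- NA_real_
  hb$h_noncvd <- NA_real_
  for (i in seq_len(nrow(hb))) {
    m <- band_rates(table, profile$sex, hb$band_start[i])
    hr <- hazard_ratio(profile, means, coefs, hb$band_start[i])
    hb$h_cvd[i] <- conv(m[["m_cvd"]]) * hr
    hb$h_noncvd[i] <- conv(m[["m_noncvd"]])
  }
  hb
}

# Chain piecewise-constant two-cause hazards into 10-year outcome
# probabilities.  `bands` needs columns h_cvd, h_noncvd, exposure.
chain_bands <- function(bands) {
  surv <- 1
  cif_cvd <- 0
  cif_noncvd <- 0
  for (i in seq_len(nrow(bands))) {
    t <- bands$exposure[i]
    h1 <- bands$h_cvd[i]
    h2 <- bands$h_noncvd[i]
    cif_cvd <- cif_cvd + surv * cif_band(h1, h2, t)
    cif_noncvd <- cif_noncvd + surv * cif_band(h2, h1, t)
    surv <- surv * exp(-(h1 + h2) * t)
  }
  list(cif_cvd = cif_cvd, cif_noncvd = cif_noncvd, survival = surv)
}

#' 10-year fatal-CVD risk, constant within-band rates
#'
#' The recalibrated absolute risk: the 10-year horizon from the profile's
#' age is partitioned along the 5-year band grid; within each band the
#' cause-specific hazards are constant (the observed CVD rate scaled by the
#' profile's hazard ratio against that band's means, and the unmodified
#' non-CVD rate); the cumulative incidence of CVD death is chained across
#' bands:
#' \deqn{R = \sum_b S(t_b)\,\frac{h_{cvd,b}}{h_b}(1 - e^{-h_b \Delta_b}),
#'   \qquad S(t_b) = \prod_{b' < b} e^{-h_{b'} \Delta_{b'}}.}
#' Mortality rates are not interpolated between bands: constant within-band
#' rates are what the Markov (current-band-only) assumption implies.
#'
#' @param profile a [risk_profile()].
#' @param table a [mortality_table()].
#' @param means a [risk_factor_means()].
#' @param coefs a [coefficients_set()].
#' @param strict_hazard if TRUE convert annual rates to hazards by
#'   \eqn{-\log(1-m)} instead of using the rate directly (the difference is
#'   below chart rounding resolution for rates under 0.05/year).
#' @return the 10-year cumulative incidence of CVD death, in \[0, 1\].
#' @examples
#' p <- sim_params(seed = 1)
#' tab <- synth_mortality(p)
#' mn <- default_means()
#' cf <- coefficients_set(beta_sbp = 0.015, beta_tc = 0.25, beta_smoke = 0.7)
#' ten_year_risk_constant(risk_profile("male", 60, 160, 6, smoker = TRUE),
#'                        tab, mn, cf)
#' @export
ten_year_risk_constant <- function(profile, table, means, coefs,
                                   strict_hazard = FALSE) {
  hb <- profile_band_hazards(profile, table, means, coefs, strict_hazard)
  chain_bands(hb)$cif_cvd
}

#' @rdname ten_year_risk_constant
#' @return `ten_year_outcomes_constant()` returns all three probabilities
#'   (`cif_cvd`, `cif_noncvd`, `survival`), which sum to 1.
#' @export
ten_year_outcomes_constant <- function(profile, table, means, coefs,
                                       strict_hazard = FALSE) {
  hb <- profile_band_hazards(profile, table, means, coefs, strict_hazard)
  chain_bands(hb)
}

# Interpolated annual rates: rates are anchored at band midpoints
# (start + 2.5) and joined linearly in age, with constant extrapolation
# beyond the outermost midpoints.
interp_rate_fun <- function(table, sex, strict_hazard = FALSE) {
  e <- table$entries[table$entries$sex == sex, ]
  e <- e[order(e$age_band_start), ]
  mid <- e$age_band_start + 2.5
  conv <- if (strict_hazard) function(m) -log1p(-m) else identity
  m_cvd <- conv(e$deaths_cvd / e$population)
  m_noncvd <- conv(e$deaths_noncvd / e$population)
  function(age) {
    c(m_cvd = stats::approx(mid, m_cvd, xout = age, rule = 2)$y,
      m_noncvd = stats::approx(mid, m_noncvd, xout = age, rule = 2)$y)
  }
}

#' 10-year fatal-CVD risk, interpolated rates (legacy method variant)
#'
#' The earlier chart generation interpolated the 5-year mortality rates
#' across age rather than holding them constant within bands.  This variant
#' reproduces that behaviour for sensitivity comparison: the horizon is
#' walked in 1-year steps; each step uses annual cause-specific rates
#' linearly interpolated (in age, between band midpoints, constant beyond
#' the ends) at the step midpoint, scaled by the hazard ratio of the band
#' containing that midpoint; chaining is as in [ten_year_risk_constant()].
#' When all bands share identical rates the two methods agree exactly.
#'
#' @inheritParams ten_year_risk_constant
#' @return the 10-year cumulative incidence of CVD death, in \[0, 1\].
#' @export
ten_year_risk_interpolated <- function(profile, table, means, coefs,
                                       strict_hazard = FALSE) {
  stopifnot(inherits(profile, "risk_profile"))
  horizon_bands(profile$age, table, profile$sex)  # coverage check
  rate_at <- interp_rate_fun(table, profile$sex, strict_hazard)
  steps <- data.frame(start = profile$age + 0:9, exposure = 1)
  steps$h_cvd <- NA_real_
  steps$h_noncvd <- NA_real_
  for (i in seq_len(nrow(steps))) {
    a_mid <- steps$start[i] + 0.5
    m <- rate_at(a_mid)
    hr <- hazard_ratio(profile, means, coefs, band_start(a_mid))
    steps$h_cvd[i] <- m[["m_cvd"]] * hr
    steps$h_noncvd[i] <- m[["m_noncvd"]]
  }
  chain_bands(steps)$cif_cvd
}

#' @rdname ten_year_risk_constant
#' @param method "constant" (current method) or "interpolated" (legacy
#'   variant).
#' @export
ten_year_risk <- function(profile, table, means, coefs,
                          method = c("constant", "interpolated"),
                          strict_hazard = FALSE) {
  method <- match.arg(method)
  if (method == "constant")
    ten_year_risk_constant(profile, table, means, coefs, strict_hazard)
  else
    ten_year_risk_interpolated(profile, table, means, coefs, strict_hazard)
}
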