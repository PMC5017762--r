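#' Parameters of the synthetic-data generators
#'
#' One parameter object drives all generators: Gompertz cause-specific
#' mortality (annual rate \eqn{m(a) = m_0 e^{\gamma (a - 40)}} times a sex
#' multiplier, evaluated at band midpoints), approximately normal SBP and
#' cholesterol with linear age trends, Bernoulli smoking, log-normal survey
#' weights, and planted missingness and prior-CVD flags for filter testing.
#'
#' Defaults emulate the conditions of a contemporary western European
#' population study: CVD mortality around 5/10,000 per year at age 40
#' doubling roughly every 8 years and higher in men; SBP near 120/127 mmHg
#' (women/men) at 40, rising ~0.5 mmHg per year; total cholesterol near
#' 5.2-5.5 mmol/L; HDL-C near 1.6/1.3 mmol/L; smoking prevalence 24%/30%;
#' prior-CVD prevalence 5.1% in women and 10.9% in men and ~3.8% of
#' records with a missing variable (the exclusion fractions typical of a
#' national examination survey of 40-65 year olds).
#'
#' @param n number of survey records.
#' @param seed RNG seed; mandatory, every stochastic generator is seeded.
#' @param m0_cvd,m0_noncvd annual death rates at age 40 (reference sex:
#'   male).
#' @param gamma_cvd,gamma_noncvd Gompertz log-slopes per year of age.
#' @param sexmult_cvd,sexmult_noncvd named rate multipliers per sex.
#' @param sbp_mean40,sbp_trend,sbp_sd SBP distribution: mean at age 40 per
#'   sex (mmHg), mmHg per year of age, SD.
#' @param tc_mean40,tc_trend,tc_sd total cholesterol, mmol/L.
#' @param hdl_mean,hdl_sd HDL cholesterol, mmol/L (truncated above 0.3).
#' @param smoking_prev smoking prevalence per sex.
#' @param weight_meanlog,weight_sdlog log-normal survey-weight parameters.
#' @param missing_rate fraction of records with one variable blanked.
#' @param prior_cvd_rate named per-sex probability of a prior-CVD flag.
#' @param age_range ages drawn uniformly over this interval.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n = 5000, seed,
                       m0_cvd = 5e-4, gamma_cvd = 0.090,
                       m0_noncvd = 1.5e-3, gamma_noncvd = 0.085,
                       sexmult_cvd = c(female = 0.55, male = 1),
                       sexmult_noncvd = c(female = 0.65, male = 1),
                       sbp_mean40 = c(female = 120, male = 127),
                       sbp_trend = 0.5, sbp_sd = 16,
                       tc_mean40 = c(female = 5.2, male = 5.5),
                       tc_trend = 0.015, tc_sd = 1.0,
                       hdl_mean = c(female = 1.6, male = 1.3),
                       hdl_sd = 0.35,
                       smoking_prev = c(female = 0.24, male = 0.30),
                       weight_meanlog = 0, weight_sdlog = 0.5,
                       missing_rate = 0.038,
                       prior_cvd_rate = c(female = 0.051, male = 0.109),
                       age_range = c(38, 75)) {
  if (missing(seed)) stop_validation("sim_params requires a seed")
  check_number(seed, "seed")
  check_number(n, "n", lo = 1)
  for (nm in c("m0_cvd", "gamma_cvd", "m0_noncvd", "gamma_noncvd",
               "sbp_trend", "tc_trend"))
    check_number(get(nm), nm, lo = 0)
  for (nm in c("sbp_sd", "tc_sd", "hdl_sd", "weight_sdlog"))
    check_number(get(nm), nm, lo = 0, strict_lo = TRUE)
  for (nm in c("missing_rate")) check_number(get(nm), nm, lo = 0, hi = 1)
  for (v in list(sexmult_cvd, sexmult_noncvd, sbp_mean40, tc_mean40,
                 hdl_mean, smoking_prev, prior_cvd_rate))
    if (!all(SEXES %in% names(v)))
      stop_validation("per-sex parameters need named entries for both sexes")
  if (any(smoking_prev < 0 | smoking_prev > 1) ||
      any(prior_cvd_rate < 0 | prior_cvd_rate > 1))
    stop_validation("probabilities must lie in [0, 1]")
  structure(as.list(environment()), class = "sim_params")
}

# Expected annual cause-specific rate at an exact age.
gompertz_rate <- function(params, cause = c("cvd", "noncvd"), sex, age) {
  cause <- match.arg(cause)
  m0 <- if (cause == "cvd") params$m0_cvd else params$m0_noncvd
  g <- if (cause == "cvd") params$gamma_cvd else params$gamma_noncvd
  mult <- if (cause == "cvd") params$sexmult_cvd else params$sexmult_noncvd
  m0 * exp(g * (age - 40)) * mult[[sex]]
}

#' Synthetic national mortality table
#'
#' Builds a [mortality_table()] for sex x band 40-44 ... 70-74 from the
#' Gompertz rates in `params`, evaluated at each band midpoint.  In
#' deterministic mode (default) death counts are set to their expectation
#' `population * m`; otherwise they are Poisson draws under the params
#' seed.
#'
#' @param params a [sim_params()].
#' @param deterministic expectation counts (TRUE) or Poisson counts.
#' @param population person-years per sex x band cell.
#' @return a [mortality_table()].
#' @export
synth_mortality <- function(params, deterministic = TRUE,
                            population = 1e5) {
  stopifnot(inherits(params, "sim_params"))
  grid <- expand.grid(sex = SEXES, age_band_start = seq(40, 70, 5),
                      stringsAsFactors = FALSE)
  mid <- grid$age_band_start + 2.5
  m_cvd <- mapply(function(sx, a) gompertz_rate(params, "cvd", sx, a),
                  grid$sex, mid)
  m_noncvd <- mapply(function(sx, a) gompertz_rate(params, "noncvd", sx, a),
                     grid$sex, mid)
  if (deterministic) {
    d_cvd <- population * m_cvd
    d_noncvd <- population * m_noncvd
  } else {
    set.seed(params$seed)
    d_cvd <- stats::rpois(nrow(grid), population * m_cvd)
    d_noncvd <- stats::rpois(nrow(grid), population * m_noncvd)
  }
  mortality_table(data.frame(sex = grid$sex,
                             age_band_start = grid$age_band_start,
                             deaths_cvd = d_cvd, deaths_noncvd = d_noncvd,
                             population = population))
}

#' Deterministic population mean risk-factor levels
#'
#' The [risk_factor_means()] implied directly by the generator's configured
#' distributions, evaluated at band midpoints (no sampling).  Useful as a
#' noise-free reference and for worked examples; [estimate_means()] is the
#' survey-based estimator that should recover these values.
#'
#' @param params a [sim_params()]; any seed works, nothing is drawn.
#' @return a [risk_factor_means()] covering bands 40-44 through 70-74.
#' @export
default_means <- function(params = sim_params(seed = 0)) {
  stopifnot(inherits(params, "sim_params"))
  grid <- expand.grid(sex = SEXES, age_band_start = seq(40, 70, 5),
                      stringsAsFactors = FALSE)
  mid <- grid$age_band_start + 2.5
  mean_tc <- params$tc_mean40[grid$sex] + params$tc_trend * (mid - 40)
  risk_factor_means(data.frame(
    sex = grid$sex,
    age_band_start = grid$age_band_start,
    mean_sbp = params$sbp_mean40[grid$sex] + params$sbp_trend * (mid - 40),
    mean_tc = mean_tc,
    mean_ratio = mean_tc / params$hdl_mean[grid$sex],
    smoking_prev = params$smoking_prev[grid$sex]))
}

#' Synthetic survey cohort with planted defects
#'
#' Draws `n` survey records under the params seed: uniform ages, normal SBP
#' and cholesterol with age trends, truncated-normal HDL (> 0.3 mmol/L),
#' Bernoulli smoking, log-normal weights; then plants prior-CVD flags at the
#' per-sex rates and blanks one randomly chosen required variable in a
#' `missing_rate` fraction of records.  The returned ground-truth
#' disposition labels use the same sequential accounting as
#' [filter_cohort()] (missing first, then prior CVD, then age outside
#' \[40, 65\]), so filter tallies can be checked against the plan.
#'
#' @param params a [sim_params()].
#' @return list with `records` (cohort data.frame), `truth` (planted
#'   disposition per record) and `params`.
#' @export
synth_survey <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n
  sex <- sample(SEXES, n, replace = TRUE)
  age <- stats::runif(n, params$age_range[1], params$age_range[2])
  sbp <- stats::rnorm(n, params$sbp_mean40[sex] +
                        params$sbp_trend * (age - 40), params$sbp_sd)
  tc <- stats::rnorm(n, params$tc_mean40[sex] +
                       params$tc_trend * (age - 40), params$tc_sd)
  hdl <- stats::rnorm(n, params$hdl_mean[sex], params$hdl_sd)
  while (any(hdl <= 0.3))  # truncation by redraw, still seed-determined
    hdl[hdl <= 0.3] <- stats::rnorm(sum(hdl <= 0.3),
                                    params$hdl_mean[sex[hdl <= 0.3]],
                                    params$hdl_sd)
  smoker <- stats::rbinom(n, 1, params$smoking_prev[sex])
  weight <- stats::rlnorm(n, params$weight_meanlog, params$weight_sdlog)
  any_prior <- stats::rbinom(n, 1, params$prior_cvd_rate[sex]) == 1
  which_flag <- sample(c("prior_chd", "prior_stroke", "prior_hf"), n,
                       replace = TRUE)
  records <- data.frame(
    id = sprintf("r%06d", seq_len(n)), age = age, sex = sex, sbp = sbp,
    tc = tc, hdl = hdl, smoker = smoker, weight = weight,
    prior_chd = FALSE, prior_stroke = FALSE, prior_hf = FALSE)
  for (fl in c("prior_chd", "prior_stroke", "prior_hf"))
    records[[fl]][any_prior & which_flag == fl] <- TRUE
  plant_missing <- stats::runif(n) < params$missing_rate
  blank_var <- sample(COHORT_REQUIRED[COHORT_REQUIRED != "id"], n,
                      replace = TRUE)
  for (i in which(plant_missing)) records[i, blank_var[i]] <- NA
  truth <- rep("eligible", n)
  truth[plant_missing] <- "missing"
  truth[!plant_missing & any_prior] <- "prior_cvd"
  truth[!plant_missing & !any_prior & (age < 40 | age > 65)] <- "age"
  list(records = records, truth = truth, params = params)
}

#' Survey-based estimation of population mean risk-factor levels
#'
#' The saturated-model estimator of band means: survey-weighted means of
#' SBP, TC, the per-person TC/HDL-C ratio, and smoking prevalence within
#' each sex x 5-year band (equivalent to regression on age as a categorical
#' 5-year factor).  Records with any missing ingredient are dropped.
#'
#' @param records cohort records (see [filter_cohort()] for the schema).
#' @param weights survey weights; defaults to the records' `weight` column.
#' @param bands band start ages to estimate (default 40-70).
#' @return a [risk_factor_means()].
#' @export
estimate_means <- function(records, weights = records$weight,
                           bands = seq(40, 70, 5)) {
  records <- as.data.frame(records)
  need <- c("age", "sex", "sbp", "tc", "hdl", "smoker")
  ok <- stats::complete.cases(records[need]) & !is.na(weights) & weights > 0
  r <- records[ok, ]
  w <- weights[ok]
  b <- band_start(r$age)
  out <- expand.grid(sex = SEXES, age_band_start = bands,
                     stringsAsFactors = FALSE)
  wmean <- function(x, wt) sum(wt * x) / sum(wt)
  for (col in c("mean_sbp", "mean_tc", "mean_ratio", "smoking_prev"))
    out[[col]] <- NA_real_
  for (i in seq_len(nrow(out))) {
    sel <- r$sex == out$sex[i] & b == out$age_band_start[i]
    if (!any(sel))
      stop_validation("no usable records in cell (", out$sex[i], ", band ",
                      band_label(out$age_band_start[i]), ")")
    out$mean_sbp[i] <- wmean(r$sbp[sel], w[sel])
    out$mean_tc[i] <- wmean(r$tc[sel], w[sel])
    out$mean_ratio[i] <- wmean(r$tc[sel] / r$hdl[sel], w[sel])
    out$smoking_prev[i] <- wmean(as.numeric(r$smoker[sel]), w[sel])
  }
  risk_factor_means(out)
}

#' Monte-Carlo lifetimes through piecewise-constant competing hazards
#'
#' The empirical counterpart of the analytic cumulative incidence, used as
#' a correctness oracle: `n` individuals are walked through the band
#' sequence; in each band, times to CVD death and to non-CVD death are
#' drawn from the band's exponentials, the earliest event within the band's
#' exposure wins, and survivors advance to the next band.
#'
#' @param bands data.frame with columns `h_cvd`, `h_noncvd`, `exposure`
#'   (e.g. from the risk engine's horizon).
#' @param n number of simulated individuals.
#' @param seed RNG seed.
#' @return list: `fraction` dying of CVD within the horizon, its binomial
#'   `se`, and `n`.
#' @export
simulate_deaths <- function(bands, n, seed) {
  check_number(n, "n", lo = 1)
  check_number(seed, "seed")
  bands <- as.data.frame(bands)
  if (any(bands$h_cvd < 0) || any(bands$h_noncvd < 0))
    stop_validation("hazards must be non-negative")
  set.seed(seed)
  alive <- rep(TRUE, n)
  died_cvd <- rep(FALSE, n)
  rexp_safe <- function(k, rate)  # rate 0 => event never happens
    if (rate == 0) rep(Inf, k) else stats::rexp(k, rate)
  for (i in seq_len(nrow(bands))) {
    k <- sum(alive)
    if (k == 0) break
    t_cvd <- rexp_safe(k, bands$h_cvd[i])
    t_non <- rexp_safe(k, bands$h_noncvd[i])
    t_min <- pmin(t_cvd, t_non)
    event <- t_min < bands$exposure[i]
    idx <- which(alive)
    died_cvd[idx[event & t_cvd <= t_non]] <- TRUE
    alive[idx[event]] <- FALSE
  }
  f <- mean(died_cvd)
  list(fraction = f, se = sqrt(f * (1 - f) / n), n = n)
}
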