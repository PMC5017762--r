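#' Cause-specific mortality table
#'
#' National mortality statistics aggregated by sex and 5-year age band:
#' counts of CVD deaths and non-CVD deaths together with the population
#' denominator (person-years).  The derived annual rates
#' \eqn{m = \mathrm{deaths}/\mathrm{population}} are the baseline
#' cause-specific hazards of the recalibration.
#'
#' @param entries data.frame with columns `sex` ("female"/"male"),
#'   `age_band_start` (multiples of 5), `deaths_cvd`, `deaths_noncvd`
#'   (counts, possibly non-integer in expectation mode) and `population`
#'   (person-years, strictly positive).
#' @param cause_definition free-text cause-of-death definition recorded as
#'   metadata; defaults to the ICD-10 CVD set used for the German charts.
#' @return an object of class `mortality_table`.
#' @export
mortality_table <- function(entries,
                            cause_definition =
                              "ICD-10 I10-I15, I20-I25, I44-I51, I61-I73") {
  req <- c("sex", "age_band_start", "deaths_cvd", "deaths_noncvd", "population")
  miss <- setdiff(req, names(entries))
  if (length(miss))
    stop_validation("mortality table missing column(s): ",
                    paste(miss, collapse = ", "))
  entries <- as.data.frame(entries)[req]
  if (!all(entries$sex %in% SEXES))
    stop_validation("mortality table sex values must be in {",
                    paste(SEXES, collapse = ", "), "}")
  if (!all(SEXES %in% entries$sex))
    stop_validation("mortality table must contain both sexes")
  if (any(entries$age_band_start %% 5 != 0))
    stop_validation("age_band_start values must be multiples of 5")
  key <- paste(entries$sex, entries$age_band_start)
  if (anyDuplicated(key))
    stop_validation("duplicate (sex, band) entry: ", key[duplicated(key)][1])
  if (any(!is.finite(entries$population) | entries$population <= 0))
    stop_validation("population must be > 0 in every row")
  for (col in c("deaths_cvd", "deaths_noncvd"))
    if (any(!is.finite(entries[[col]]) | entries[[col]] < 0))
      stop_validation(col, " must be non-negative in every row")
  m <- (entries$deaths_cvd + entries$deaths_noncvd) / entries$population
  if (any(m >= 1))
    stop_validation("derived annual death rate >= 1/year; counts and ",
                    "population are inconsistent")
  for (sx in SEXES) {
    have <- sort(entries$age_band_start[entries$sex == sx])
    need <- seq(40, 70, by = 5)
    gap <- setdiff(need, have)
    if (length(gap))
      stop_validation("mortality table for sex '", sx,
                      "' does not cover band ", band_label(gap[1]),
                      " (bands 40-44 through 70-74 are required)")
  }
  entries <- entries[order(entries$sex, entries$age_band_start), ]
  rownames(entries) <- NULL
  structure(list(entries = entries, cause_definition = cause_definition),
            class = "mortality_table")
}

#' @export
print.mortality_table <- function(x, ...) {
  cat("Cause-specific mortality table (", x$cause_definition, ")\n", sep = "")
  print(x$entries)
  invisible(x)
}

#' Cause-specific annual death rates for one sex and band
#'
#' @param table a [mortality_table()].
#' @param sex "female" or "male".
#' @param band band start age (e.g. 40 for band 40-44).
#' @return named numeric vector `c(m_cvd =, m_noncvd =)` of per-year rates.
#' @examples
#' tab <- synth_mortality(sim_params(seed = 1))
#' band_rates(tab, "male", 60)
#' @export
band_rates <- function(table, sex, band) {
  stopifnot(inherits(table, "mortality_table"))
  check_sex(sex)
  e <- table$entries
  i <- which(e$sex == sex & e$age_band_start == band)
  if (length(i) != 1L)
    stop_validation("no mortality entry for sex '", sex, "', band ",
                    band_label(band))
  if (e$population[i] <= 0)
    stop_validation("population <= 0 for sex '", sex, "', band ",
                    band_label(band))
  c(m_cvd = e$deaths_cvd[i] / e$population[i],
    m_noncvd = e$deaths_noncvd[i] / e$population[i])
}

#' Population mean risk-factor levels by sex and band
#'
#' The reference point of the hazard-ratio computation: the national mean
#' systolic blood pressure (mmHg), total cholesterol (mmol/L), TC/HDL-C
#' ratio and smoking prevalence, per sex and 5-year age band.  An
#' individual's relative risk is `exp(beta' (x - xbar))` against the means
#' of each band the 10-year horizon passes through.
#'
#' @param entries data.frame with columns `sex`, `age_band_start`,
#'   `mean_sbp`, `mean_tc`, `mean_ratio`, `smoking_prev`.
#' @return an object of class `risk_factor_means`.
#' @export
risk_factor_means <- function(entries) {
  req <- c("sex", "age_band_start", "mean_sbp", "mean_tc", "mean_ratio",
           "smoking_prev")
  miss <- setdiff(req, names(entries))
  if (length(miss))
    stop_validation("risk-factor means missing column(s): ",
                    paste(miss, collapse = ", "))
  entries <- as.data.frame(entries)[req]
  if (!all(entries$sex %in% SEXES))
    stop_validation("means sex values must be in {",
                    paste(SEXES, collapse = ", "), "}")
  key <- paste(entries$sex, entries$age_band_start)
  if (anyDuplicated(key))
    stop_validation("duplicate (sex, band) means entry: ",
                    key[duplicated(key)][1])
  rng <- list(mean_sbp = c(60, 250), mean_tc = c(1, 15),
              mean_ratio = c(1, 15), smoking_prev = c(0, 1))
  for (col in names(rng)) {
    bad <- !is.finite(entries[[col]]) | entries[[col]] < rng[[col]][1] |
      entries[[col]] > rng[[col]][2]
    if (any(bad))
      stop_validation(col, " = ", entries[[col]][bad][1],
                      " outside plausible range [", rng[[col]][1], ", ",
                      rng[[col]][2], "]")
  }
  entries <- entries[order(entries$sex, entries$age_band_start), ]
  rownames(entries) <- NULL
  structure(list(entries = entries), class = "risk_factor_means")
}

#' @export
print.risk_factor_means <- function(x, ...) {
  cat("Population mean risk-factor levels\n")
  print(x$entries)
  invisible(x)
}

band_means <- function(means, sex, band) {
  stopifnot(inherits(means, "risk_factor_means"))
  e <- means$entries
  i <- which(e$sex == sex & e$age_band_start == band)
  if (length(i) != 1L)
    stop_validation("no risk-factor means for sex '", sex, "', band ",
                    band_label(band))
  e[i, c("mean_sbp", "mean_tc", "mean_ratio", "smoking_prev")]
}

#' Log hazard-ratio coefficients
#'
#' The relative-risk component of the recalibration: log hazard ratios per
#' mmHg of systolic blood pressure, per mmol/L of total cholesterol, per
#' unit of TC/HDL-C ratio, and for current smoking.  These come from an
#' external proportional-hazards analysis (for the German charts, the SCORE
#' project database); they are configuration with a provenance string, never
#' constants of this package.
#'
#' @param beta_sbp log HR per mmHg.
#' @param beta_tc log HR per mmol/L total cholesterol.
#' @param beta_ratio log HR per unit TC/HDL-C.
#' @param beta_smoke log HR, current smoker vs non-smoker.
#' @param sex optional named list of per-sex overrides, e.g.
#'   `list(male = list(beta_smoke = 0.8))`.
#' @param provenance free-text source description.
#' @return an object of class `coefficients_set`.
#' @export
coefficients_set <- function(beta_sbp, beta_tc = NULL, beta_ratio = NULL,
                             beta_smoke = 0, sex = NULL,
                             provenance = "unspecified") {
  for (nm in c("beta_sbp", "beta_smoke")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_validation(nm, " must be a single finite number")
  }
  for (nm in c("beta_tc", "beta_ratio")) {
    v <- get(nm)
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || !is.finite(v)))
      stop_validation(nm, " must be NULL or a single finite number")
  }
  if (!is.null(sex)) {
    bad <- setdiff(names(sex), SEXES)
    if (length(bad))
      stop_validation("unknown sex override(s): ", paste(bad, collapse = ", "))
  }
  structure(list(beta_sbp = beta_sbp, beta_tc = beta_tc,
                 beta_ratio = beta_ratio, beta_smoke = beta_smoke,
                 sex = sex, provenance = provenance),
            class = "coefficients_set")
}

#' @export
print.coefficients_set <- function(x, ...) {
  cat("Log hazard-ratio coefficients (", x$provenance, ")\n", sep = "")
  cat(sprintf("  beta_sbp   = %s per mmHg\n", format(x$beta_sbp)))
  cat(sprintf("  beta_tc    = %s per mmol/L\n",
              if (is.null(x$beta_tc)) "<unset>" else format(x$beta_tc)))
  cat(sprintf("  beta_ratio = %s per TC/HDL-C unit\n",
              if (is.null(x$beta_ratio)) "<unset>" else format(x$beta_ratio)))
  cat(sprintf("  beta_smoke = %s smoker vs non-smoker\n",
              format(x$beta_smoke)))
  if (!is.null(x$sex))
    cat("  per-sex overrides for:", paste(names(x$sex), collapse = ", "), "\n")
  invisible(x)
}

# Resolve coefficients for one sex (apply per-sex overrides) and one
# cholesterol measure.  Errors when the needed cholesterol beta is unset.
resolve_coefs <- function(coefs, sex, chol_measure) {
  stopifnot(inherits(coefs, "coefficients_set"))
  out <- coefs[c("beta_sbp", "beta_tc", "beta_ratio", "beta_smoke")]
  ov <- coefs$sex[[sex]]
  if (!is.null(ov)) out[names(ov)] <- ov
  bchol <- switch(chol_measure, TC = out$beta_tc, RATIO = out$beta_ratio,
                  stop_validation("chol_measure must be 'TC' or 'RATIO'"))
  if (is.null(bchol))
    stop_validation("no cholesterol coefficient configured for measure '",
                    chol_measure, "'")
  list(beta_sbp = out$beta_sbp, beta_chol = bchol,
       beta_smoke = out$beta_smoke)
}

#' An individual's risk-factor profile
#'
#' @param sex "female" or "male".
#' @param age age in years, in \[40, 65\].
#' @param sbp systolic blood pressure, mmHg.
#' @param chol_value total cholesterol (mmol/L) or TC/HDL-C ratio, per
#'   `chol_measure`.
#' @param chol_measure "TC" or "RATIO".
#' @param smoker logical, current smoker.
#' @return an object of class `risk_profile`.
#' @export
risk_profile <- function(sex, age, sbp, chol_value, chol_measure = "TC",
                         smoker = FALSE) {
  check_sex(sex)
  check_number(age, "age", lo = 40, hi = 65)
  check_number(sbp, "sbp", lo = 0, strict_lo = TRUE)
  check_number(chol_value, "chol_value", lo = 0, strict_lo = TRUE)
  if (!chol_measure %in% c("TC", "RATIO"))
    stop_validation("chol_measure must be 'TC' or 'RATIO'")
  if (!is.logical(smoker) || length(smoker) != 1L || is.na(smoker))
    stop_validation("smoker must be TRUE or FALSE")
  structure(list(sex = sex, age = age, sbp = sbp, chol_value = chol_value,
                 chol_measure = chol_measure, smoker = smoker),
            class = "risk_profile")
}
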