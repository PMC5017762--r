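# Variables required to compute a risk and apply the exclusion rules.
COHORT_REQUIRED <- c("age", "sex", "sbp", "tc", "hdl", "smoker", "weight",
                     "prior_chd", "prior_stroke", "prior_hf")

#' Eligibility filtering of survey records
#'
#' Applies the chart-application exclusion cascade, in this fixed order:
#' records missing any risk variable or any prior-CVD flag are dropped
#' first; of the remainder, records with a history of major CVD (coronary
#' heart disease, stroke or heart failure) are dropped; finally records
#' outside the supported age range are dropped.  A record failing several
#' rules is counted once, at the first failing step.
#'
#' @param records data.frame of cohort records (columns `id`, `age`, `sex`,
#'   `sbp`, `tc`, `hdl`, `smoker`, `weight`, `prior_chd`, `prior_stroke`,
#'   `prior_hf`; empty/NA = missing).
#' @param age_min,age_max supported age range (default 40-65).
#' @return a list with `eligible` (the surviving records) and `report`, an
#'   `eligibility_report` holding the step tallies and the per-record
#'   disposition labels ("eligible", "missing", "prior_cvd", "age").
#' @export
filter_cohort <- function(records, age_min = 40, age_max = 65) {
  records <- as.data.frame(records)
  miss_col <- setdiff(COHORT_REQUIRED, names(records))
  if (length(miss_col))
    stop_validation("cohort records missing column(s): ",
                    paste(miss_col, collapse = ", "))
  n <- nrow(records)
  disposition <- rep("eligible", n)
  missing_any <- Reduce(`|`, lapply(COHORT_REQUIRED,
                                    function(v) is.na(records[[v]])))
  bad_weight <- !missing_any & records$weight <= 0
  if (any(bad_weight)) {
    warning(sum(bad_weight), " record(s) with non-positive weight treated ",
            "as missing", call. = FALSE)
    missing_any <- missing_any | bad_weight
  }
  disposition[missing_any] <- "missing"
  prior <- !missing_any & (records$prior_chd | records$prior_stroke |
                             records$prior_hf)
  disposition[prior] <- "prior_cvd"
  age_out <- !missing_any & !prior &
    (records$age < age_min | records$age > age_max)
  disposition[age_out] <- "age"
  report <- structure(list(
    n_input = n,
    n_excluded_missing = sum(missing_any),
    n_excluded_prior_cvd = sum(prior),
    n_excluded_age = sum(age_out),
    n_eligible = sum(disposition == "eligible"),
    disposition = disposition,
    age_range = c(age_min, age_max)
  ), class = "eligibility_report")
  list(eligible = records[disposition == "eligible", , drop = FALSE],
       report = report)
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat(sprintf("Cohort eligibility: %d records in\n", x$n_input))
  cat(sprintf("  excluded, missing data : %d\n", x$n_excluded_missing))
  cat(sprintf("  excluded, prior CVD    : %d\n", x$n_excluded_prior_cvd))
  cat(sprintf("  excluded, age outside [%d, %d]: %d\n",
              x$age_range[1], x$age_range[2], x$n_excluded_age))
  cat(sprintf("  eligible               : %d\n", x$n_eligible))
  invisible(x)
}

#' Per-record 10-year risk for a cohort
#'
#' Computes each eligible record's 10-year fatal-CVD risk directly from the
#' risk formula at the exact recorded age (no chart rounding), using the
#' three-band horizon partition for intermediate ages.  For the TC/HDL-C
#' chart version the ratio is formed per person as `tc / hdl`.
#'
#' @param records eligible cohort records (see [filter_cohort()]).
#' @param table a [mortality_table()].
#' @param means a [risk_factor_means()].
#' @param coefs a [coefficients_set()].
#' @param chol_measure "TC" or "RATIO".
#' @param method "constant" or "interpolated".
#' @param strict_hazard passed to the risk engine.
#' @return data.frame with columns `id` and `risk`.
#' @export
apply_risk <- function(records, table, means, coefs,
                       chol_measure = c("TC", "RATIO"),
                       method = c("constant", "interpolated"),
                       strict_hazard = FALSE) {
  chol_measure <- match.arg(chol_measure)
  method <- match.arg(method)
  records <- as.data.frame(records)
  risk <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    chol <- if (chol_measure == "TC") r$tc else r$tc / r$hdl
    p <- tryCatch(
      risk_profile(r$sex, r$age, r$sbp, chol, chol_measure,
                   as.logical(r$smoker)),
      cvdrecal_validation_error = function(e)
        stop_validation("record '", r$id, "': ", conditionMessage(e)))
    tryCatch(
      ten_year_risk(p, table, means, coefs, method, strict_hazard),
      cvdrecal_validation_error = function(e)
        stop_validation("record '", r$id, "': ", conditionMessage(e)))
  }, numeric(1))
  data.frame(id = records$id, risk = risk)
}

# Survey-weighted mean of y with a Taylor-linearized SE (weights taken as
# given; no stratum/cluster structure).  For the Hajek mean
# ybar = sum(w y)/sum(w), the with-replacement linearization is
# var = n/(n-1) * sum_i (w_i (y_i - ybar) / W)^2.
weighted_estimate <- function(y, w, ci_level = 0.95, clamp = c(0, 1)) {
  if (!length(y)) stop_validation("empty input")
  if (length(y) != length(w)) stop_validation("y and w lengths differ")
  if (any(!is.finite(w)) || any(w <= 0))
    stop_validation("weights must be finite and > 0")
  W <- sum(w)
  est <- sum(w * y) / W
  n <- length(y)
  se <- if (n == 1) 0 else {
    d <- w * (y - est) / W
    sqrt(n / (n - 1) * sum(d^2))
  }
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  lo <- est - z * se
  hi <- est + z * se
  if (!is.null(clamp)) {
    lo <- max(clamp[1], lo)
    hi <- min(clamp[2], hi)
  }
  structure(list(estimate = est, se = se, ci_low = lo, ci_high = hi,
                 n_unweighted = n, ci_level = ci_level),
            class = "weighted_estimate")
}

#' @export
print.weighted_estimate <- function(x, ...) {
  cat(sprintf("%.4f [%.0f%% CI %.4f-%.4f], SE %.4f, n = %d\n",
              x$estimate, 100 * x$ci_level, x$ci_low, x$ci_high,
              x$se, x$n_unweighted))
  invisible(x)
}

#' Survey-weighted high-risk prevalence
#'
#' Weighted proportion of people at high risk — 10-year fatal-CVD risk at
#' or above the guideline threshold (5% by default, the "5% or more" rule)
#' — with a Taylor-linearized standard error and a normal-approximation
#' confidence interval truncated to \[0, 1\].  Weights are taken as given;
#' stratum/cluster design information is not used.
#'
#' @param risks per-person 10-year risks in \[0, 1\].
#' @param weights positive survey weights, aligned with `risks`.
#' @param threshold high-risk cut-point (inclusive), default 0.05.
#' @param ci_level confidence level, default 0.95.
#' @return a `weighted_estimate`.
#' @export
weighted_high_risk_prevalence <- function(risks, weights, threshold = 0.05,
                                          ci_level = 0.95) {
  check_number(threshold, "threshold", lo = 0, hi = 1, strict_lo = TRUE)
  weighted_estimate(as.numeric(risks >= threshold), weights, ci_level)
}

#' Survey-weighted mean risk
#'
#' @inheritParams weighted_high_risk_prevalence
#' @return a `weighted_estimate` of the weighted mean 10-year risk.
#' @export
weighted_mean_risk <- function(risks, weights, ci_level = 0.95) {
  weighted_estimate(risks, weights, ci_level)
}
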