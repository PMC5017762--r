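#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' ICC(A,1): the single-measurement absolute-agreement intraclass
#' correlation from the two-way random-effects mean-squares decomposition,
#' for paired measurements (k = 2 raters, here two chart-generation
#' methods) on n targets (chart cells):
#' \deqn{\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E +
#'   \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} the row (target), column (rater)
#' and residual mean squares.
#'
#' @param a,b paired measurements (equal length >= 2).
#' @return the ICC, in \[-1, 1\].  If every value is identical across both
#'   raters and targets the ICC is defined as 1 when `a == b` elementwise
#'   and is an error otherwise (agreement is undefined without variance).
#' @examples
#' icc(c(1, 2, 3, 4), c(2, 3, 4, 5))  # 10/13
#' @export
icc <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop_validation("icc needs two equal-length vectors with >= 2 pairs")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop_validation("icc inputs must be finite")
  x <- cbind(a, b)
  n <- nrow(x)
  k <- 2
  grand <- mean(x)
  rm_ <- rowMeans(x)
  cm_ <- colMeans(x)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm_ - grand)^2) / (k - 1)
  res <- x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + grand
  mse <- sum(res^2) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= 0) {
    if (all(a == b)) return(1)
    stop_validation("ICC undefined: no variance across targets or raters")
  }
  (msr - mse) / denom
}

#' Compare two chart grids cell-wise
#'
#' Matches cells of two grids (same cholesterol measure) on sex, smoking,
#' age, SBP and cholesterol level, optionally restricted to an age range,
#' and reports: counts of cells where A is higher / lower / equal to B on
#' the rounded display values (the chart reader's view; "<1" counts as 0),
#' the mean and SD of the absolute cell differences in raw percentage
#' points, and the absolute-agreement ICC of the paired raw values.
#'
#' Legacy charts with a single 40-49 age band can be compared to a modern
#' grid via `age_map`, a data.frame with columns `age_a`, `age_b` listing
#' the (possibly one-to-many) entry-age pairings; e.g. legacy age 45
#' matched to both 40 and 45.
#'
#' @param grid_a,grid_b [chart_grid()] objects sharing a cholesterol
#'   measure.
#' @param age_range optional `c(min, max)` restriction on entry age (both
#'   grids, applied before matching).
#' @param icc_on compute the ICC (TRUE by default).
#' @param on "display" (default) or "raw": the scale of the
#'   higher/lower/equal counts.
#' @param age_map optional explicit age pairing (see Details).
#' @return an object of class `comparison_stats`.
#' @export
compare_charts <- function(grid_a, grid_b, age_range = NULL, icc_on = TRUE,
                           on = c("display", "raw"), age_map = NULL) {
  stopifnot(inherits(grid_a, "chart_grid"), inherits(grid_b, "chart_grid"))
  on <- match.arg(on)
  if (grid_a$chol_measure != grid_b$chol_measure)
    stop_validation("grids use different cholesterol measures (",
                    grid_a$chol_measure, " vs ", grid_b$chol_measure, ")")
  ca <- grid_a$cells
  cb <- grid_b$cells
  if (!is.null(age_range)) {
    ca <- ca[ca$age >= age_range[1] & ca$age <= age_range[2], ]
    cb <- cb[cb$age >= age_range[1] & cb$age <= age_range[2], ]
  }
  if (is.null(age_map)) {
    common <- intersect(unique(ca$age), unique(cb$age))
    if (!length(common))
      stop_validation("no common entry ages to compare; supply age_map")
    age_map <- data.frame(age_a = common, age_b = common)
  }
  pairs <- NULL
  for (i in seq_len(nrow(age_map))) {
    sa <- ca[ca$age == age_map$age_a[i], ]
    sb <- cb[cb$age == age_map$age_b[i], ]
    m <- merge(sa, sb, by = c("sex", "smoker", "sbp", "chol"),
               suffixes = c("_a", "_b"))
    if (nrow(m) != nrow(sa) || nrow(m) != nrow(sb))
      stop_validation("axes do not match for ages ", age_map$age_a[i],
                      " vs ", age_map$age_b[i],
                      " (", nrow(sa), " vs ", nrow(sb), " cells, ",
                      nrow(m), " matched)")
    pairs <- rbind(pairs, m)
  }
  disp_num <- function(r) ifelse(100 * r < 0.5, 0, round_half_away(100 * r))
  if (on == "display") {
    va <- disp_num(pairs$risk_a)
    vb <- disp_num(pairs$risk_b)
  } else {
    va <- pairs$risk_a
    vb <- pairs$risk_b
  }
  adiff <- abs(100 * (pairs$risk_a - pairs$risk_b))
  structure(list(
    n_cells_compared = nrow(pairs),
    n_higher = sum(va > vb),
    n_lower = sum(va < vb),
    n_equal = sum(va == vb),
    mean_abs_diff = mean(adiff),
    sd_abs_diff = stats::sd(adiff),
    icc = if (icc_on) icc(pairs$risk_a, pairs$risk_b) else NA_real_,
    age_range = if (is.null(age_range))
      range(age_map$age_a) else age_range,
    compared_on = on
  ), class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf("Chart comparison over %d cells (ages %d-%d, %s values)\n",
              x$n_cells_compared, x$age_range[1], x$age_range[2],
              x$compared_on))
  cat(sprintf("  A higher: %d   A lower: %d   equal: %d\n",
              x$n_higher, x$n_lower, x$n_equal))
  cat(sprintf("  |diff|: mean %.3f pp, SD %.3f pp\n",
              x$mean_abs_diff, x$sd_abs_diff))
  if (!is.na(x$icc)) cat(sprintf("  ICC(A,1) = %.4f\n", x$icc))
  invisible(x)
}
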