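#' 5-year age-band helpers
#'
#' The recalibration works on a fixed 5-year age-band grid: the band covering
#' age \eqn{a} starts at \eqn{5 \lfloor a/5 \rfloor}.  Bands are identified by
#' their start age (40, 45, ..., 70) and always have width 5.
#'
#' @param age age in years (may be fractional).
#' @return `band_start()` returns the start age of the band containing `age`.
#' @examples
#' band_start(43.2)  # 40
#' band_start(45)    # 45
#' @export
band_start <- function(age) {
  5 * floor(age / 5)
}

#' @rdname band_start
#' @return `band_label()` returns a human-readable "40-44" style label.
#' @export
band_label <- function(age) {
  s <- band_start(age)
  sprintf("%d-%d", s, s + 4L)
}

#' Round an age to the nearest chart entry age
#'
#' Chart reading rounds a person's age to the nearest age shown on the chart
#' (entry ages 40, 45, ..., 65 by default); ties round up, and ages outside
#' the chart range clamp to the nearest end.
#'
#' @param age age in years.
#' @param chart_ages entry ages shown on the chart.
#' @return the nearest chart age.
#' @export
nearest_chart_age <- function(age, chart_ages = seq(40, 65, by = 5)) {
  chart_ages <- sort(chart_ages)
  vapply(age, function(a) {
    d <- abs(chart_ages - a)
    # ties round toward the older age
    chart_ages[max(which(d == min(d)))]
  }, numeric(1))
}

#' Partition a 10-year horizon by the 5-year band grid
#'
#' Splits the interval \eqn{[age, age+10)} at the 5-year band boundaries.
#' Entry ages that are multiples of 5 (chart ages) give exactly two 5-year
#' pieces; intermediate ages give three pieces whose exposures sum to 10.
#'
#' @param age entry age in years, in \[40, 65\].
#' @param table optional [mortality_table()]; when supplied together with
#'   `sex` the partition is checked against the table's band coverage and a
#'   validation error names any missing band.
#' @param sex "female" or "male"; required when `table` is given.
#' @return a data.frame with columns `band_start` and `exposure` (years).
#' @examples
#' horizon_bands(40)  # 40 (5 y), 45 (5 y)
#' horizon_bands(43)  # 40 (2 y), 45 (5 y), 50 (3 y)
#' @export
horizon_bands <- function(age, table = NULL, sex = NULL) {
  check_number(age, "age", lo = 40, hi = 65)
  end <- age + 10
  starts <- seq(band_start(age), band_start(end - 1e-9), by = 5)
  exposure <- pmin(starts + 5, end) - pmax(starts, age)
  keep <- exposure > 0
  out <- data.frame(band_start = starts[keep], exposure = exposure[keep])
  stopifnot(abs(sum(out$exposure) - 10) < 1e-9)
  if (!is.null(table)) {
    check_sex(sex)
    have <- table$entries$age_band_start[table$entries$sex == sex]
    miss <- setdiff(out$band_start, have)
    if (length(miss))
      stop_validation("mortality table does not cover band ",
                      band_label(miss[1]), " for sex '", sex, "'")
  }
  out
}
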