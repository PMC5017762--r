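#' Chart axes
#'
#' The grid of entry ages, systolic blood pressures and cholesterol levels
#' a risk chart tabulates, always crossed with both sexes and both smoking
#' states.  Defaults give the conventional 480-cell layout: 6 entry ages x
#' 4 SBP levels x 5 cholesterol levels x 2 sexes x 2 smoking states.
#'
#' @param ages entry ages (multiples of 5 within \[40, 65\]).
#' @param sbp_levels SBP axis values, mmHg.
#' @param chol_levels cholesterol axis values; defaults depend on
#'   `chol_measure` (4-8 mmol/L for TC, 3-7 for the TC/HDL-C ratio).
#' @param chol_measure "TC" or "RATIO".
#' @return an object of class `chart_axes`.
#' @export
chart_axes <- function(ages = seq(40, 65, by = 5),
                       sbp_levels = c(120, 140, 160, 180),
                       chol_levels = NULL,
                       chol_measure = c("TC", "RATIO")) {
  chol_measure <- match.arg(chol_measure)
  if (is.null(chol_levels))
    chol_levels <- if (chol_measure == "TC") 4:8 else 3:7
  for (nm in c("ages", "sbp_levels", "chol_levels")) {
    v <- get(nm)
    if (!length(v) || any(!is.finite(v)) || is.unsorted(v, strictly = TRUE))
      stop_validation(nm, " must be non-empty, finite and strictly increasing")
  }
  if (any(ages < 40 | ages > 65 | ages %% 5 != 0))
    stop_validation("ages must be multiples of 5 within [40, 65]")
  structure(list(ages = ages, sbp_levels = sbp_levels,
                 chol_levels = chol_levels, chol_measure = chol_measure,
                 sexes = SEXES, smoking = c(FALSE, TRUE)),
            class = "chart_axes")
}

n_cells <- function(axes) {
  length(axes$sexes) * length(axes$smoking) * length(axes$ages) *
    length(axes$sbp_levels) * length(axes$chol_levels)
}

#' Tabulate the risk function into a chart grid
#'
#' Pure tabulation: one cell per axis combination, each cell exactly the
#' [ten_year_risk()] value for the corresponding profile — no smoothing or
#' rounding is applied to the stored raw risks.
#'
#' @param axes a [chart_axes()].
#' @param table a [mortality_table()].
#' @param means a [risk_factor_means()].
#' @param coefs a [coefficients_set()].
#' @param method "constant" or "interpolated".
#' @param strict_hazard passed to the risk engine.
#' @return an object of class `chart_grid`: the axes, method and a cell
#'   data.frame (`sex`, `smoker`, `age`, `sbp`, `chol`, `risk`).
#' @examples
#' grid <- generate_chart(chart_axes(), synth_mortality(sim_params(seed = 1)),
#'                        default_means(),
#'                        coefficients_set(0.015, beta_tc = 0.25,
#'                                         beta_smoke = 0.7))
#' nrow(grid$cells)  # 480
#' @export
generate_chart <- function(axes, table, means, coefs,
                           method = c("constant", "interpolated"),
                           strict_hazard = FALSE) {
  stopifnot(inherits(axes, "chart_axes"))
  method <- match.arg(method)
  cells <- expand.grid(chol = axes$chol_levels, sbp = axes$sbp_levels,
                       age = axes$ages, smoker = axes$smoking,
                       sex = axes$sexes, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[, c("sex", "smoker", "age", "sbp", "chol")]
  cells$risk <- vapply(seq_len(nrow(cells)), function(i) {
    p <- risk_profile(cells$sex[i], cells$age[i], cells$sbp[i],
                      cells$chol[i], axes$chol_measure, cells$smoker[i])
    tryCatch(ten_year_risk(p, table, means, coefs, method, strict_hazard),
             cvdrecal_validation_error = function(e) stop_validation(
               "cell (", cells$sex[i], ", smoker=", cells$smoker[i], ", age ",
               cells$age[i], ", sbp ", cells$sbp[i], ", chol ", cells$chol[i],
               "): ", conditionMessage(e)))
  }, numeric(1))
  structure(list(chol_measure = axes$chol_measure, axes = axes,
                 method = method, cells = cells),
            class = "chart_grid")
}

#' @export
print.chart_grid <- function(x, ...) {
  cat(sprintf("Risk chart grid: %d cells, cholesterol measure %s, %s rates\n",
              nrow(x$cells), x$chol_measure, x$method))
  cat(sprintf("  raw risk range %.4f - %.4f\n",
              min(x$cells$risk), max(x$cells$risk)))
  invisible(x)
}

# Half-away-from-zero integer rounding (chart convention; R's round() is
# half-to-even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Chart display value and colour category of a raw risk
#'
#' Charts print each cell as a whole-percent risk, rounded half away from
#' zero, with risks below 0.5% shown as "<1"; the colour legend bins the
#' displayed percentages as <1, 1, 2, 3-4, 5-9, 10-14 and >=15.
#'
#' @param risk raw 10-year risk in \[0, 1\] (vectorised).
#' @return `risk_display()`: character vector of cell labels.
#' @export
risk_display <- function(risk) {
  pct <- 100 * risk
  ifelse(pct < 0.5, "<1", as.character(round_half_away(pct)))
}

#' @rdname risk_display
#' @return `risk_category()`: the colour-legend bin of each cell.
#' @export
risk_category <- function(risk) {
  pct <- 100 * risk
  d <- ifelse(pct < 0.5, 0, round_half_away(pct))
  cut(d, breaks = c(-Inf, 0, 1, 2, 4, 9, 14, Inf),
      labels = c("<1", "1", "2", "3-4", "5-9", "10-14", ">=15"))
}

# Long-format data.frame view of a grid (the chart CSV schema).
chart_long <- function(grid) {
  stopifnot(inherits(grid, "chart_grid"))
  data.frame(chol_measure = grid$chol_measure,
             sex = grid$cells$sex,
             smoker = as.integer(grid$cells$smoker),
             age = grid$cells$age,
             sbp = grid$cells$sbp,
             chol = grid$cells$chol,
             risk_raw = grid$cells$risk,
             risk_display = risk_display(grid$cells$risk),
             category = as.character(risk_category(grid$cells$risk)))
}

#' Render a chart grid
#'
#' Emits the grid as a long-format CSV (one row per cell with raw risk,
#' display value and colour category), as a plain-text matrix layout in the
#' conventional chart arrangement (per sex x smoking panel: SBP rows by
#' cholesterol columns, age blocks), or as a PNG of that matrix.
#'
#' @param grid a [chart_grid()] from [generate_chart()].
#' @param format "csv", "text" or "png".
#' @param path output file; for "text", NULL prints to the console.
#' @return the path (csv/png) or the text lines, invisibly.
#' @export
render_chart <- function(grid, format = c("csv", "text", "png"),
                         path = NULL) {
  stopifnot(inherits(grid, "chart_grid"))
  format <- match.arg(format)
  if (format == "csv") {
    if (is.null(path)) stop_io("render_chart(format='csv') needs a path")
    utils::write.csv(chart_long(grid), path, row.names = FALSE,
                     quote = FALSE)
    return(invisible(path))
  }
  lines <- character()
  cl <- grid$cells
  for (sx in grid$axes$sexes) for (sm in grid$axes$smoking) {
    lines <- c(lines, sprintf("== %s, %s ==", sx,
                              if (sm) "smoker" else "non-smoker"))
    for (age in rev(grid$axes$ages)) {
      lines <- c(lines, sprintf("age %d  (%s %s)", age, grid$chol_measure,
                                paste(grid$axes$chol_levels, collapse = " ")))
      for (sbp in rev(grid$axes$sbp_levels)) {
        sel <- cl$sex == sx & cl$smoker == sm & cl$age == age & cl$sbp == sbp
        row <- cl[sel, ]
        row <- row[order(row$chol), ]
        lines <- c(lines, sprintf("  sbp %3d : %s", sbp,
                                  paste(formatC(risk_display(row$risk),
                                                width = 3), collapse = " ")))
      }
    }
    lines <- c(lines, "")
  }
  if (format == "text") {
    if (is.null(path)) cat(lines, sep = "\n") else writeLines(lines, path)
    return(invisible(lines))
  }
  # png: the text layout typeset onto a canvas
  if (is.null(path)) stop_io("render_chart(format='png') needs a path")
  grDevices::png(path, width = 900,
                 height = 20 * length(lines) + 40, res = 96)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::text(0.02, seq(0.98, 0.02, length.out = length(lines)),
                 lines, adj = 0, family = "mono", cex = 0.8)
  invisible(path)
}
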