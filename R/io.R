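# CSV dialect: comma-separated, UTF-8, dot decimal, mandatory header;
# sexes "female"/"male"; booleans 0/1; empty field = missing.

read_csv_checked <- function(path, required, label) {
  if (!file.exists(path)) stop_io(label, " file not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                 na.strings = c("", "NA")),
                 error = function(e) stop_io("cannot parse ", label, " '",
                                             path, "': ", conditionMessage(e)))
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_validation(label, " '", path, "' missing column(s): ",
                    paste(miss, collapse = ", "))
  df
}

check_numeric_col <- function(df, cols, path, allow_na = FALSE) {
  for (col in cols) {
    v <- df[[col]]
    if (is.character(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop_validation("'", path, "' line ", bad[1] + 1L,
                        ": non-numeric value '", v[bad[1]],
                        "' in column ", col)
      v <- vn
    }
    if (!allow_na && anyNA(v))
      stop_validation("'", path, "' line ", which(is.na(v))[1] + 1L,
                      ": missing value in column ", col)
    df[[col]] <- v
  }
  df
}

#' Read and write the domain CSV / JSON schemas
#'
#' Readers return fully validated domain objects (all type invariants are
#' enforced at load; errors carry the file and line).  Writers emit the
#' same schema the readers consume, so every write/read pair round-trips.
#'
#' Schemas: mortality CSV `sex, age_band_start, deaths_cvd, deaths_noncvd,
#' population`; means CSV `sex, age_band_start, mean_sbp, mean_tc,
#' mean_ratio, smoking_prev`; coefficients JSON keys `beta_sbp`, `beta_tc`,
#' `beta_ratio`, `beta_smoke`, optional per-sex objects under `sex`, and
#' `provenance`; cohort CSV `id, age, sex, sbp, tc, hdl, smoker, weight,
#' prior_chd, prior_stroke, prior_hf` with empty fields meaning missing.
#'
#' @param path file to read or write.
#' @return `read_mortality()` a [mortality_table()]; `read_means()` a
#'   [risk_factor_means()]; `read_coefficients()` a [coefficients_set()];
#'   `read_cohort()` a cohort data.frame.
#' @name io
NULL

#' @rdname io
#' @export
read_mortality <- function(path) {
  df <- read_csv_checked(path, c("sex", "age_band_start", "deaths_cvd",
                                 "deaths_noncvd", "population"),
                         "mortality table")
  df <- check_numeric_col(df, c("age_band_start", "deaths_cvd",
                                "deaths_noncvd", "population"), path)
  mortality_table(df)
}

#' @rdname io
#' @param table,means,coefs,records the object to write.
#' @export
write_mortality <- function(table, path) {
  stopifnot(inherits(table, "mortality_table"))
  utils::write.csv(table$entries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_means <- function(path) {
  df <- read_csv_checked(path, c("sex", "age_band_start", "mean_sbp",
                                 "mean_tc", "mean_ratio", "smoking_prev"),
                         "risk-factor means")
  df <- check_numeric_col(df, c("age_band_start", "mean_sbp", "mean_tc",
                                "mean_ratio", "smoking_prev"), path)
  risk_factor_means(df)
}

#' @rdname io
#' @export
write_means <- function(means, path) {
  stopifnot(inherits(means, "risk_factor_means"))
  utils::write.csv(means$entries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) stop_io("coefficients file not found: ", path)
  j <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                error = function(e) stop_io("cannot parse coefficients '",
                                            path, "': ",
                                            conditionMessage(e)))
  if (is.null(j$beta_sbp))
    stop_validation("coefficients '", path, "' missing beta_sbp")
  coefficients_set(beta_sbp = j$beta_sbp, beta_tc = j$beta_tc,
                   beta_ratio = j$beta_ratio,
                   beta_smoke = if (is.null(j$beta_smoke)) 0 else j$beta_smoke,
                   sex = j$sex,
                   provenance = if (is.null(j$provenance)) "unspecified"
                   else j$provenance)
}

#' @rdname io
#' @export
write_coefficients <- function(coefs, path) {
  stopifnot(inherits(coefs, "coefficients_set"))
  jsonlite::write_json(Filter(Negate(is.null), unclass(coefs)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname io
#' @export
read_cohort <- function(path) {
  df <- read_csv_checked(path, COHORT_REQUIRED, "cohort") # id optional-ish
  if (!"id" %in% names(df)) df$id <- sprintf("row%d", seq_len(nrow(df)))
  df <- check_numeric_col(df, c("age", "sbp", "tc", "hdl", "weight"),
                          path, allow_na = TRUE)
  for (col in c("smoker", "prior_chd", "prior_stroke", "prior_hf")) {
    v <- df[[col]]
    if (is.character(v)) suppressWarnings(v <- as.numeric(v))
    bad <- which(!is.na(v) & !v %in% c(0, 1))
    if (length(bad))
      stop_validation("'", path, "' line ", bad[1] + 1L, ": column ", col,
                      " must be 0/1, got '", df[[col]][bad[1]], "'")
    df[[col]] <- as.logical(v)
  }
  bad_sex <- which(!is.na(df$sex) & !df$sex %in% SEXES)
  if (length(bad_sex))
    stop_validation("'", path, "' line ", bad_sex[1] + 1L,
                    ": sex must be female/male, got '",
                    df$sex[bad_sex[1]], "'")
  df
}

#' @rdname io
#' @export
write_cohort <- function(records, path) {
  out <- as.data.frame(records)
  for (col in c("smoker", "prior_chd", "prior_stroke", "prior_hf"))
    out[[col]] <- as.integer(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname io
#' @param grid a `chart_grid` to write, or a chart CSV to read back.
#' @export
read_chart_csv <- function(path) {
  df <- read_csv_checked(path, c("chol_measure", "sex", "smoker", "age",
                                 "sbp", "chol", "risk_raw"), "chart")
  df <- check_numeric_col(df, c("smoker", "age", "sbp", "chol", "risk_raw"),
                          path)
  measure <- unique(df$chol_measure)
  if (length(measure) != 1L)
    stop_validation("'", path, "' mixes cholesterol measures")
  axes <- chart_axes(ages = sort(unique(df$age)),
                     sbp_levels = sort(unique(df$sbp)),
                     chol_levels = sort(unique(df$chol)),
                     chol_measure = measure)
  cells <- data.frame(sex = df$sex, smoker = df$smoker == 1, age = df$age,
                      sbp = df$sbp, chol = df$chol, risk = df$risk_raw)
  if (nrow(cells) != n_cells(axes))
    stop_validation("'", path, "' has ", nrow(cells),
                    " cells but its axes imply ", n_cells(axes))
  structure(list(chol_measure = measure, axes = axes, method = "unknown",
                 cells = cells), class = "chart_grid")
}
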