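# Internal date helpers shared across modules.

# ISO-8601 week label ("1975-W11") for a date; uses the ISO year (%G).
iso_week_str <- function(date) {
  format(date, "%G-W%V")
}

# Monday of an ISO week given as "YYYY-Www". January 4th always falls in ISO
# week 1, which anchors the arithmetic.
iso_week_monday <- function(week_str) {
  ok <- grepl("^\\d{4}-W\\d{2}$", week_str)
  if (any(!ok & !is.na(week_str))) {
    abort(paste0("malformed ISO week value(s): ",
                 paste(utils::head(week_str[!ok], 3), collapse = ", ")),
          class = "respcohort_argument_error")
  }
  yr <- as.integer(substr(week_str, 1, 4))
  wk <- as.integer(substr(week_str, 7, 8))
  jan4 <- as.Date(paste0(yr, "-01-04"))
  monday_w1 <- jan4 - (as.integer(format(jan4, "%u")) - 1L)
  monday_w1 + 7L * (wk - 1L)
}

# Age in completed years at `at` for someone born on `birth`.
age_completed_years <- function(birth, at) {
  yrs <- as.integer(format(at, "%Y")) - as.integer(format(birth, "%Y"))
  before_birthday <- format(at, "%m%d") < format(birth, "%m%d")
  yrs - as.integer(before_birthday)
}

# Uniformly sampled dates in [from, to].
runif_dates <- function(n, from, to) {
  from <- as.Date(from)
  to <- as.Date(to)
  from + floor(runif(n, 0, as.numeric(to - from) + 1))
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "respcohort_schema_error")
  }
  invisible(df)
}

as_date_scalar <- function(x, what = "date") {
  if (is.null(x) || (length(x) == 1 && is.na(x))) return(as.Date(NA))
  out <- as.Date(x)
  if (length(out) != 1 || is.na(out)) {
    abort(paste0(what, " must be a single valid date"),
          class = "respcohort_argument_error")
  }
  out
}
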