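#' Tidy a cohort into its member table
#' @param x A `cohort`.
#' @param ... Unused.
#' @return Tibble of cohort members.
#' @export
tidy.cohort <- function(x, ...) {
  as_tibble(x$members)
}

#' One-row summary of a cohort build
#' @param x A `cohort`.
#' @param ... Unused.
#' @return One-row tibble: input and included counts plus one column per
#'   exclusion criterion.
#' @export
glance.cohort <- function(x, ...) {
  wide <- setNames(as.list(x$exclusions$n), x$exclusions$criterion)
  bind_cols(tibble(disease = x$spec$disease, dialect = x$profile$name,
                   n_input = x$n_input, n_included = nrow(x$members)),
            as_tibble(wide))
}

#' Tidy a cohort description into one long table
#' @param x A `cohort_description`.
#' @param ... Unused.
#' @return Tibble (`variable`, `level`, `n`, `pct`).
#' @export
tidy.cohort_description <- function(x, ...) {
  purrr::imap_dfr(x$tables, function(tb, nm) {
    tb |> mutate(variable = nm, .before = 1)
  })
}

#' One-row summary of a cohort description
#' @param x A `cohort_description`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.cohort_description <- function(x, ...) {
  tibble(disease = x$disease, dialect = x$dialect, n = x$n,
         index_date = x$index_date, window_start = x$window_start,
         lookback_years = x$lookback_years)
}

#' @export
tidy.ehr_bundle <- function(x, ...) {
  purrr::map_dfr(bundle_tables(), function(tb) {
    tibble(table = tb, n_rows = nrow(x[[tb]]))
  })
}

#' @export
glance.ehr_bundle <- function(x, ...) {
  tibble(dialect = x$profile$name, n_patients = nrow(x$patients),
         n_events = nrow(x$clinical_events),
         n_prescriptions = nrow(x$prescriptions))
}
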