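#' Source-dialect profiles
#'
#' A dialect profile captures the structural differences between the three
#' primary-care source flavours the toolkit harmonises:
#'
#' * `cprd_like` — each GP registration gets its own patient identifier (a
#'   mover appears under several IDs), only year of birth is held, clinical
#'   events are medcode-coded, prescriptions are GP-issued and product-coded
#'   (dm+d-style), events outside the registration period are not used, and
#'   deprivation is English IMD 2019.
#' * `sail_like` — one identifier per person, week of birth, Read V2 events
#'   and prescriptions, GP-issued prescriptions all-time, WIMD 2019.
#' * `dataloch_like` — one identifier per person, month and year of birth,
#'   Read V2 events, BNF-coded *dispensed* prescriptions available from 2009
#'   onwards, SIMD 2020v2.
#'
#' The administrative dates default to the data snapshots the toolkit
#' emulates: extraction on 2022-02-01 / 2022-03-07 / 2023-05-01 for the
#' CPRD-, SAIL- and DataLoch-like dialects, a national mortality-register
#' coverage end of 2021-03-31 and a last practice collection date of
#' 2022-01-15 for the CPRD-like dialect.
#'
#' @param name One of `"cprd_like"`, `"sail_like"`, `"dataloch_like"`.
#' @param extraction_date Optional override for the data extraction date.
#' @return A `dialect_profile` list.
#' @examples
#' dialect_profile("sail_like")$birth_granularity
#' @export
dialect_profile <- function(name = c("cprd_like", "sail_like", "dataloch_like"),
                            extraction_date = NULL) {
  name <- match.arg(name)
  base <- switch(name,
    cprd_like = list(
      name = "cprd_like",
      birth_granularity = "year",
      patient_id_scope = "per_registration",
      prescription_semantics = "issued",
      prescription_start_year = NA_integer_,
      drug_coding = "product_code",
      drug_system = "dmd",
      event_system = "medcode",
      events_restricted_to_registration = TRUE,
      deprivation_scheme = "imd_england_2019",
      region_policy = "england_regions",
      death_source = "primary_with_internal_fallback",
      extraction_date = as.Date("2022-02-01"),
      primary_death_coverage_end = as.Date("2021-03-31"),
      last_collection_date = as.Date("2022-01-15")),
    sail_like = list(
      name = "sail_like",
      birth_granularity = "week",
      patient_id_scope = "per_person",
      prescription_semantics = "issued",
      prescription_start_year = NA_integer_,
      drug_coding = "read",
      drug_system = "read_v2",
      event_system = "read_v2",
      events_restricted_to_registration = FALSE,
      deprivation_scheme = "wimd_2019",
      region_policy = "wales",
      death_source = "primary_register",
      extraction_date = as.Date("2022-03-07"),
      primary_death_coverage_end = as.Date(NA),
      last_collection_date = as.Date(NA)),
    dataloch_like = list(
      name = "dataloch_like",
      birth_granularity = "month",
      patient_id_scope = "per_person",
      prescription_semantics = "dispensed",
      prescription_start_year = 2009L,
      drug_coding = "bnf",
      drug_system = "bnf",
      event_system = "read_v2",
      events_restricted_to_registration = FALSE,
      deprivation_scheme = "simd_2020v2",
      region_policy = "lothian",
      death_source = "internal_derived",
      extraction_date = as.Date("2023-05-01"),
      primary_death_coverage_end = as.Date(NA),
      last_collection_date = as.Date(NA)))
  if (!is.null(extraction_date)) {
    base$extraction_date <- as_date_scalar(extraction_date, "extraction_date")
  }
  structure(base, class = "dialect_profile")
}

#' @export
print.dialect_profile <- function(x, ...) {
  cat("<dialect_profile '", x$name, "'>\n", sep = "")
  cat("  birth granularity:  ", x$birth_granularity, "\n", sep = "")
  cat("  patient id scope:   ", x$patient_id_scope, "\n", sep = "")
  cat("  events:             ", x$event_system,
      if (x$events_restricted_to_registration) " (registration-restricted)" else "",
      "\n", sep = "")
  cat("  prescriptions:      ", x$prescription_semantics, ", ", x$drug_system,
      if (!is.na(x$prescription_start_year))
        paste0(", from ", x$prescription_start_year) else "",
      "\n", sep = "")
  cat("  deprivation scheme: ", x$deprivation_scheme, "\n", sep = "")
  invisible(x)
}

as_dialect_profile <- function(profile) {
  if (inherits(profile, "dialect_profile")) return(profile)
  if (is.character(profile) && length(profile) == 1) {
    return(dialect_profile(profile))
  }
  abort("expected a dialect_profile or a dialect name",
        class = "respcohort_argument_error")
}

#' English ITL1 regions used by the CPRD-like dialect
#' @return Character vector of the nine English region names.
#' @export
english_regions <- function() {
  c("North East", "North West", "Yorkshire and The Humber", "East Midlands",
    "West Midlands", "East of England", "London", "South East", "South West")
}
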