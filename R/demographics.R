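#' Impute a date of birth from dialect-granular birth information
#'
#' Each source dialect records birth at a different granularity and the
#' harmonised rule is deterministic: year-only births are set to 1st July of
#' that year; week-of-birth becomes the Monday of that (ISO) week; month and
#' year of birth becomes the 1st of that month; exact dates pass through.
#'
#' Expected input formats by granularity: `"1980"` (year), `"1975-W11"`
#' (ISO week), `"1990-05"` (month), `"1990-05-21"` (exact).
#'
#' @param birth Character vector of birth values in the profile's
#'   granularity.
#' @param profile A [dialect_profile()], dialect name, or one of
#'   `"year"`, `"week"`, `"month"`, `"exact"`.
#' @return Vector of imputed `Date`s.
#' @examples
#' impute_birth_date("1980", "year")         # 1980-07-01
#' impute_birth_date("1975-W11", "week")     # Monday 1975-03-10
#' impute_birth_date("1990-05", "month")     # 1990-05-01
#' @export
impute_birth_date <- function(birth, profile) {
  granularity <- if (is.character(profile) &&
                     profile %in% c("year", "week", "month", "exact")) {
    profile
  } else {
    as_dialect_profile(profile)$birth_granularity
  }
  birth <- as.character(birth)
  pattern <- switch(granularity,
                    year = "^\\d{4}$",
                    week = "^\\d{4}-W\\d{2}$",
                    month = "^\\d{4}-\\d{2}$",
                    exact = "^\\d{4}-\\d{2}-\\d{2}$")
  bad <- !is.na(birth) & !grepl(pattern, birth)
  if (any(bad)) {
    abort(paste0("birth value(s) do not match granularity '", granularity,
                 "': ", paste(utils::head(birth[bad], 3), collapse = ", ")),
          class = "respcohort_argument_error")
  }
  switch(granularity,
         year = as.Date(ifelse(is.na(birth), NA, paste0(birth, "-07-01"))),
         week = iso_week_monday(birth),
         month = as.Date(ifelse(is.na(birth), NA, paste0(birth, "-01"))),
         exact = as.Date(birth))
}

#' Resolve date of death per dialect precedence rules
#'
#' Death dates come from different sources per dialect. For the CPRD-like
#' dialect the national mortality register is primary: its death date is
#' used; if a register record exists with the death date missing, the
#' register's registration-of-death date is used instead; and because
#' register coverage ends at a fixed date, deaths after that point fall back
#' to the internally recorded GP death date. The SAIL-like dialect reads the
#' mortality register directly; the DataLoch-like dialect uses its
#' internally derived death date. A patient absent from every source is
#' treated as alive.
#'
#' @param deaths Tibble with columns `patient_id`, `primary_death_date`,
#'   `primary_registration_date`, `internal_death_date` (any may be `NA`; a
#'   primary register record exists when either primary column is non-`NA`).
#' @param profile A [dialect_profile()] or dialect name.
#' @param birth_dates Optional tibble (`patient_id`, `birth_date`); when
#'   given, deaths before the (imputed) birth date are flagged but retained.
#' @return Tibble (`patient_id`, `death_date`, `death_before_birth`).
#' @export
resolve_death_date <- function(deaths, profile, birth_dates = NULL) {
  profile <- as_dialect_profile(profile)
  assert_columns(deaths, c("patient_id", "primary_death_date",
                           "primary_registration_date", "internal_death_date"),
                 what = "deaths table")
  deaths <- as_tibble(deaths) |>
    mutate(across(c("primary_death_date", "primary_registration_date",
                    "internal_death_date"), as.Date))
  resolved <- switch(profile$death_source,
    primary_with_internal_fallback = {
      cov_end <- profile$primary_death_coverage_end
      deaths |>
        mutate(death_date = coalesce(.data$primary_death_date,
                                     .data$primary_registration_date),
               death_date = if_else(is.na(.data$death_date) &
                                      !is.na(.data$internal_death_date) &
                                      .data$internal_death_date > cov_end,
                                    .data$internal_death_date,
                                    .data$death_date))
    },
    primary_register = deaths |>
      mutate(death_date = coalesce(.data$primary_death_date,
                                   .data$primary_registration_date)),
    internal_derived = deaths |>
      mutate(death_date = .data$internal_death_date))
  out <- resolved |> select("patient_id", "death_date")
  if (!is.null(birth_dates)) {
    out <- out |>
      left_join(birth_dates, by = "patient_id") |>
      mutate(death_before_birth = !is.na(.data$death_date) &
               !is.na(.data$birth_date) &
               .data$death_date < .data$birth_date) |>
      select("patient_id", "death_date", "death_before_birth")
    if (any(out$death_before_birth)) {
      warn(paste0(sum(out$death_before_birth),
                  " patient(s) have a death date before the imputed birth ",
                  "date; dates retained and flagged"))
    }
  } else {
    out$death_before_birth <- FALSE
  }
  out
}

#' Harmonise a deprivation quintile to a descriptive label
#'
#' The English IMD 2019 counts quintile 1 as least deprived, while the Welsh
#' WIMD 2019 and Scottish SIMD 2020v2 count quintile 1 as most deprived.
#' Because the scales run in opposite directions, harmonised results always
#' use descriptive labels rather than numbers. Middle quintiles map
#' order-preservingly, so quintile `q` under one convention carries the same
#' label as `6 - q` under the other.
#'
#' @param quintile Integer vector in 1..5.
#' @param scheme `"imd_england_2019"`, `"wimd_2019"` or `"simd_2020v2"`
#'   (recycled against `quintile`).
#' @return Factor with levels `most deprived`, `2`, `3`, `4`,
#'   `least deprived`.
#' @examples
#' harmonise_deprivation(1, "imd_england_2019")  # least deprived
#' harmonise_deprivation(1, "wimd_2019")         # most deprived
#' @export
harmonise_deprivation <- function(quintile, scheme) {
  labels <- deprivation_labels()
  quintile <- as.integer(quintile)
  if (any(!is.na(quintile) & (quintile < 1 | quintile > 5))) {
    abort("deprivation quintile must be between 1 and 5",
          class = "respcohort_argument_error")
  }
  scheme <- as.character(scheme)
  bad <- setdiff(unique(scheme[!is.na(scheme)]),
                 c("imd_england_2019", "wimd_2019", "simd_2020v2"))
  if (length(bad) > 0) {
    abort(paste0("unknown deprivation scheme(s): ", paste(bad, collapse = ", ")),
          class = "respcohort_argument_error")
  }
  # Position 1 of `labels` is "most deprived". IMD quintile 5 is most
  # deprived; WIMD/SIMD quintile 1 is most deprived.
  len <- max(length(quintile), length(scheme))
  quintile <- rep_len(quintile, len)
  is_imd <- rep_len(scheme == "imd_england_2019", len)
  idx <- ifelse(is_imd, 6L - quintile, quintile)
  factor(labels[idx], levels = labels)
}

#' Ordered harmonised deprivation labels (most to least deprived)
#' @return Character vector of the five labels.
#' @export
deprivation_labels <- function() {
  c("most deprived", "2", "3", "4", "least deprived")
}

# Modal value with most-recent-record tie-break (then alphabetical for
# determinism). `values` and `dates` are parallel vectors.
resolve_modal <- function(values, dates) {
  keep <- !is.na(values)
  values <- values[keep]
  dates <- dates[keep]
  if (length(values) == 0) return(NA_character_)
  counts <- table(values)
  tied <- names(counts)[counts == max(counts)]
  if (length(tied) == 1) return(tied)
  in_tie <- values %in% tied
  latest <- max(dates[in_tie])
  cands <- sort(unique(values[in_tie & dates == latest]))
  cands[length(cands)]
}

#' Derive ethnicity from GP and hospital coded events
#'
#' GP-recorded ethnicity is preferred; hospital records are used only for
#' patients with no GP ethnicity code, to reduce missingness. Within the
#' chosen source, conflicts are resolved per classification scheme by taking
#' the modal category, breaking ties by the most recent record. The
#' ethnicity codelist carries four categorisations per code: the broad
#' six-level scheme (White, Black, Asian, Mixed, Other, plus Missing when no
#' source has a code), England & Wales Census 2011, Scotland Census 2011 and
#' the UK harmonised Census 2011 scheme.
#'
#' @param gp_events,hospital_events Tibbles with columns `patient_id`,
#'   `date`, `code`, `system` (either may be empty/`NULL`).
#' @param codelist Ethnicity `codelist` with columns `category` (broad),
#'   `cat_ew2011`, `cat_sc2011`, `cat_harmonised`.
#' @return Tibble with one row per patient that has at least one mapped
#'   code: `patient_id`, `ethnicity_broad`, `ethnicity_ew2011`,
#'   `ethnicity_sc2011`, `ethnicity_harmonised`, `ethnicity_source`.
#' @export
derive_ethnicity <- function(gp_events, hospital_events, codelist) {
  if (!identical(codelist_purpose(codelist), "ethnicity")) {
    abort("derive_ethnicity() requires an ethnicity codelist",
          class = "respcohort_argument_error")
  }
  assert_columns(codelist, c("cat_ew2011", "cat_sc2011", "cat_harmonised"),
                 what = "ethnicity codelist")
  lookup <- codelist |>
    select("code", "system", broad = "category", ew2011 = "cat_ew2011",
           sc2011 = "cat_sc2011", harmonised = "cat_harmonised")
  prep <- function(events, source) {
    if (is.null(events) || nrow(events) == 0) {
      return(tibble(patient_id = character(), date = as.Date(character()),
                    broad = character(), ew2011 = character(),
                    sc2011 = character(), harmonised = character(),
                    source = character()))
    }
    assert_columns(events, c("patient_id", "date", "code", "system"),
                   what = paste0(source, " ethnicity events"))
    events |>
      mutate(date = as.Date(.data$date)) |>
      inner_join(lookup, by = c("code", "system")) |>
      mutate(source = source) |>
      select("patient_id", "date", "broad", "ew2011", "sc2011", "harmonised",
             "source")
  }
  gp <- prep(gp_events, "gp")
  hosp <- prep(hospital_events, "hospital")
  hosp <- hosp |> anti_join(distinct(gp, .data$patient_id), by = "patient_id")
  bind_rows(gp, hosp) |>
    group_by(.data$patient_id) |>
    summarise(ethnicity_broad = resolve_modal(.data$broad, .data$date),
              ethnicity_ew2011 = resolve_modal(.data$ew2011, .data$date),
              ethnicity_sc2011 = resolve_modal(.data$sc2011, .data$date),
              ethnicity_harmonised = resolve_modal(.data$harmonised, .data$date),
              ethnicity_source = .data$source[1],
              .groups = "drop")
}
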