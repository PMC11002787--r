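#' Cohort specification
#'
#' The harmonised inclusion rules: patients of male or female sex with at
#' least one valid disease event on or before the latest event date
#' (2019-12-31) who were alive and registered for any period from the study
#' start (2004-01-01). Events are valid when within the patient lifetime and
#' at or above the disease's minimum event age: 35 years for COPD, 40 for
#' ILD, none for asthma (a display age floor of 1 applies only in
#' reporting).
#'
#' @param disease `"asthma"`, `"copd"` or `"ild"`.
#' @param min_event_age_years Minimum age (completed years) at a valid
#'   event; defaults 0 / 35 / 40 by disease.
#' @param study_start,latest_event_date Study window dates.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(disease = c("asthma", "copd", "ild"),
                        min_event_age_years = NULL,
                        study_start = "2004-01-01",
                        latest_event_date = "2019-12-31") {
  disease <- match.arg(disease)
  min_age <- min_event_age_years %||%
    switch(disease, asthma = 0, copd = 35, ild = 40)
  study_start <- as_date_scalar(study_start, "study_start")
  latest_event_date <- as_date_scalar(latest_event_date, "latest_event_date")
  if (min_age < 0) {
    abort("min_event_age_years must be >= 0",
          class = "respcohort_argument_error")
  }
  if (study_start >= latest_event_date) {
    abort("study_start must be before latest_event_date",
          class = "respcohort_argument_error")
  }
  structure(list(disease = disease, min_event_age_years = min_age,
                 study_start = study_start,
                 latest_event_date = latest_event_date,
                 required_sexes = c("male", "female")),
            class = "cohort_spec")
}

#' Restrict events to registration periods
#'
#' In the CPRD-like dialect, GP codes outside the patient identifier's
#' registration period are not used (each registration is its own
#' identifier, so out-of-registration events would double-count or
#' mis-attribute activity). Other dialects keep all events.
#'
#' @param events Tibble (`patient_id`, `date`, ...).
#' @param registrations Tibble (`patient_id`, `reg_start`, `reg_end`).
#' @param profile A [dialect_profile()] or dialect name.
#' @return The filtered (or untouched) events tibble.
#' @export
restrict_events_to_registration <- function(events, registrations, profile) {
  profile <- as_dialect_profile(profile)
  assert_columns(events, c("patient_id", "date"), what = "events")
  assert_columns(registrations, c("patient_id", "reg_start", "reg_end"),
                 what = "registrations")
  unknown <- setdiff(unique(events$patient_id),
                     unique(registrations$patient_id))
  if (length(unknown) > 0) {
    abort(paste0("event(s) reference patient id(s) with no registration: ",
                 paste(utils::head(unknown, 3), collapse = ", ")),
          class = "respcohort_integrity_error")
  }
  if (!profile$events_restricted_to_registration) {
    return(events)
  }
  events |>
    mutate(.row = row_number()) |>
    inner_join(registrations, by = "patient_id",
               relationship = "many-to-many") |>
    filter(.data$date >= .data$reg_start, .data$date <= .data$reg_end) |>
    distinct(.data$.row, .keep_all = TRUE) |>
    select(-"reg_start", -"reg_end", -".row")
}

#' Compute follow-up windows per patient identifier
#'
#' For the CPRD-like dialect (one identifier per registration) follow-up
#' runs from the registration start to the earliest of: date of death, last
#' practice collection date, and registration end date. For the SAIL- and
#' DataLoch-like dialects follow-up runs from the minimum registration start
#' to the earliest of: date of death, maximum registration end date, and
#' date of data extraction. A window that ends before it starts is flagged
#' invalid rather than dropped.
#'
#' @param registrations Tibble (`patient_id`, `reg_start`, `reg_end`); must
#'   be non-empty.
#' @param deaths Tibble (`patient_id`, `death_date`) of resolved death
#'   dates (see [resolve_death_date()]), or `NULL`.
#' @param profile A [dialect_profile()] or dialect name.
#' @param admin_dates Optional overrides: list with `last_collection` and/or
#'   `extraction`; defaults come from the profile.
#' @return Tibble (`patient_id`, `followup_start`, `followup_end`,
#'   `valid_followup`).
#' @export
compute_followup <- function(registrations, deaths = NULL, profile,
                             admin_dates = list()) {
  profile <- as_dialect_profile(profile)
  assert_columns(registrations, c("patient_id", "reg_start", "reg_end"),
                 what = "registrations")
  if (nrow(registrations) == 0) {
    abort("at least one registration is required",
          class = "respcohort_precondition_error")
  }
  last_collection <- as_date_scalar(admin_dates$last_collection %||%
                                      profile$last_collection_date,
                                    "last_collection")
  extraction <- as_date_scalar(admin_dates$extraction %||%
                                 profile$extraction_date, "extraction")
  dd <- if (is.null(deaths)) {
    tibble(patient_id = character(), death_date = as.Date(character()))
  } else {
    deaths |> select("patient_id", "death_date")
  }
  agg <- registrations |>
    mutate(reg_start = as.Date(.data$reg_start),
           reg_end = as.Date(.data$reg_end)) |>
    group_by(.data$patient_id) |>
    summarise(min_start = min(.data$reg_start),
              max_end = max(coalesce(.data$reg_end, extraction)),
              .groups = "drop") |>
    left_join(dd, by = "patient_id")
  out <- if (profile$name == "cprd_like") {
    agg |>
      mutate(followup_start = .data$min_start,
             followup_end = pmin(coalesce(.data$death_date, as.Date("9999-12-31")),
                                 last_collection, .data$max_end, na.rm = FALSE))
  } else {
    agg |>
      mutate(followup_start = .data$min_start,
             followup_end = pmin(coalesce(.data$death_date, as.Date("9999-12-31")),
                                 .data$max_end, extraction))
  }
  out |>
    mutate(valid_followup = .data$followup_end >= .data$followup_start) |>
    select("patient_id", "followup_start", "followup_end", "valid_followup")
}

#' Derive earliest mention and date of incidence
#'
#' The earliest mention is the first dated disease code of any
#' classification. The date of incidence is the first date of an
#' incident-classified code, set to missing whenever the earliest mention
#' falls within the first year of registration — incident rates are
#' spuriously high there because GPs enter prevalent history as if new when
#' a patient joins a practice. "First year" is the half-open interval
#' `[followup_start, followup_start + 1 calendar year)`.
#'
#' @param classified_events Tibble (`patient_id`, `date`, `classification`)
#'   with classification values from [classify_event_code()]; events must
#'   already be restricted to validity. Must be non-empty.
#' @param followup Tibble (`patient_id`, `followup_start`) or a single
#'   `Date` when `classified_events` holds one patient.
#' @return Tibble (`patient_id`, `earliest_mention`, `date_of_incidence`).
#' @export
derive_diagnosis_dates <- function(classified_events, followup) {
  assert_columns(classified_events, c("patient_id", "date", "classification"),
                 what = "classified events")
  if (nrow(classified_events) == 0) {
    abort("classified_events is empty: exclude the patient instead",
          class = "respcohort_precondition_error")
  }
  if (inherits(followup, "Date") || is.character(followup)) {
    followup <- tibble(patient_id = unique(classified_events$patient_id),
                       followup_start = as.Date(followup))
  }
  assert_columns(followup, c("patient_id", "followup_start"),
                 what = "followup")
  classified_events |>
    mutate(date = as.Date(.data$date)) |>
    filter(.data$classification %in% c("incident_and_prevalent",
                                       "prevalent_only")) |>
    group_by(.data$patient_id) |>
    summarise(
      earliest_mention = min(.data$date),
      incidence_raw = if (any(.data$classification == "incident_and_prevalent"))
        min(.data$date[.data$classification == "incident_and_prevalent"])
      else as.Date(NA),
      .groups = "drop") |>
    inner_join(followup |>
                 mutate(followup_start = as.Date(.data$followup_start)),
               by = "patient_id") |>
    mutate(first_year_end = .data$followup_start %m+% years(1),
           date_of_incidence = if_else(
             .data$earliest_mention < .data$first_year_end,
             as.Date(NA), .data$incidence_raw)) |>
    select("patient_id", "earliest_mention", "date_of_incidence")
}

#' Flag ILD subtypes from coded events
#'
#' Adds independent boolean flags for the presence of codes indicating the
#' type of ILD: idiopathic pulmonary fibrosis with broad and narrow
#' definitions (a narrow-definition code also satisfies the broad one),
#' exposure-related (hypersensitivity pneumonitis, pneumoconiosis),
#' autoimmune-related (sarcoidosis, rheumatoid arthritis-related, systemic
#' sclerosis), treatment-related (drug or radiation induced) and other. No
#' single final classification is assigned: subtype attribution can depend
#' on information outside coded primary care.
#'
#' @param events Tibble (`patient_id`, `date`, `code`, `system`).
#' @param codelist ILD `codelist` whose `category` column labels subtype
#'   codes.
#' @return Tibble with `patient_id` and logical columns `ipf_broad`,
#'   `ipf_narrow`, `exposure_related`, `autoimmune_related`,
#'   `treatment_related`, `other`.
#' @export
classify_ild_subtypes <- function(events, codelist) {
  assert_columns(events, c("patient_id", "code", "system"), what = "events")
  lookup <- codelist |>
    filter(!is.na(.data$category), .data$category != "") |>
    select("code", "system", "category")
  events |>
    inner_join(lookup, by = c("code", "system")) |>
    group_by(.data$patient_id) |>
    summarise(ipf_narrow = any(.data$category == "ipf_narrow"),
              ipf_broad = any(.data$category %in% c("ipf_narrow", "ipf_broad")),
              exposure_related = any(.data$category == "exposure_related"),
              autoimmune_related = any(.data$category == "autoimmune_related"),
              treatment_related = any(.data$category == "treatment_related"),
              other = any(.data$category == "other"),
              .groups = "drop")
}

#' Apply the harmonised cohort criteria to a bundle
#'
#' Builds the disease cohort from an EHR bundle by applying, in a fixed
#' documented order, the exclusion criteria: (1) sex not male/female,
#' (2) no valid disease event (within lifetime, on or before the latest
#' event date, at or above the minimum event age, and — in the CPRD-like
#' dialect — inside the registration period), (3) no follow-up on or after
#' the study start (not alive and registered from 2004), (4) dialect
#' quality flags (CPRD acceptability/linkage and out-of-England regions;
#' DataLoch CHI validity — modelled as boolean columns on the patients
#' table). Each excluded patient is tallied under the first criterion that
#' removes them, so the tally plus the included count equals the input
#' count.
#'
#' Members get follow-up windows, earliest mention and (maskable) date of
#' incidence, age at earliest mention, and demographics: imputed birth
#' date, resolved death date, harmonised deprivation label, region and —
#' when codelists are supplied — ethnicity; ILD cohorts get subtype flags.
#'
#' @param bundle An `ehr_bundle`.
#' @param spec A [cohort_spec()].
#' @param codelist Diagnosis `codelist` for the spec's disease.
#' @param codelists Optional named list of supporting codelists (uses
#'   `ethnicity` and, for ILD, the diagnosis list's subtype categories).
#' @param admin_dates Optional follow-up admin date overrides (see
#'   [compute_followup()]).
#' @return A `cohort` object; see [tidy.cohort()] and [glance.cohort()].
#' @export
apply_cohort_criteria <- function(bundle, spec, codelist, codelists = NULL,
                                  admin_dates = list()) {
  if (!inherits(bundle, "ehr_bundle")) {
    abort("bundle must be an ehr_bundle", class = "respcohort_argument_error")
  }
  if (!inherits(spec, "cohort_spec")) {
    abort("spec must be a cohort_spec", class = "respcohort_argument_error")
  }
  profile <- bundle$profile
  patients <- bundle$patients |>
    mutate(birth_date = impute_birth_date(.data$birth, profile))
  n_input <- nrow(patients)

  deaths <- resolve_death_date(bundle$deaths, profile,
                               birth_dates = patients |>
                                 select("patient_id", "birth_date"))
  followup <- compute_followup(bundle$registrations, deaths, profile,
                               admin_dates)
  base <- patients |>
    left_join(deaths |> select("patient_id", "death_date"),
              by = "patient_id") |>
    left_join(followup, by = "patient_id")

  ## Valid disease events per patient
  ev <- bundle$clinical_events |>
    mutate(classification = classify_event_code(.data$code, .data$system,
                                                codelist)) |>
    filter(.data$classification != "not_in_list") |>
    restrict_events_to_registration(bundle$registrations, profile) |>
    inner_join(base |>
                 select("patient_id", "birth_date", "death_date"),
               by = "patient_id") |>
    filter(.data$date >= .data$birth_date,
           is.na(.data$death_date) | .data$date <= .data$death_date,
           .data$date <= spec$latest_event_date,
           age_completed_years(.data$birth_date, .data$date) >=
             spec$min_event_age_years) |>
    select("patient_id", "date", "classification")
  has_event <- unique(ev$patient_id)

  ## Sequential exclusions, tallied under the first criterion that removes
  ## a patient.
  base <- base |>
    mutate(
      fails_sex = !(.data$sex %in% spec$required_sexes),
      fails_event = !(.data$patient_id %in% has_event),
      fails_followup = is.na(.data$valid_followup) | !.data$valid_followup |
        .data$followup_end < spec$study_start,
      fails_dialect = switch(profile$name,
        cprd_like = !.data$acceptable | !.data$linkage_eligible |
          is.na(.data$region) | !(.data$region %in% english_regions()),
        dataloch_like = !.data$chi_valid,
        rep(FALSE, n())),
      excluded_by = case_when(
        .data$fails_sex ~ "sex_not_male_or_female",
        .data$fails_event ~ "no_valid_disease_event",
        .data$fails_followup ~ "no_followup_from_study_start",
        .data$fails_dialect ~ "dialect_quality_exclusion",
        TRUE ~ NA_character_))

  criteria_order <- c("sex_not_male_or_female", "no_valid_disease_event",
                      "no_followup_from_study_start",
                      "dialect_quality_exclusion")
  exclusions <- tibble(criterion = criteria_order) |>
    left_join(base |> count(.data$excluded_by),
              by = c(criterion = "excluded_by")) |>
    mutate(n = coalesce(.data$n, 0L))

  included <- base |> filter(is.na(.data$excluded_by))
  diag_dates <- if (nrow(included) == 0) {
    tibble(patient_id = character(),
           earliest_mention = as.Date(character()),
           date_of_incidence = as.Date(character()))
  } else {
    derive_diagnosis_dates(
      ev |> filter(.data$patient_id %in% included$patient_id),
      included |> select("patient_id", "followup_start"))
  }

  members <- included |>
    inner_join(diag_dates, by = "patient_id") |>
    mutate(age_at_earliest_mention =
             age_completed_years(.data$birth_date, .data$earliest_mention))

  ## Demographics: deprivation label, ethnicity
  depr <- bundle$deprivation |>
    group_by(.data$patient_id) |>
    slice_max(.data$record_date, n = 1, with_ties = FALSE) |>
    ungroup() |>
    mutate(deprivation = harmonise_deprivation(.data$quintile, .data$scheme)) |>
    select("patient_id", "deprivation")
  members <- members |> left_join(depr, by = "patient_id")

  if (!is.null(codelists$ethnicity)) {
    eth <- derive_ethnicity(bundle$clinical_events, bundle$hospital_events,
                            codelists$ethnicity)
    members <- members |> left_join(eth, by = "patient_id")
  }

  if (spec$disease == "ild") {
    flags <- classify_ild_subtypes(
      bundle$clinical_events |>
        semi_join(members, by = "patient_id") |>
        restrict_events_to_registration(bundle$registrations, profile),
      codelist)
    members <- members |>
      left_join(flags, by = "patient_id") |>
      mutate(across(c("ipf_narrow", "ipf_broad", "exposure_related",
                      "autoimmune_related", "treatment_related", "other"),
                    ~ coalesce(.x, FALSE)))
  }

  members <- members |>
    select(-"birth", -"acceptable", -"linkage_eligible", -"chi_valid",
           -dplyr::any_of(c("fails_sex", "fails_event", "fails_followup",
                            "fails_dialect", "excluded_by", "min_start",
                            "max_end")))

  structure(list(members = members, exclusions = exclusions, spec = spec,
                 profile = profile, n_input = n_input),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort: ", x$spec$disease, ", dialect '", x$profile$name, "': ",
      nrow(x$members), " members of ", x$n_input, " input patients>\n",
      sep = "")
  invisible(x)
}

#' Expected cohort persons from the truth manifest
#'
#' Applies the cohort criteria to the latent truth: persons with the
#' disease, onset on or before the latest event date, onset age at or above
#' the minimum event age (by exact dates), a recorded male/female sex, and
#' alive on or after the study start.
#'
#' @param manifest A `truth_manifest`.
#' @param spec A [cohort_spec()].
#' @return Character vector of expected `person_id`s.
#' @export
truth_expected_persons <- function(manifest, spec) {
  d <- spec$disease
  onset_col <- paste0(d, "_onset")
  manifest$persons |>
    filter(.data[[d]],
           .data[[onset_col]] <= spec$latest_event_date,
           age_completed_years(.data$birth_date, .data[[onset_col]]) >=
             spec$min_event_age_years,
           .data$sex %in% spec$required_sexes,
           is.na(.data$death_date) |
             .data$death_date >= spec$study_start) |>
    pull("person_id")
}

#' Latent persons recovered by a cohort
#' @param cohort A `cohort`.
#' @param manifest The matching `truth_manifest`.
#' @return Character vector of recovered `person_id`s.
#' @export
recovered_persons <- function(cohort, manifest) {
  manifest$id_map |>
    semi_join(cohort$members, by = "patient_id") |>
    distinct(.data$person_id) |>
    pull("person_id")
}

#' Evaluate truth recovery of a cohort against the manifest
#'
#' Compares cohort membership (mapped back to latent persons) with the
#' manifest-derived expected set and reports sensitivity and specificity.
#' With zero injected missingness both should be exactly 1.
#'
#' @param cohort A `cohort`.
#' @param manifest The matching `truth_manifest`.
#' @param spec The [cohort_spec()] used to build the cohort.
#' @return One-row tibble: `n_expected`, `n_recovered`, `n_true_positive`,
#'   `sensitivity`, `specificity`.
#' @export
evaluate_recovery <- function(cohort, manifest, spec = cohort$spec) {
  expected <- truth_expected_persons(manifest, spec)
  recovered <- recovered_persons(cohort, manifest)
  all_persons <- manifest$persons$person_id
  tp <- intersect(recovered, expected)
  fp <- setdiff(recovered, expected)
  negatives <- setdiff(all_persons, expected)
  tibble(n_expected = length(expected),
         n_recovered = length(recovered),
         n_true_positive = length(tp),
         sensitivity = if (length(expected) == 0) NA_real_ else
           length(tp) / length(expected),
         specificity = if (length(negatives) == 0) NA_real_ else
           1 - length(fp) / length(negatives))
}
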