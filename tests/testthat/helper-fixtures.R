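# Shared fixture builders. Everything is generated in code; no binary data.

`%m+%` <- lubridate::`%m+%`

fixture_codelists <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_codelists()
    cache
  }
})

fixture_mapping <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_code_mapping()
    cache
  }
})

# A tiny diagnosis codelist used by hand-built bundle tests.
mini_diag_codelist <- function(purpose = "diagnosis") {
  codelist(data.frame(
    code = c("D1", "D2", "R1"),
    system = "medcode",
    description = c("Disease diagnosed", "Disease, other form",
                    "Disease annual review"),
    incident = c(TRUE, TRUE, FALSE),
    prevalent = c(TRUE, TRUE, TRUE),
    category = NA_character_), purpose = purpose, name = "mini")
}

empty_deaths <- function() {
  tibble::tibble(patient_id = character(),
                 primary_death_date = as.Date(character()),
                 primary_registration_date = as.Date(character()),
                 internal_death_date = as.Date(character()))
}

empty_events <- function() {
  tibble::tibble(patient_id = character(), date = as.Date(character()),
                 code = character(), system = character(),
                 value = numeric())
}

# Hand-built bundle with sensible defaults; override any table.
make_bundle <- function(profile = "cprd_like", patients, registrations,
                        clinical_events = empty_events(),
                        prescriptions = NULL, deaths = empty_deaths(),
                        deprivation = NULL, hospital_events = empty_events()) {
  profile <- dialect_profile(profile)
  patients <- tibble::as_tibble(patients)
  for (col in c("acceptable", "linkage_eligible", "chi_valid")) {
    if (!col %in% names(patients)) patients[[col]] <- TRUE
  }
  if (!"region" %in% names(patients)) {
    patients$region <- switch(profile$name, cprd_like = "London",
                              sail_like = "Wales", "Lothian")
  }
  if (is.null(prescriptions)) {
    prescriptions <- tibble::tibble(patient_id = character(),
                                    date = as.Date(character()),
                                    code = character(), system = character())
  }
  if (is.null(deprivation)) {
    deprivation <- tibble::tibble(patient_id = character(),
                                  scheme = character(), quintile = integer(),
                                  record_date = as.Date(character()))
  }
  structure(list(profile = profile, patients = patients,
                 registrations = tibble::as_tibble(registrations),
                 clinical_events = tibble::as_tibble(clinical_events),
                 prescriptions = tibble::as_tibble(prescriptions),
                 deaths = tibble::as_tibble(deaths),
                 deprivation = tibble::as_tibble(deprivation),
                 hospital_events = tibble::as_tibble(hospital_events)),
            class = "ehr_bundle")
}

# Independent brute-force oracle for the diagnosis-date rules: earliest
# mention is the minimum event date of any classification; date of
# incidence is the minimum incident-classified date, masked when the
# earliest mention falls within the first calendar year of registration.
brute_force_dates <- function(dates, classes, followup_start) {
  em <- min(dates)
  inc <- dates[classes == "incident_and_prevalent"]
  doi <- if (length(inc) > 0) min(inc) else as.Date(NA)
  if (em < followup_start %m+% lubridate::years(1)) doi <- as.Date(NA)
  list(earliest_mention = em, date_of_incidence = doi)
}

# Write a codelist CSV to a temp file and return its path.
write_codelist_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(df, path, na = "")
  path
}
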