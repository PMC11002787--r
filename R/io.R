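bundle_tables <- function() {
  c("patients", "registrations", "clinical_events", "prescriptions",
    "deaths", "deprivation", "hospital_events")
}

bundle_col_types <- function(table) {
  switch(table,
    patients = readr::cols(patient_id = "c", sex = "c", birth = "c",
                           region = "c", acceptable = "l",
                           linkage_eligible = "l", chi_valid = "l"),
    registrations = readr::cols(patient_id = "c", reg_start = "D",
                                reg_end = "D"),
    clinical_events = readr::cols(patient_id = "c", date = "D", code = "c",
                                  system = "c", value = "d"),
    hospital_events = readr::cols(patient_id = "c", date = "D", code = "c",
                                  system = "c", value = "d"),
    prescriptions = readr::cols(patient_id = "c", date = "D", code = "c",
                                system = "c"),
    deaths = readr::cols(patient_id = "c", primary_death_date = "D",
                         primary_registration_date = "D",
                         internal_death_date = "D"),
    deprivation = readr::cols(patient_id = "c", scheme = "c",
                              quintile = "i", record_date = "D"))
}

#' Write an EHR bundle to a directory of CSV tables
#'
#' One CSV per table plus a `profile.json` describing the dialect. The
#' layout is the documented tabular interchange format used by the
#' command-line interface.
#'
#' @param bundle An `ehr_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tb in bundle_tables()) {
    readr::write_csv(bundle[[tb]], file.path(dir, paste0(tb, ".csv")),
                     na = "")
  }
  jsonlite::write_json(
    list(name = bundle$profile$name,
         extraction_date = format(bundle$profile$extraction_date)),
    file.path(dir, "profile.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read an EHR bundle from a directory of CSV tables
#' @param dir Directory written by [write_bundle()].
#' @return An `ehr_bundle`.
#' @export
read_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "profile.json"))
  profile <- dialect_profile(meta$name,
                             extraction_date = meta$extraction_date)
  tables <- lapply(bundle_tables(), function(tb) {
    readr::read_csv(file.path(dir, paste0(tb, ".csv")),
                    col_types = bundle_col_types(tb), progress = FALSE,
                    na = c("", "NA"))
  })
  structure(c(list(profile = profile), setNames(tables, bundle_tables())),
            class = "ehr_bundle")
}

#' Write a truth manifest to a directory
#' @param manifest A `truth_manifest`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_manifest <- function(manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(manifest$persons, file.path(dir, "persons.csv"), na = "")
  readr::write_csv(manifest$id_map, file.path(dir, "id_map.csv"), na = "")
  params <- manifest$params
  params$birth_range <- format(params$birth_range)
  params$horizon <- format(params$horizon)
  jsonlite::write_json(list(profile_name = manifest$profile_name,
                            params = unclass(params)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a truth manifest from a directory
#' @param dir Directory written by [write_manifest()].
#' @return A `truth_manifest`.
#' @export
read_manifest <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  persons <- readr::read_csv(
    file.path(dir, "persons.csv"),
    col_types = readr::cols(person_id = "c", birth_date = "D", sex = "c",
                            death_date = "D", height_m = "d",
                            ethnicity_desc = "c", deprivation_quintile = "i",
                            region_england = "c", asthma = "l",
                            asthma_onset = "D", copd = "l", copd_onset = "D",
                            ild = "l", ild_onset = "D", ild_subtype = "c"),
    progress = FALSE, na = c("", "NA"))
  id_map <- readr::read_csv(
    file.path(dir, "id_map.csv"),
    col_types = readr::cols(patient_id = "c", person_id = "c",
                            seg_index = "i", reg_start = "D", reg_end = "D"),
    progress = FALSE, na = c("", "NA"))
  params <- do.call(population_params, meta$params)
  structure(list(persons = persons, id_map = id_map, params = params,
                 profile_name = meta$profile_name),
            class = "truth_manifest")
}

#' Write a cohort to a directory
#'
#' Members as CSV plus the exclusion tally as JSON.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$members, file.path(dir, "cohort.csv"), na = "")
  jsonlite::write_json(
    list(disease = cohort$spec$disease, dialect = cohort$profile$name,
         n_input = cohort$n_input, n_included = nrow(cohort$members),
         exclusions = setNames(as.list(cohort$exclusions$n),
                               cohort$exclusions$criterion)),
    file.path(dir, "exclusion_tally.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Write a cohort description to a directory
#'
#' One CSV per frequency table plus a combined JSON.
#'
#' @param description A `cohort_description`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_description <- function(description, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(description$tables)) {
    readr::write_csv(description$tables[[nm]],
                     file.path(dir, paste0(nm, ".csv")), na = "")
  }
  if (!is.null(description$ild_flags)) {
    readr::write_csv(description$ild_flags, file.path(dir, "ild_flags.csv"),
                     na = "")
  }
  if (!is.null(description$medication_usage)) {
    readr::write_csv(description$medication_usage,
                     file.path(dir, "medication_usage.csv"), na = "")
  }
  readr::write_csv(description$continuous, file.path(dir, "continuous.csv"),
                   na = "")
  jsonlite::write_json(
    list(n = description$n, disease = description$disease,
         dialect = description$dialect,
         index_date = format(description$index_date),
         window_start = format(description$window_start),
         tables = lapply(description$tables, function(tb) {
           setNames(as.list(tb$n), tb$level)
         })),
    file.path(dir, "description.json"), auto_unbox = TRUE)
  invisible(dir)
}
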