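# Components of combination inhaler classes, used both when rendering
# Read-coded dialects (post-2016 products lack Read codes and surface as
# same-day component prescriptions) and when detecting combinations.
combination_components <- function() {
  list(SABA_SAMA = c("SABA", "SAMA"),
       LABA_LAMA = c("LABA", "LAMA"),
       LABA_ICS = c("LABA", "ICS"),
       triple_therapy = c("LABA", "LAMA", "ICS"))
}

# Registration segments per person: practice moves split the continuous
# registration history [birth, min(death, extraction)] into abutting windows.
person_segments <- function(population, extraction_date) {
  persons <- population$persons
  final_end <- tibble(person_id = persons$person_id,
                      final_end = pmin(persons$death_date, extraction_date),
                      birth_date = persons$birth_date)
  mv <- population$moves |>
    inner_join(final_end, by = "person_id") |>
    filter(.data$move_date > .data$birth_date,
           .data$move_date <= .data$final_end) |>
    select("person_id", reg_start = "move_date")
  bind_rows(persons |> select("person_id", reg_start = "birth_date"), mv) |>
    arrange(.data$person_id, .data$reg_start) |>
    group_by(.data$person_id) |>
    mutate(seg_index = row_number(),
           reg_end = lead(.data$reg_start) - 1) |>
    ungroup() |>
    left_join(final_end |> select("person_id", "final_end"),
              by = "person_id") |>
    mutate(reg_end = coalesce(.data$reg_end, .data$final_end)) |>
    filter(.data$reg_end >= .data$reg_start) |>
    select("person_id", "seg_index", "reg_start", "reg_end")
}

# Attach the dialect patient identifier owning each (person_id, date) row.
assign_patient_ids <- function(rows, id_map) {
  if (nrow(rows) == 0) {
    rows$patient_id <- character()
    return(rows)
  }
  rows |>
    inner_join(id_map, by = "person_id", relationship = "many-to-many") |>
    filter(.data$date >= .data$reg_start, .data$date <= .data$reg_end) |>
    select(-"reg_start", -"reg_end", -"seg_index")
}

drop_missing <- function(rows, rate, rule, log_env) {
  if (rate <= 0 || nrow(rows) == 0) {
    return(rows)
  }
  keep <- runif(nrow(rows)) >= rate
  log_env$log <- bind_rows(log_env$log,
                           tibble(rule = rule, n = sum(!keep)))
  rows[keep, , drop = FALSE]
}

# Pick a code in `system` for each row, by matching rows of `cl` (candidates
# already filtered to role). Errors when a required concept has no code in
# the dialect's system.
pick_codes <- function(n, candidates, what) {
  if (nrow(candidates) == 0) {
    abort(paste0("codelist has no ", what, " codes for this dialect's ",
                 "coding system"),
          class = "respcohort_configuration_error")
  }
  candidates$code[sample.int(nrow(candidates), n, replace = TRUE)]
}

#' Render a latent population into one source dialect
#'
#' Applies every structural rule of the dialect profile: birth dates are
#' coarsened to year / ISO week / month; movers are split into one patient
#' identifier per registration when the dialect keys patients by
#' registration; clinical events are coded in the dialect's terminology
#' (medcode or Read V2); prescriptions are product-, Read- or BNF-coded,
#' with dispensed-only dialects starting at their coverage year and
#' Read-coded dialects rendering post-2016 combination inhalers as same-day
#' component prescriptions (no single combination code exists); and death
#' records are written to the dialect's mortality sources. When a person
#' with active disease joins a new practice, a prevalent disease-history
#' code is recorded at registration start — the recording behaviour that
#' makes first-year-of-registration incidence unreliable.
#'
#' @param population A [generate_population()] result.
#' @param profile A [dialect_profile()] or dialect name.
#' @param codelists Named list of codelists as from [synthetic_codelists()].
#' @param mapping A `code_mapping` (used to decide which drug classes have a
#'   Read translation).
#' @param seed Integer seed for the coding choices and missingness draws.
#' @return List with elements `bundle` (an `ehr_bundle`) and `manifest` (a
#'   `truth_manifest` linking every emitted patient identifier to its latent
#'   person).
#' @export
render_dialect <- function(population, profile,
                           codelists = synthetic_codelists(),
                           mapping = synthetic_code_mapping(), seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    abort("a seed must be given", class = "respcohort_argument_error")
  }
  if (!inherits(population, "latent_population")) {
    abort("population must be created with generate_population()",
          class = "respcohort_argument_error")
  }
  profile <- as_dialect_profile(profile)
  set.seed(as.integer(seed))
  params <- population$params
  persons <- population$persons
  log_env <- new.env()
  log_env$log <- tibble(rule = character(), n = integer())

  segments <- person_segments(population, profile$extraction_date)
  id_map <- segments |>
    mutate(patient_id = if (profile$patient_id_scope == "per_registration") {
      paste0(.data$person_id, "-R", .data$seg_index)
    } else {
      .data$person_id
    })

  registrations <- id_map |>
    select("patient_id", "reg_start", "reg_end") |>
    arrange(.data$patient_id, .data$reg_start)

  birth_str <- switch(profile$birth_granularity,
                      year = format(persons$birth_date, "%Y"),
                      week = iso_week_str(persons$birth_date),
                      month = format(persons$birth_date, "%Y-%m"))
  region <- switch(profile$region_policy,
                   england_regions = persons$region_england,
                   wales = rep("Wales", nrow(persons)),
                   lothian = rep("Lothian", nrow(persons)))
  person_attrs <- tibble(person_id = persons$person_id,
                         sex = persons$sex, birth = birth_str,
                         region = region)
  patients <- id_map |>
    distinct(.data$patient_id, .data$person_id) |>
    inner_join(person_attrs, by = "person_id") |>
    mutate(acceptable = TRUE, linkage_eligible = TRUE, chi_valid = TRUE) |>
    select("patient_id", "sex", "birth", "region", "acceptable",
           "linkage_eligible", "chi_valid")

  ## ---- diagnosis events (latent incident + reviews, plus prevalent
  ## history codes recorded when an already-diagnosed person joins a new
  ## practice) ----
  sysname <- profile$event_system
  joins <- id_map |>
    inner_join(persons |>
                 select("person_id", asthma_onset = "asthma_onset",
                        copd_onset = "copd_onset", ild_onset = "ild_onset"),
               by = "person_id") |>
    tidyr::pivot_longer(cols = c("asthma_onset", "copd_onset", "ild_onset"),
                        names_to = "disease", values_to = "onset") |>
    mutate(disease = sub("_onset$", "", .data$disease)) |>
    filter(!is.na(.data$onset), .data$reg_start > .data$onset) |>
    transmute(.data$person_id, .data$disease, date = .data$reg_start,
              role = "review", subtype = NA_character_)
  diag_latent <- bind_rows(population$diagnosis_events, joins)

  diag_events <- purrr::map_dfr(c("asthma", "copd", "ild"), function(d) {
    cl <- codelists[[d]]
    rows <- diag_latent |> filter(.data$disease == d)
    if (nrow(rows) == 0) return(NULL)
    inc_rows <- rows |> filter(.data$role == "incident")
    rev_rows <- rows |> filter(.data$role == "review")
    out <- list()
    if (nrow(inc_rows) > 0) {
      if (d == "ild") {
        inc_rows <- inc_rows |>
          group_by(.data$subtype) |>
          group_modify(function(g, key) {
            cand <- cl |> filter(.data$system == sysname, .data$incident,
                                 .data$category == key$subtype)
            g$code <- pick_codes(nrow(g), cand,
                                 paste0("incident ILD (", key$subtype, ")"))
            g
          }) |>
          ungroup()
      } else {
        cand <- cl |> filter(.data$system == sysname, .data$incident)
        inc_rows$code <- pick_codes(nrow(inc_rows), cand,
                                    paste0("incident ", d))
      }
      out$inc <- inc_rows
    }
    if (nrow(rev_rows) > 0) {
      cand <- cl |> filter(.data$system == sysname, !.data$incident,
                           .data$prevalent)
      rev_rows$code <- pick_codes(nrow(rev_rows), cand,
                                  paste0("prevalent ", d))
      out$rev <- rev_rows
    }
    bind_rows(out)
  }) |>
    transmute(.data$person_id, .data$date, .data$code, system = sysname,
              value = NA_real_) |>
    drop_missing(params$missingness$diagnosis, "missingness_diagnosis",
                 log_env)

  ## ---- smoking / BMI / spirometry measurement events ----
  smoking_lu <- codelists$smoking |>
    filter(.data$system == sysname) |>
    select("code", status = "category")
  smoking_events <- population$smoking_obs |>
    inner_join(smoking_lu, by = "status") |>
    transmute(.data$person_id, .data$date, .data$code, system = sysname,
              value = NA_real_) |>
    drop_missing(params$missingness$smoking, "missingness_smoking", log_env)

  bmi_lu <- codelists$bmi |>
    filter(.data$system == sysname) |>
    select("code", kind = "category")
  bmi_code <- bmi_lu$code[bmi_lu$kind == "bmi"][1]
  weight_code <- bmi_lu$code[bmi_lu$kind == "weight"][1]
  height_code <- bmi_lu$code[bmi_lu$kind == "height"][1]
  bmi_events <- bind_rows(
    population$bmi_obs |>
      filter(.data$mode == "bmi") |>
      transmute(.data$person_id, .data$date, code = bmi_code,
                value = round(.data$bmi, 1)),
    population$bmi_obs |>
      filter(.data$mode == "pair") |>
      transmute(.data$person_id, .data$date, code = weight_code,
                value = round(.data$weight_kg, 1)),
    population$bmi_obs |>
      filter(.data$mode == "pair") |>
      transmute(.data$person_id, .data$date, code = height_code,
                value = round(.data$height_m, 2))) |>
    mutate(system = sysname) |>
    drop_missing(params$missingness$bmi, "missingness_bmi", log_env)

  spiro_lu <- codelists$spirometry |>
    filter(.data$system == sysname) |>
    select("code", kind = "category")
  kind_code <- function(kind) spiro_lu$code[spiro_lu$kind == kind][1]
  so <- population$spirometry_obs
  spiro_events <- bind_rows(
    so |> transmute(.data$person_id, .data$date, code = kind_code("fev1"),
                    value = round(.data$fev1, 2)),
    so |> filter(.data$gp_pct_entered) |>
      transmute(.data$person_id, .data$date,
                code = kind_code("fev1_pct_predicted"),
                value = round(.data$pct_predicted, 1)),
    so |> filter(.data$bronchodilation == "pre") |>
      transmute(.data$person_id, .data$date,
                code = kind_code("pre_bronchodilation"), value = NA_real_),
    so |> filter(.data$bronchodilation == "post") |>
      transmute(.data$person_id, .data$date,
                code = kind_code("post_bronchodilation"), value = NA_real_)) |>
    mutate(system = sysname) |>
    drop_missing(params$missingness$spirometry, "missingness_spirometry",
                 log_env)

  ## ---- ethnicity (GP events in the clinical table, hospital events in a
  ## minimal hospital table) ----
  eth_lu <- codelists$ethnicity |>
    filter(.data$system == sysname) |>
    select("code", "description")
  eth_rows <- population$ethnicity_obs |>
    inner_join(persons |> select("person_id", "ethnicity_desc"),
               by = "person_id") |>
    inner_join(eth_lu, by = c(ethnicity_desc = "description")) |>
    transmute(.data$person_id, .data$date, .data$code, system = sysname,
              value = NA_real_, .data$source) |>
    drop_missing(params$missingness$ethnicity, "missingness_ethnicity",
                 log_env)

  clinical_events <- bind_rows(diag_events, smoking_events, bmi_events,
                               spiro_events,
                               eth_rows |> filter(.data$source == "gp") |>
                                 select(-"source")) |>
    assign_patient_ids(id_map) |>
    select("patient_id", "date", "code", "system", "value") |>
    arrange(.data$patient_id, .data$date, .data$code)

  hospital_events <- eth_rows |>
    filter(.data$source == "hospital") |>
    select(-"source") |>
    assign_patient_ids(id_map) |>
    select("patient_id", "date", "code", "system", "value") |>
    arrange(.data$patient_id, .data$date)

  ## ---- prescriptions ----
  drug_cl <- codelists$drugs
  rx <- population$prescriptions
  if (!is.na(profile$prescription_start_year)) {
    pre <- rx |>
      filter(as.integer(format(.data$date, "%Y")) <
               profile$prescription_start_year)
    log_env$log <- bind_rows(log_env$log,
                             tibble(rule = "dispensed_before_start_year",
                                    n = nrow(pre)))
    rx <- rx |> anti_join(pre, by = names(pre))
  }
  drug_lu <- drug_cl |>
    filter(.data$system == profile$drug_system) |>
    select(category = "category", code = "code") |>
    group_by(.data$category) |>
    slice(1) |>
    ungroup()
  if (profile$drug_coding == "read") {
    comp <- combination_components()
    has_read <- drug_lu$category
    missing_read <- setdiff(unique(rx$category), has_read)
    direct <- rx |> filter(.data$category %in% has_read)
    decomposed <- rx |>
      filter(.data$category %in% missing_read,
             .data$category %in% names(comp)) |>
      mutate(components = purrr::map(.data$category, function(ct) comp[[ct]])) |>
      tidyr::unnest("components") |>
      mutate(category = .data$components) |>
      select(-"components")
    dropped <- rx |>
      filter(.data$category %in% missing_read,
             !.data$category %in% names(comp))
    log_env$log <- bind_rows(
      log_env$log,
      tibble(rule = "decomposed_same_day_components",
             n = nrow(rx) - nrow(direct) - nrow(dropped)),
      tibble(rule = "no_read_translation_dropped", n = nrow(dropped)))
    rx <- bind_rows(direct, decomposed)
  }
  prescriptions <- rx |>
    inner_join(drug_lu, by = "category") |>
    mutate(system = profile$drug_system) |>
    drop_missing(params$missingness$prescription, "missingness_prescription",
                 log_env) |>
    assign_patient_ids(id_map) |>
    select("patient_id", "date", "code", "system") |>
    arrange(.data$patient_id, .data$date, .data$code)

  ## ---- deaths ----
  deceased <- persons |>
    filter(!is.na(.data$death_date),
           .data$death_date <= profile$extraction_date) |>
    select("person_id", date = "death_date")
  deceased <- assign_patient_ids(deceased, id_map) |>
    rename(death = "date")
  deaths <- switch(profile$death_source,
    primary_with_internal_fallback = deceased |>
      mutate(on_register = .data$death <= profile$primary_death_coverage_end,
             primary_death_date = if_else(.data$on_register, .data$death,
                                          as.Date(NA)),
             primary_registration_date = as.Date(NA),
             internal_death_date = .data$death) |>
      select("patient_id", "primary_death_date", "primary_registration_date",
             "internal_death_date"),
    primary_register = deceased |>
      transmute(.data$patient_id, primary_death_date = .data$death,
                primary_registration_date = as.Date(NA),
                internal_death_date = as.Date(NA)),
    internal_derived = deceased |>
      transmute(.data$patient_id, primary_death_date = as.Date(NA),
                primary_registration_date = as.Date(NA),
                internal_death_date = .data$death))

  ## ---- deprivation ----
  scheme_name <- profile$deprivation_scheme
  imd_scheme <- scheme_name == "imd_england_2019"
  deprivation <- patients |>
    select("patient_id") |>
    inner_join(id_map |> distinct(.data$patient_id, .data$person_id),
               by = "patient_id") |>
    inner_join(persons |> select("person_id", "deprivation_quintile"),
               by = "person_id") |>
    mutate(scheme = scheme_name,
           quintile = if (imd_scheme) {
             6L - .data$deprivation_quintile
           } else {
             .data$deprivation_quintile
           },
           record_date = as.Date("2020-06-01")) |>
    select("patient_id", "scheme", "quintile", "record_date")

  bundle <- structure(list(profile = profile,
                           patients = patients,
                           registrations = registrations,
                           clinical_events = clinical_events,
                           prescriptions = prescriptions,
                           deaths = deaths,
                           deprivation = deprivation,
                           hospital_events = hospital_events),
                      class = "ehr_bundle",
                      render_log = log_env$log |>
                        group_by(.data$rule) |>
                        summarise(n = sum(.data$n), .groups = "drop"))

  manifest <- structure(list(persons = persons,
                             id_map = id_map |>
                               select("patient_id", "person_id", "seg_index",
                                      "reg_start", "reg_end"),
                             params = params,
                             profile_name = profile$name),
                        class = "truth_manifest")
  list(bundle = bundle, manifest = manifest)
}

#' @export
print.ehr_bundle <- function(x, ...) {
  cat("<ehr_bundle '", x$profile$name, "': ", nrow(x$patients),
      " patients, ", nrow(x$clinical_events), " clinical events, ",
      nrow(x$prescriptions), " prescriptions>\n", sep = "")
  invisible(x)
}

#' @export
print.truth_manifest <- function(x, ...) {
  cat("<truth_manifest: ", nrow(x$persons), " latent persons, ",
      nrow(x$id_map), " dialect patient ids ('", x$profile_name, "')>\n",
      sep = "")
  invisible(x)
}

#' Render-stage drop log of a bundle
#'
#' Every record a dialect rule removed (pre-coverage dispensed
#' prescriptions, combination products without a Read translation) or
#' missingness injected is tallied under a named rule.
#'
#' @param bundle An `ehr_bundle`.
#' @return Tibble (`rule`, `n`).
#' @export
render_log <- function(bundle) {
  attr(bundle, "render_log") %||% tibble(rule = character(), n = integer())
}
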