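#' Asthma/COPD drug category labels
#'
#' The commonly prescribed drug categories tracked per patient-day: SABA,
#' SAMA, LABA, LAMA, ICS, the fixed combinations SABA-SAMA, LABA-LAMA and
#' LABA-ICS, OCS, triple therapy (LAMA + LABA + ICS), theophylline, PDE4
#' inhibitors (COPD cohorts only) and antibiotics (COPD cohorts only).
#'
#' @return Character vector of category labels.
#' @export
drug_categories <- function() {
  c("SABA", "SAMA", "LABA", "LAMA", "ICS", "SABA_SAMA", "LABA_LAMA",
    "LABA_ICS", "OCS", "triple_therapy", "theophylline", "PDE4",
    "antibiotics")
}

#' Classify a prescription code into drug categories
#'
#' Returns every category whose codelist entry contains the code. When the
#' code is absent in its own system, one-hop translations through the
#' mapping are tried against the codelist's systems. The set may be empty —
#' post-2016 combination inhalers have no Read translation in Read-coded
#' dialects and are instead caught later by same-day component matching.
#'
#' @param code A code string.
#' @param system Its coding system.
#' @param drug_codelist Medication `codelist` with `category` labels.
#' @param mapping Optional `code_mapping` for cross-system lookups.
#' @return Character vector (possibly empty) of category labels.
#' @export
classify_prescription <- function(code, system, drug_codelist,
                                  mapping = NULL) {
  system <- match.arg(system, code_systems())
  hits <- drug_codelist$category[drug_codelist$code == as.character(code) &
                                   drug_codelist$system == system]
  if (length(hits) == 0 && !is.null(mapping)) {
    for (target in setdiff(unique(drug_codelist$system), system)) {
      translated <- translate_code(code, system, target, mapping)
      if (length(translated) > 0) {
        hits <- c(hits,
                  drug_codelist$category[drug_codelist$code %in% translated &
                                           drug_codelist$system == target])
      }
    }
  }
  sort(unique(hits[!is.na(hits)]))
}

#' Classify a prescriptions table into drug categories
#'
#' Table counterpart of [classify_prescription()]: joins prescriptions to
#' the drug codelist by (code, system) and returns one row per
#' (patient, date, category). Uncategorised prescriptions are dropped.
#'
#' @param prescriptions Tibble (`patient_id`, `date`, `code`, `system`).
#' @param drug_codelist Medication `codelist`.
#' @param mapping Optional `code_mapping`; unmatched codes are retried via
#'   one-hop translation.
#' @return Tibble (`patient_id`, `date`, `category`), distinct.
#' @export
classify_prescriptions <- function(prescriptions, drug_codelist,
                                   mapping = NULL) {
  assert_columns(prescriptions, c("patient_id", "date", "code", "system"),
                 what = "prescriptions")
  lookup <- drug_codelist |>
    filter(!is.na(.data$category)) |>
    select("code", "system", "category")
  rx <- prescriptions |> mutate(date = as.Date(.data$date))
  direct <- rx |>
    inner_join(lookup, by = c("code", "system"),
               relationship = "many-to-many")
  out <- direct
  if (!is.null(mapping)) {
    unmatched <- rx |> anti_join(lookup, by = c("code", "system"))
    if (nrow(unmatched) > 0) {
      edges <- mapping |>
        rename(code = "source_code", system = "source_system") |>
        inner_join(lookup,
                   by = c(target_code = "code", target_system = "system"))
      translated <- unmatched |>
        inner_join(edges, by = c("code", "system"),
                   relationship = "many-to-many")
      out <- bind_rows(direct, translated)
    }
  }
  out |>
    distinct(.data$patient_id, .data$date, .data$category) |>
    arrange(.data$patient_id, .data$date, .data$category)
}

#' Add same-day combination-therapy flags to one patient-day
#'
#' Given the drug categories recorded for a single patient-day, adds the
#' combination flags implied by component drugs prescribed on the same day:
#' `triple_therapy` when LAMA, LABA and ICS are all present, `LABA_LAMA`
#' when LABA and LAMA are present, and `SABA_SAMA` when SABA and SAMA are
#' present. Combination products contribute their components (LABA_ICS
#' counts as LABA and ICS, and so on), which is how these therapies are
#' identified in Read-coded dialects where post-2016 products have no code
#' of their own. Original flags are retained.
#'
#' @param day_categories Character vector of category labels for one
#'   patient-day.
#' @return Augmented character vector of category labels.
#' @examples
#' flag_same_day_combinations(c("LAMA", "LABA", "ICS"))
#' @export
flag_same_day_combinations <- function(day_categories) {
  comp <- combination_components()
  present <- unique(day_categories)
  components <- unique(c(setdiff(present, names(comp)),
                         unlist(comp[intersect(present, names(comp))],
                                use.names = FALSE)))
  add <- names(comp)[vapply(comp, function(cc) all(cc %in% components),
                            logical(1))]
  sort(unique(c(present, add)))
}

#' Add combination flags across a classified prescriptions table
#'
#' Applies [flag_same_day_combinations()] to every patient-day. Run in every
#' dialect — harmless where single combination codes exist — so that flags
#' are comparable across dialects.
#'
#' @param classified Tibble (`patient_id`, `date`, `category`) from
#'   [classify_prescriptions()].
#' @return Tibble of the same shape with combination rows added.
#' @export
flag_combination_days <- function(classified) {
  assert_columns(classified, c("patient_id", "date", "category"),
                 what = "classified prescriptions")
  comp <- combination_components()
  expanded <- classified |>
    filter(.data$category %in% names(comp)) |>
    mutate(component = purrr::map(.data$category, function(ct) comp[[ct]])) |>
    tidyr::unnest("component") |>
    select("patient_id", "date", category = "component")
  components <- bind_rows(
    classified |> filter(!.data$category %in% names(comp)),
    expanded) |>
    distinct()
  added <- purrr::map_dfr(names(comp), function(ct) {
    needed <- comp[[ct]]
    components |>
      filter(.data$category %in% needed) |>
      distinct(.data$patient_id, .data$date, .data$category) |>
      count(.data$patient_id, .data$date) |>
      filter(.data$n == length(needed)) |>
      transmute(.data$patient_id, .data$date, category = ct)
  })
  bind_rows(classified, added) |>
    distinct(.data$patient_id, .data$date, .data$category) |>
    arrange(.data$patient_id, .data$date, .data$category)
}

#' Patients per drug category with any prescription in a year
#'
#' Counts, per category, the number of distinct cohort members with at
#' least one flagged patient-day in the calendar year; a patient counts
#' once per category regardless of prescription volume. In the CPRD-like
#' dialect only prescriptions inside the member's follow-up window count.
#' PDE4 inhibitors and antibiotics are reported for COPD cohorts only.
#'
#' @param flagged Tibble (`patient_id`, `date`, `category`) from
#'   [flag_combination_days()].
#' @param cohort A `cohort`.
#' @param year Calendar year.
#' @return Tibble (`category`, `n_patients`) over all applicable
#'   categories, with a `prescription_semantics` attribute (issued vs
#'   dispensed).
#' @export
annual_category_usage <- function(flagged, cohort, year) {
  assert_columns(flagged, c("patient_id", "date", "category"),
                 what = "flagged prescriptions")
  members <- cohort$members |>
    select("patient_id", "followup_start", "followup_end")
  rx <- flagged |>
    mutate(date = as.Date(.data$date)) |>
    filter(as.integer(format(.data$date, "%Y")) == as.integer(year)) |>
    inner_join(members, by = "patient_id")
  if (cohort$profile$name == "cprd_like") {
    rx <- rx |> filter(.data$date >= .data$followup_start,
                       .data$date <= .data$followup_end)
  }
  cats <- drug_categories()
  if (cohort$spec$disease != "copd") {
    cats <- setdiff(cats, c("PDE4", "antibiotics"))
  }
  out <- rx |>
    filter(.data$category %in% cats) |>
    distinct(.data$category, .data$patient_id) |>
    count(.data$category, name = "n_patients") |>
    right_join(tibble(category = cats), by = "category") |>
    mutate(n_patients = coalesce(.data$n_patients, 0L)) |>
    arrange(match(.data$category, cats))
  attr(out, "prescription_semantics") <- cohort$profile$prescription_semantics
  out
}
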