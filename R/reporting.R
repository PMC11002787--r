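freq_table <- function(values, n_total, levels = NULL) {
  values <- as.character(values)
  lev <- levels %||% sort(unique(values[!is.na(values)]))
  counts <- table(factor(values, levels = lev))
  out <- tibble(level = c(lev, "Missing"),
                n = c(as.integer(counts), sum(is.na(values))))
  out$pct <- if (n_total > 0) out$n / n_total * 100 else 0
  out
}

#' WHO BMI category bands
#' @param bmi Numeric BMI values (kg/m2).
#' @return Factor with levels `<18.5`, `18.5-24.9`, `25-29.9`, `>=30`.
#' @export
bmi_category <- function(bmi) {
  cut(bmi, breaks = c(-Inf, 18.5, 25, 30, Inf),
      labels = c("<18.5", "18.5-24.9", "25-29.9", ">=30"),
      right = FALSE)
}

#' Describe a cohort at an index date
#'
#' Produces the harmonised cohort description: frequency tables (with
#' explicit Missing rows so counts always sum to the cohort size) for sex,
#' broad ethnicity, deprivation label, smoking status, BMI category and —
#' when a spirometry record is supplied — GOLD stage; ILD subtype flag
#' counts for ILD cohorts; continuous summaries (age at index, BMI); and
#' drug-category usage for the index year. Only members alive and in
#' follow-up at the index date enter the description (a prevalent-at-date
#' population). Clinical measures use the most recent measurement in the
#' lookback window — five years by default, so an index of 2019-12-31 reads
#' measurements from 2015-01-01 to 2019-12-31 inclusive. Deprivation is
#' reported as descriptive labels only, never raw quintile numbers, because
#' the English and Welsh/Scottish schemes number their quintiles in
#' opposite directions.
#'
#' @param cohort A `cohort`.
#' @param records Named list of longitudinal records: `smoking`
#'   ([build_smoking_record()]), `bmi` ([build_bmi_record()]), `spirometry`
#'   ([build_spirometry_record()]); any may be omitted.
#' @param medication_flags Optional flagged prescriptions from
#'   [flag_combination_days()].
#' @param index_date Index date (default 2019-12-31).
#' @param lookback_years Lookback for clinical measures (default 5).
#' @return A `cohort_description`.
#' @export
describe_cohort <- function(cohort, records = list(),
                            medication_flags = NULL,
                            index_date = "2019-12-31",
                            lookback_years = 5) {
  index_date <- as_date_scalar(index_date, "index_date")
  window_start <- (index_date %m-% years(lookback_years)) + 1
  members <- cohort$members |>
    filter(.data$followup_start <= index_date,
           .data$followup_end >= index_date)
  n <- nrow(members)

  tables <- list()
  tables$sex <- freq_table(members$sex, n, levels = c("female", "male"))
  if ("ethnicity_broad" %in% names(members)) {
    tables$ethnicity <- freq_table(
      members$ethnicity_broad, n,
      levels = c("White", "Black", "Asian", "Mixed", "Other"))
  }
  tables$deprivation <- freq_table(members$deprivation, n,
                                   levels = deprivation_labels())

  pick_latest <- function(record) {
    if (is.null(record)) return(NULL)
    latest_in_window(record |> semi_join(members, by = "patient_id"),
                     index_date, window_start)
  }
  smoking_latest <- pick_latest(records$smoking)
  if (!is.null(smoking_latest)) {
    status <- members |>
      left_join(smoking_latest |> select("patient_id", "status"),
                by = "patient_id") |>
      pull("status")
    tables$smoking <- freq_table(status, n,
                                 levels = c("never", "ex", "current"))
  }
  bmi_latest <- pick_latest(records$bmi)
  bmi_values <- NULL
  if (!is.null(bmi_latest)) {
    bmi_values <- members |>
      left_join(bmi_latest |> select("patient_id", "bmi"), by = "patient_id") |>
      pull("bmi")
    tables$bmi_category <- freq_table(bmi_category(bmi_values), n,
                                      levels = levels(bmi_category(numeric())))
  }
  spiro <- records$spirometry
  if (!is.null(spiro)) {
    spiro_latest <- pick_latest(spiro |>
                                  filter(!is.na(.data$fev1_pct_predicted)))
    stage <- members |>
      left_join(spiro_latest |> select("patient_id", "gold_stage"),
                by = "patient_id") |>
      pull("gold_stage")
    tables$gold_stage <- freq_table(stage, n, levels = as.character(1:4))
  }

  ild_flags <- NULL
  if (cohort$spec$disease == "ild" && "ipf_broad" %in% names(members)) {
    flag_cols <- c("ipf_broad", "ipf_narrow", "exposure_related",
                   "autoimmune_related", "treatment_related", "other")
    flag_counts <- vapply(flag_cols,
                          function(cc) sum(members[[cc]], na.rm = TRUE),
                          integer(1))
    ild_flags <- tibble(flag = flag_cols, n_flagged = unname(flag_counts),
                        pct = if (n > 0) unname(flag_counts) / n * 100 else 0)
  }

  ages <- age_completed_years(members$birth_date, index_date)
  continuous <- bind_rows(
    tibble(variable = "age_at_index",
           median = stats::median(ages),
           q1 = stats::quantile(ages, 0.25, names = FALSE),
           q3 = stats::quantile(ages, 0.75, names = FALSE),
           n_missing = sum(is.na(ages))),
    if (!is.null(bmi_values)) {
      tibble(variable = "bmi",
             median = stats::median(bmi_values, na.rm = TRUE),
             q1 = stats::quantile(bmi_values, 0.25, na.rm = TRUE,
                                  names = FALSE),
             q3 = stats::quantile(bmi_values, 0.75, na.rm = TRUE,
                                  names = FALSE),
             n_missing = sum(is.na(bmi_values)))
    })

  medication_usage <- NULL
  if (!is.null(medication_flags)) {
    cohort_at <- cohort
    cohort_at$members <- members
    medication_usage <- annual_category_usage(
      medication_flags, cohort_at, as.integer(format(index_date, "%Y")))
    medication_usage$pct <- if (n > 0) {
      medication_usage$n_patients / n * 100
    } else {
      0
    }
  }

  structure(list(tables = tables, ild_flags = ild_flags,
                 continuous = continuous,
                 medication_usage = medication_usage,
                 n = n, index_date = index_date,
                 window_start = window_start,
                 lookback_years = lookback_years,
                 disease = cohort$spec$disease,
                 dialect = cohort$profile$name),
            class = "cohort_description")
}

#' @export
print.cohort_description <- function(x, ...) {
  cat("<cohort_description: ", x$disease, " ('", x$dialect, "'), n = ",
      x$n, " at ", format(x$index_date), ">\n", sep = "")
  for (nm in names(x$tables)) {
    cat("\n-- ", nm, " --\n", sep = "")
    print(as.data.frame(x$tables[[nm]]), row.names = FALSE)
  }
  invisible(x)
}

#' Age-at-first-mention distribution by sex
#'
#' Tabulates, per sex stratum, the proportion of cohort members by age in
#' completed years at the earliest mention of the condition. Ages are
#' capped at 93 to avoid small-number cells; a display age floor (1 year
#' for asthma, matching the cohort age thresholds of 35/40 for COPD/ILD)
#' removes infant records from the display only, not from the cohort.
#' Proportions are computed within each sex stratum and sum to 100%.
#'
#' @param cohort A `cohort`.
#' @param max_age Display cap (default 93); older members are pooled at
#'   the cap.
#' @param min_age Display floor; defaults to 1 for asthma, otherwise the
#'   cohort's minimum event age.
#' @return Tibble (`sex`, `age`, `n`, `proportion`).
#' @export
age_at_first_mention_distribution <- function(cohort, max_age = 93,
                                              min_age = NULL) {
  min_age <- min_age %||%
    max(1, cohort$spec$min_event_age_years)
  cohort$members |>
    mutate(age = pmin(.data$age_at_earliest_mention, max_age)) |>
    filter(.data$age >= min_age) |>
    count(.data$sex, .data$age) |>
    group_by(.data$sex) |>
    mutate(proportion = .data$n / sum(.data$n) * 100) |>
    ungroup() |>
    arrange(.data$sex, .data$age)
}
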