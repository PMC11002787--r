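#' Configuration for clinical-measure cleaning
#'
#' Plausible-value ranges and reference-equation coefficients used by the
#' longitudinal cleaning functions. The defaults follow common primary-care
#' cleaning practice for adults: BMI 10–80 kg/m2, height 1.0–2.2 m, weight
#' 20–250 kg, FEV1 0.1–8 L and FEV1 percent-predicted 10–150%. The FEV1
#' reference coefficients are the standard ERS 1993 adult regression
#' equations (per metre of height, per year of age, litres):
#' male `4.30 H - 0.029 A - 2.49`, female `3.95 H - 0.025 A - 2.60`.
#' GOLD stage boundaries are 80 / 50 / 30 percent-predicted, each boundary
#' belonging to the less severe stage.
#'
#' @param bmi_range,height_range,weight_range,fev1_range,pct_predicted_range
#'   Two-element numeric ranges (inclusive).
#' @param fev1_coef Named list `male` / `female`, each
#'   `c(height =, age =, intercept =)`.
#' @param gold_breaks Decreasing percent-predicted boundaries for stages
#'   1/2, 2/3 and 3/4.
#' @return A `measure_config` list.
#' @export
measure_config <- function(bmi_range = c(10, 80),
                           height_range = c(1.0, 2.2),
                           weight_range = c(20, 250),
                           fev1_range = c(0.1, 8),
                           pct_predicted_range = c(10, 150),
                           fev1_coef = list(
                             male = c(height = 4.30, age = -0.029,
                                      intercept = -2.49),
                             female = c(height = 3.95, age = -0.025,
                                        intercept = -2.60)),
                           gold_breaks = c(80, 50, 30)) {
  structure(list(bmi_range = bmi_range, height_range = height_range,
                 weight_range = weight_range, fev1_range = fev1_range,
                 pct_predicted_range = pct_predicted_range,
                 fev1_coef = fev1_coef, gold_breaks = gold_breaks),
            class = "measure_config")
}

#' Predicted FEV1 from sex, age and height
#'
#' Evaluates the ERS 1993 adult reference equations. Although the equations
#' were developed for White European adults aged 18–70, they are applied to
#' all patients for simplicity and comparability across sources. Returns
#' `NA` for unknown sex (the caller records the percent-predicted value as
#' missing).
#'
#' @param sex `"male"` / `"female"` (anything else yields `NA`).
#' @param age Age in years at measurement.
#' @param height Height in metres.
#' @param config A [measure_config()].
#' @return Predicted FEV1 in litres.
#' @examples
#' predict_fev1("male", 50, 1.75)    # 3.585
#' predict_fev1("female", 40, 1.60)  # 2.720
#' @export
predict_fev1 <- function(sex, age, height, config = measure_config()) {
  m <- config$fev1_coef$male
  f <- config$fev1_coef$female
  out <- ifelse(sex == "male",
                m[["height"]] * height + m[["age"]] * age + m[["intercept"]],
                ifelse(sex == "female",
                       f[["height"]] * height + f[["age"]] * age +
                         f[["intercept"]],
                       NA_real_))
  out[is.na(sex) | is.na(age) | is.na(height)] <- NA_real_
  unname(out)
}

#' GOLD stage from FEV1 percent-predicted
#'
#' Global Initiative for Chronic Obstructive Lung Disease severity grading:
#' stage 1 at >= 80% predicted, stage 2 at 50–79.99%, stage 3 at 30–49.99%,
#' stage 4 below 30%. Boundaries belong to the less severe stage. Staging is
#' applied to all available percent-predicted measurements regardless of
#' bronchodilation status.
#'
#' @param fev1_pct_predicted Percent-predicted values (vectorised; `NA`
#'   passes through).
#' @param config A [measure_config()]; values outside its
#'   `pct_predicted_range` are an error.
#' @return Integer stages 1–4.
#' @export
gold_stage <- function(fev1_pct_predicted, config = measure_config()) {
  rng <- config$pct_predicted_range
  bad <- !is.na(fev1_pct_predicted) &
    (fev1_pct_predicted < rng[1] | fev1_pct_predicted > rng[2])
  if (any(bad)) {
    abort(paste0("percent-predicted value(s) outside the plausible range [",
                 rng[1], ", ", rng[2], "]"),
          class = "respcohort_argument_error")
  }
  b <- config$gold_breaks
  ifelse(is.na(fev1_pct_predicted), NA_integer_,
         ifelse(fev1_pct_predicted >= b[1], 1L,
                ifelse(fev1_pct_predicted >= b[2], 2L,
                       ifelse(fev1_pct_predicted >= b[3], 3L, 4L))))
}

#' Build a cleaned longitudinal smoking record
#'
#' Compiles coded smoking events into a chronologically ordered per-patient
#' record of `never` / `current` / `ex` statuses. Two cleaning rules apply:
#' same-day conflicting statuses are resolved by the precedence
#' current > ex > never, and a `never` recorded after any current/ex
#' observation is re-coded to `ex` (once an ever-smoker, always at least an
#' ex-smoker). Codes not in the codelist are ignored.
#'
#' @param events Tibble (`patient_id`, `date`, `code`, `system`).
#' @param codelist Smoking `codelist` whose `category` column maps codes to
#'   statuses.
#' @return Tibble (`patient_id`, `date`, `status`), ordered within patient.
#' @export
build_smoking_record <- function(events, codelist) {
  if (!identical(codelist_purpose(codelist), "smoking")) {
    abort("build_smoking_record() requires a smoking codelist",
          class = "respcohort_argument_error")
  }
  assert_columns(events, c("patient_id", "date", "code", "system"),
                 what = "smoking events")
  lookup <- codelist |> select("code", "system", status = "category")
  prec <- c(current = 1L, ex = 2L, never = 3L)
  events |>
    mutate(date = as.Date(.data$date)) |>
    inner_join(lookup, by = c("code", "system")) |>
    filter(.data$status %in% names(prec)) |>
    group_by(.data$patient_id, .data$date) |>
    slice_min(prec[.data$status], n = 1, with_ties = FALSE) |>
    ungroup() |>
    arrange(.data$patient_id, .data$date) |>
    group_by(.data$patient_id) |>
    mutate(ever_before = lag(cumsum(.data$status != "never"), default = 0L) > 0L,
           status = if_else(.data$status == "never" & .data$ever_before,
                            "ex", .data$status)) |>
    ungroup() |>
    select("patient_id", "date", "status")
}

new_drop_log <- function() {
  tibble(patient_id = character(), date = as.Date(character()),
         rule = character(), value = numeric())
}

#' Build a cleaned longitudinal BMI record
#'
#' Recorded BMI values inside the plausible range are kept as-is. For
#' dialects that clean raw weight and height (the CPRD- and SAIL-like
#' dialects), a BMI value is additionally derived as `weight / height^2` on
#' days with a usable weight and no recorded BMI, using the most recent
#' in-range height on or before that day. The DataLoch-like dialect uses
#' only the raw recorded BMI values. Every dropped value is logged with a
#' rule name (see [measure_drops()]).
#'
#' @param events Tibble (`patient_id`, `date`, `code`, `system`, `value`)
#'   carrying BMI (kg/m2), weight (kg) and height (m) events.
#' @param codelist BMI `codelist` with categories `bmi`, `weight`, `height`.
#' @param profile A [dialect_profile()] or dialect name.
#' @param config A [measure_config()].
#' @return Tibble (`patient_id`, `date`, `bmi`, `provenance`) ordered within
#'   patient, with a `drops` attribute.
#' @export
build_bmi_record <- function(events, codelist, profile,
                             config = measure_config()) {
  if (!identical(codelist_purpose(codelist), "bmi")) {
    abort("build_bmi_record() requires a bmi codelist",
          class = "respcohort_argument_error")
  }
  profile <- as_dialect_profile(profile)
  assert_columns(events, c("patient_id", "date", "code", "system", "value"),
                 what = "bmi events")
  lookup <- codelist |> select("code", "system", kind = "category")
  ev <- events |>
    mutate(date = as.Date(.data$date)) |>
    inner_join(lookup, by = c("code", "system"))
  drops <- new_drop_log()
  range_split <- function(df, rng, rule) {
    bad <- df |> filter(is.na(.data$value) | .data$value < rng[1] |
                          .data$value > rng[2])
    if (nrow(bad) > 0) {
      drops <<- bind_rows(drops, bad |>
                            transmute(.data$patient_id, .data$date,
                                      rule = rule, value = .data$value))
    }
    df |> filter(!is.na(.data$value), .data$value >= rng[1],
                 .data$value <= rng[2])
  }
  bmi <- range_split(ev |> filter(.data$kind == "bmi"), config$bmi_range,
                     "bmi_out_of_range")
  recorded <- bmi |>
    transmute(.data$patient_id, .data$date, bmi = .data$value,
              provenance = "recorded")
  derive <- profile$name %in% c("cprd_like", "sail_like")
  derived <- NULL
  if (derive) {
    weight <- range_split(ev |> filter(.data$kind == "weight"),
                          config$weight_range, "weight_out_of_range")
    height <- range_split(ev |> filter(.data$kind == "height"),
                          config$height_range, "height_out_of_range")
    heights <- height |>
      select("patient_id", height_date = "date", height = "value") |>
      arrange(.data$patient_id, .data$height_date)
    derived <- weight |>
      anti_join(recorded, by = c("patient_id", "date")) |>
      left_join(heights, by = "patient_id",
                relationship = "many-to-many") |>
      filter(is.na(.data$height_date) | .data$height_date <= .data$date) |>
      group_by(.data$patient_id, .data$date, .data$value) |>
      slice_max(.data$height_date, n = 1, with_ties = FALSE) |>
      ungroup() |>
      filter(!is.na(.data$height)) |>
      mutate(bmi = .data$value / .data$height^2)
    derived <- range_split(derived |> mutate(value = .data$bmi),
                           config$bmi_range, "derived_bmi_out_of_range") |>
      transmute(.data$patient_id, .data$date, bmi = .data$bmi,
                provenance = "derived_from_height_weight")
  }
  out <- bind_rows(recorded, derived) |>
    arrange(.data$patient_id, .data$date)
  attr(out, "drops") <- drops
  out
}

#' Build a cleaned longitudinal spirometry record
#'
#' Compiles FEV1 (litres) and FEV1 percent-predicted events into one
#' observation per patient-day: where several FEV1 values share a day the
#' highest is used; a GP-entered percent-predicted value from the same day
#' is attached when present, otherwise percent-predicted is derived as
#' `FEV1 / predicted FEV1 * 100` with [predict_fev1()] (using age at
#' measurement, sex, and the most recent usable height on or before the
#' day). Bronchodilation status is taken from same-day codes (post beats
#' pre; otherwise unknown) and a GOLD stage is attached to every
#' percent-predicted value. Out-of-range values are dropped and logged.
#'
#' @param events Tibble (`patient_id`, `date`, `code`, `system`, `value`).
#' @param patients Tibble (`patient_id`, `sex`, `birth_date`).
#' @param codelist Spirometry `codelist` with categories `fev1`,
#'   `fev1_pct_predicted`, `pre_bronchodilation`, `post_bronchodilation`.
#' @param heights Optional tibble (`patient_id`, `date`, `height`) of
#'   cleaned height measurements in metres; without a usable height the
#'   derivation is skipped and percent-predicted left missing.
#' @param config A [measure_config()].
#' @return Tibble (`patient_id`, `date`, `fev1`, `fev1_pct_predicted`,
#'   `pct_predicted_provenance`, `bronchodilation`, `gold_stage`) with a
#'   `drops` attribute.
#' @export
build_spirometry_record <- function(events, patients, codelist,
                                    heights = NULL,
                                    config = measure_config()) {
  if (!identical(codelist_purpose(codelist), "spirometry")) {
    abort("build_spirometry_record() requires a spirometry codelist",
          class = "respcohort_argument_error")
  }
  assert_columns(events, c("patient_id", "date", "code", "system", "value"),
                 what = "spirometry events")
  assert_columns(patients, c("patient_id", "sex", "birth_date"),
                 what = "patients")
  lookup <- codelist |> select("code", "system", kind = "category")
  ev <- events |>
    mutate(date = as.Date(.data$date)) |>
    inner_join(lookup, by = c("code", "system"))
  drops <- new_drop_log()
  take_range <- function(df, rng, rule) {
    bad <- df |> filter(is.na(.data$value) | .data$value < rng[1] |
                          .data$value > rng[2])
    if (nrow(bad) > 0) {
      drops <<- bind_rows(drops, bad |>
                            transmute(.data$patient_id, .data$date,
                                      rule = rule, value = .data$value))
    }
    df |> filter(!is.na(.data$value), .data$value >= rng[1],
                 .data$value <= rng[2])
  }
  fev1 <- take_range(ev |> filter(.data$kind == "fev1"), config$fev1_range,
                     "fev1_out_of_range") |>
    group_by(.data$patient_id, .data$date) |>
    slice_max(.data$value, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("patient_id", "date", fev1 = "value")
  gp_pct <- take_range(ev |> filter(.data$kind == "fev1_pct_predicted"),
                       config$pct_predicted_range,
                       "pct_predicted_out_of_range") |>
    group_by(.data$patient_id, .data$date) |>
    slice_max(.data$value, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("patient_id", "date", gp_pct = "value")
  bronch <- ev |>
    filter(.data$kind %in% c("pre_bronchodilation", "post_bronchodilation")) |>
    group_by(.data$patient_id, .data$date) |>
    summarise(bronchodilation = if (any(.data$kind == "post_bronchodilation"))
      "post" else "pre", .groups = "drop")

  out <- fev1 |>
    left_join(gp_pct, by = c("patient_id", "date")) |>
    left_join(bronch, by = c("patient_id", "date")) |>
    left_join(patients |> select("patient_id", "sex", "birth_date"),
              by = "patient_id") |>
    mutate(age = as.numeric(.data$date - as.Date(.data$birth_date)) / 365.25)
  if (!is.null(heights) && nrow(heights) > 0) {
    assert_columns(heights, c("patient_id", "date", "height"),
                   what = "heights")
    hh <- heights |>
      filter(.data$height >= config$height_range[1],
             .data$height <= config$height_range[2]) |>
      select("patient_id", height_date = "date", height = "height")
    out <- out |>
      left_join(hh, by = "patient_id", relationship = "many-to-many") |>
      filter(is.na(.data$height_date) | .data$height_date <= .data$date) |>
      group_by(.data$patient_id, .data$date) |>
      slice_max(.data$height_date, n = 1, with_ties = FALSE) |>
      ungroup()
  } else {
    out$height <- NA_real_
  }
  out <- out |>
    mutate(predicted = predict_fev1(.data$sex, .data$age, .data$height,
                                    config),
           derived_pct = if_else(!is.na(.data$predicted) & .data$predicted > 0,
                                 .data$fev1 / .data$predicted * 100,
                                 NA_real_),
           fev1_pct_predicted = coalesce(.data$gp_pct, .data$derived_pct),
           pct_predicted_provenance = case_when(
             !is.na(.data$gp_pct) ~ "gp_entered",
             !is.na(.data$derived_pct) ~ "derived",
             TRUE ~ NA_character_),
           bronchodilation = coalesce(.data$bronchodilation, "unknown"))
  # Derived values outside the plausible percent-predicted range are
  # dropped like any other implausible value.
  rng <- config$pct_predicted_range
  out_of_range <- !is.na(out$fev1_pct_predicted) &
    (out$fev1_pct_predicted < rng[1] | out$fev1_pct_predicted > rng[2])
  if (any(out_of_range)) {
    drops <- bind_rows(drops, out[out_of_range, ] |>
                         transmute(.data$patient_id, .data$date,
                                   rule = "derived_pct_out_of_range",
                                   value = .data$fev1_pct_predicted))
    out$fev1_pct_predicted[out_of_range] <- NA_real_
    out$pct_predicted_provenance[out_of_range] <- NA_character_
  }
  out <- out |>
    mutate(gold_stage = gold_stage(.data$fev1_pct_predicted, config)) |>
    select("patient_id", "date", "fev1", "fev1_pct_predicted",
           "pct_predicted_provenance", "bronchodilation", "gold_stage") |>
    arrange(.data$patient_id, .data$date)
  attr(out, "drops") <- drops
  out
}

#' Cleaning drop log of a longitudinal record
#' @param record Result of [build_bmi_record()] or
#'   [build_spirometry_record()].
#' @return Tibble (`patient_id`, `date`, `rule`, `value`).
#' @export
measure_drops <- function(record) {
  attr(record, "drops") %||% new_drop_log()
}

#' Most recent observation in a lookback window
#'
#' Returns, per patient, the latest observation with
#' `window_start <= date <= index_date` (both bounds inclusive), or no row
#' when nothing falls inside the window. Used for cohort description with a
#' five-year lookback.
#'
#' @param record Tibble with `patient_id` and `date` columns,
#'   chronologically ordered.
#' @param index_date,window_start Window bounds (inclusive).
#' @return One row per patient with an in-window observation.
#' @export
latest_in_window <- function(record, index_date, window_start) {
  index_date <- as_date_scalar(index_date, "index_date")
  window_start <- as_date_scalar(window_start, "window_start")
  if (window_start > index_date) {
    abort("window_start must not be after index_date",
          class = "respcohort_argument_error")
  }
  record |>
    mutate(date = as.Date(.data$date)) |>
    filter(.data$date >= window_start, .data$date <= index_date) |>
    group_by(.data$patient_id) |>
    slice_max(.data$date, n = 1, with_ties = FALSE) |>
    ungroup()
}
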