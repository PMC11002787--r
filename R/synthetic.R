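#' Parameters for the synthetic latent population
#'
#' The generator draws a latent population with exact dates and known truth
#' (disease status, onset dates, smoking/BMI/spirometry trajectories,
#' prescriptions) which [render_dialect()] then coarsens into each source
#' dialect. Defaults describe a desk-scale population that exercises every
#' harmonisation pathway: disease prevalences of 10% (asthma), 5% (COPD) and
#' 1% (ILD); COPD onset ages centred at 65 and ILD at 72 years, well above
#' the 35/40-year cohort age thresholds as is clinically typical; asthma
#' onset mostly in childhood; a 20% mover fraction with practice moves
#' uniform over adulthood; and zero missingness (record-level missingness is
#' injected as independent Bernoulli drops with configurable per-variable
#' rates).
#'
#' @param n Number of latent persons.
#' @param prevalence Named list/vector of disease prevalences in `[0, 1]`
#'   (`asthma`, `copd`, `ild`).
#' @param onset_age Per-disease onset-age settings (see defaults).
#' @param mover_fraction Fraction of persons who change GP practice at least
#'   once during adulthood.
#' @param sex_unknown_rate Fraction of persons with sex recorded unknown.
#' @param missingness Named per-variable Bernoulli drop rates in `[0, 1]`
#'   (`diagnosis`, `smoking`, `bmi`, `spirometry`, `ethnicity`,
#'   `prescription`).
#' @param birth_range Two dates bounding latent birth dates.
#' @param horizon Last calendar date of generated clinical activity.
#' @param smoking_record_rate,bmi_record_rate Fractions of persons with any
#'   smoking / BMI observations.
#' @param bmi_pair_fraction Fraction of BMI observations recorded as a
#'   same-day weight + height pair instead of a direct BMI value.
#' @param gp_ethnicity_rate,hospital_ethnicity_rate Fractions of persons
#'   with an ethnicity code in GP / hospital records.
#' @param annual_review_rate Probability a living patient gets a disease
#'   review code in a given year after onset.
#' @param gp_pct_predicted_rate Probability a spirometry day carries a
#'   GP-entered FEV1 percent-predicted value alongside the FEV1 value.
#' @return A `population_params` list.
#' @export
population_params <- function(n = 1000,
                              prevalence = list(asthma = 0.10, copd = 0.05,
                                                ild = 0.01),
                              onset_age = list(
                                asthma = list(child_frac = 0.6,
                                              child_range = c(1, 16),
                                              adult_range = c(18, 70)),
                                copd = list(mean = 65, sd = 10,
                                            range = c(42, 90)),
                                ild = list(mean = 72, sd = 8,
                                           range = c(46, 95))),
                              mover_fraction = 0.2,
                              sex_unknown_rate = 0.01,
                              missingness = list(diagnosis = 0, smoking = 0,
                                                 bmi = 0, spirometry = 0,
                                                 ethnicity = 0,
                                                 prescription = 0),
                              birth_range = c("1925-01-01", "2009-12-31"),
                              horizon = "2021-12-31",
                              smoking_record_rate = 0.8,
                              bmi_record_rate = 0.8,
                              bmi_pair_fraction = 0.3,
                              gp_ethnicity_rate = 0.7,
                              hospital_ethnicity_rate = 0.5,
                              annual_review_rate = 0.9,
                              gp_pct_predicted_rate = 0.5) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    abort("n must be a single integer >= 1", class = "respcohort_argument_error")
  }
  prevalence <- as.list(prevalence)
  for (d in c("asthma", "copd", "ild")) {
    p <- prevalence[[d]]
    if (is.null(p) || is.na(p) || p < 0 || p > 1) {
      abort(paste0("prevalence for '", d, "' must be in [0, 1]"),
            class = "respcohort_argument_error")
    }
  }
  missingness <- utils::modifyList(
    list(diagnosis = 0, smoking = 0, bmi = 0, spirometry = 0, ethnicity = 0,
         prescription = 0), as.list(missingness))
  if (any(unlist(missingness) < 0 | unlist(missingness) > 1)) {
    abort("missingness rates must be in [0, 1]",
          class = "respcohort_argument_error")
  }
  for (p in c(mover_fraction, sex_unknown_rate, smoking_record_rate,
              bmi_record_rate, bmi_pair_fraction, gp_ethnicity_rate,
              hospital_ethnicity_rate, annual_review_rate,
              gp_pct_predicted_rate)) {
    if (is.na(p) || p < 0 || p > 1) {
      abort("rate parameters must be in [0, 1]",
            class = "respcohort_argument_error")
    }
  }
  structure(list(n = as.integer(n), prevalence = prevalence,
                 onset_age = onset_age, mover_fraction = mover_fraction,
                 sex_unknown_rate = sex_unknown_rate,
                 missingness = missingness,
                 birth_range = as.Date(birth_range),
                 horizon = as.Date(horizon),
                 smoking_record_rate = smoking_record_rate,
                 bmi_record_rate = bmi_record_rate,
                 bmi_pair_fraction = bmi_pair_fraction,
                 gp_ethnicity_rate = gp_ethnicity_rate,
                 hospital_ethnicity_rate = hospital_ethnicity_rate,
                 annual_review_rate = annual_review_rate,
                 gp_pct_predicted_rate = gp_pct_predicted_rate),
            class = "population_params")
}

# Synthetic ethnicity concept frequencies; descriptions match the packaged
# ethnicity codelist.
ethnicity_concept_freqs <- function() {
  tibble(
    description = c("Ethnic group: White British", "Ethnic group: White Irish",
                    "Ethnic group: Indian", "Ethnic group: Pakistani",
                    "Ethnic group: Chinese", "Ethnic group: Black African",
                    "Ethnic group: Black Caribbean",
                    "Ethnic group: Mixed White and Asian",
                    "Ethnic group: Any other ethnic group"),
    prob = c(0.70, 0.10, 0.03, 0.025, 0.015, 0.03, 0.02, 0.03, 0.05))
}

ild_subtype_freqs <- function() {
  tibble(category = c("ipf_narrow", "ipf_broad", "exposure_related",
                      "autoimmune_related", "treatment_related", "other"),
         prob = c(0.35, 0.20, 0.10, 0.15, 0.05, 0.15))
}

# Per-disease drug prescribing schedule: probability of at least one
# prescription of the class in a treated person-year. Combination inhalers
# without Read translations entered UK use in 2017, hence the year floors.
drug_schedule <- function() {
  dplyr::bind_rows(
    tibble(disease = "asthma",
           category = c("SABA", "ICS", "LABA_ICS", "OCS", "theophylline",
                        "SABA_SAMA"),
           prob = c(0.90, 0.70, 0.30, 0.15, 0.05, 0.05),
           min_year = c(1995, 1995, 2000, 1995, 1995, 1995)),
    tibble(disease = "copd",
           category = c("SABA", "SAMA", "LAMA", "LABA", "LABA_ICS",
                        "LABA_LAMA", "triple_therapy", "OCS", "PDE4",
                        "antibiotics", "theophylline", "SABA_SAMA"),
           prob = c(0.80, 0.30, 0.60, 0.30, 0.40, 0.30, 0.30, 0.20, 0.05,
                    0.40, 0.05, 0.10),
           min_year = c(1995, 1995, 2002, 1995, 2000, 2017, 2017, 1995, 2011,
                        1995, 1995, 1995)))
}

sample_onset_age <- function(n, disease, onset_age) {
  cfg <- onset_age[[disease]]
  if (disease == "asthma") {
    child <- runif(n) < cfg$child_frac
    age <- numeric(n)
    age[child] <- runif(sum(child), cfg$child_range[1], cfg$child_range[2])
    age[!child] <- runif(sum(!child), cfg$adult_range[1], cfg$adult_range[2])
    age
  } else {
    pmin(pmax(rnorm(n, cfg$mean, cfg$sd), cfg$range[1]), cfg$range[2])
  }
}

#' Generate a latent population with known truth
#'
#' Draws `params$n` latent persons with exact birth/death dates, disease
#' status and onset dates, practice moves, smoking/BMI/spirometry
#' trajectories, prescriptions and ethnicity/deprivation attributes. Latent
#' truth always uses exact dates; coarsening to the dialects' year/week/month
#' birth granularity happens only in [render_dialect()], so imputation error
#' can be quantified exactly.
#'
#' @param params A [population_params()] object (or arguments for one).
#' @param seed Integer seed; the same seed reproduces the population
#'   byte-for-byte.
#' @return A `latent_population`: list of tibbles `persons`, `moves`,
#'   `diagnosis_events`, `smoking_obs`, `bmi_obs`, `spirometry_obs`,
#'   `prescriptions`, `ethnicity_obs`, plus `params`.
#' @examples
#' pop <- generate_population(population_params(n = 50), seed = 1)
#' nrow(pop$persons)
#' @export
generate_population <- function(params = population_params(), seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    abort("a seed must be given", class = "respcohort_argument_error")
  }
  if (!inherits(params, "population_params")) {
    abort("params must be created with population_params()",
          class = "respcohort_argument_error")
  }
  set.seed(as.integer(seed))
  n <- params$n
  horizon <- params$horizon

  persons <- tibble(
    person_id = sprintf("L%06d", seq_len(n)),
    birth_date = runif_dates(n, params$birth_range[1], params$birth_range[2]),
    sex = sample(c("male", "female", "unknown"), n, replace = TRUE,
                 prob = c((1 - params$sex_unknown_rate) / 2,
                          (1 - params$sex_unknown_rate) / 2,
                          params$sex_unknown_rate)))
  persons$death_date <- persons$birth_date +
    round(pmin(pmax(rnorm(n, 85, 12), 1), 105) * 365.25)
  persons$height_m <- pmin(pmax(
    rnorm(n, ifelse(persons$sex == "male", 1.75,
                    ifelse(persons$sex == "female", 1.62, 1.68)),
          ifelse(persons$sex == "male", 0.07, 0.06)), 1.45), 2.05)
  eth <- ethnicity_concept_freqs()
  persons$ethnicity_desc <- sample(eth$description, n, replace = TRUE,
                                   prob = eth$prob)
  persons$deprivation_quintile <- sample(1:5, n, replace = TRUE)
  persons$region_england <- sample(english_regions(), n, replace = TRUE)
  persons$smoking_type <- sample(c("never", "current", "quitter"), n,
                                 replace = TRUE, prob = c(0.45, 0.25, 0.30))
  persons$smoking_start_age <- runif(n, 16, 25)
  persons$smoking_quit_age <- persons$smoking_start_age + runif(n, 5, 40)
  persons$bmi_base <- pmin(pmax(rnorm(n, 27, 4), 16), 45)

  for (d in c("asthma", "copd", "ild")) {
    has <- runif(n) < params$prevalence[[d]]
    age <- sample_onset_age(n, d, params$onset_age)
    onset <- persons$birth_date + round(age * 365.25)
    invalid <- onset >= persons$death_date - 30
    has[invalid] <- FALSE
    onset[!has] <- NA
    persons[[d]] <- has
    persons[[paste0(d, "_onset")]] <- onset
  }
  persons$ild_subtype <- NA_character_
  sub <- ild_subtype_freqs()
  persons$ild_subtype[persons$ild] <- sample(sub$category,
                                             sum(persons$ild), replace = TRUE,
                                             prob = sub$prob)

  # Practice moves: uniform over adulthood, before death and the activity
  # horizon.
  mover <- runif(n) < params$mover_fraction
  n_moves <- ifelse(mover, sample(1:2, n, replace = TRUE, prob = c(0.7, 0.3)),
                    0L)
  moves <- persons |>
    mutate(n_moves = n_moves,
           adult_start = .data$birth_date + round(18 * 365.25),
           adult_end = pmin(.data$death_date - 1, horizon)) |>
    filter(.data$n_moves > 0, .data$adult_end > .data$adult_start + 30) |>
    select("person_id", "n_moves", "adult_start", "adult_end") |>
    tidyr::uncount(.data$n_moves) |>
    mutate(move_date = .data$adult_start +
             floor(runif(n()) * as.numeric(.data$adult_end - .data$adult_start))) |>
    distinct(.data$person_id, .data$move_date) |>
    arrange(.data$person_id, .data$move_date) |>
    select("person_id", "move_date")

  diagnosis_events <- purrr::map_dfr(c("asthma", "copd", "ild"), function(d) {
    dp <- persons |>
      filter(.data[[d]]) |>
      transmute(.data$person_id, disease = d,
                onset = .data[[paste0(d, "_onset")]],
                subtype = if (d == "ild") .data$ild_subtype else NA_character_,
                end_active = pmin(.data$death_date - 1, horizon))
    if (nrow(dp) == 0) return(NULL)
    incident <- dp |>
      filter(.data$onset <= .data$end_active) |>
      transmute(.data$person_id, .data$disease, date = .data$onset,
                role = "incident", .data$subtype)
    reviews <- dp |>
      mutate(k_max = pmax(0, floor(as.numeric(.data$end_active - .data$onset) /
                                     365.25))) |>
      filter(.data$k_max > 0) |>
      tidyr::uncount(.data$k_max, .id = "k") |>
      mutate(date = .data$onset %m+% years(.data$k)) |>
      filter(.data$date <= .data$end_active,
             runif(n()) < params$annual_review_rate) |>
      transmute(.data$person_id, .data$disease, .data$date, role = "review",
                subtype = NA_character_)
    bind_rows(incident, reviews)
  })
  if (nrow(diagnosis_events) == 0) {
    diagnosis_events <- tibble(person_id = character(), disease = character(),
                               date = as.Date(character()),
                               role = character(), subtype = character())
  }

  obs_dates <- function(df, from, to) {
    df |>
      mutate(span = as.numeric({{ to }} - {{ from }})) |>
      filter(.data$span > 0) |>
      mutate(date = {{ from }} + floor(runif(n()) * .data$span))
  }

  smoking_obs <- persons |>
    filter(runif(n()) < params$smoking_record_rate) |>
    mutate(k = rpois(n(), 3)) |>
    filter(.data$k > 0) |>
    tidyr::uncount(.data$k) |>
    mutate(from = pmax(.data$birth_date + round(16 * 365.25),
                       as.Date("1990-01-01")),
           to = pmin(.data$death_date - 1, horizon)) |>
    obs_dates(.data$from, .data$to) |>
    mutate(age = as.numeric(.data$date - .data$birth_date) / 365.25,
           status = case_when(
             .data$smoking_type == "never" ~ "never",
             .data$age < .data$smoking_start_age ~ "never",
             .data$smoking_type == "current" ~ "current",
             .data$age < .data$smoking_quit_age ~ "current",
             TRUE ~ "ex")) |>
    select("person_id", "date", "status") |>
    arrange(.data$person_id, .data$date)

  bmi_obs <- persons |>
    filter(runif(n()) < params$bmi_record_rate) |>
    mutate(k = rpois(n(), 3)) |>
    filter(.data$k > 0) |>
    tidyr::uncount(.data$k) |>
    mutate(from = pmax(.data$birth_date + round(18 * 365.25),
                       as.Date("1995-01-01")),
           to = pmin(.data$death_date - 1, horizon)) |>
    obs_dates(.data$from, .data$to) |>
    mutate(bmi = pmin(pmax(.data$bmi_base + rnorm(n(), 0, 1.5), 12), 70),
           weight_kg = .data$bmi * .data$height_m^2,
           mode = sample(c("bmi", "pair"), n(), replace = TRUE,
                         prob = c(1 - params$bmi_pair_fraction,
                                  params$bmi_pair_fraction))) |>
    select("person_id", "date", "bmi", "weight_kg", height_m = "height_m",
           "mode") |>
    arrange(.data$person_id, .data$date)

  spirometry_obs <- persons |>
    filter(.data$copd, .data$sex %in% c("male", "female")) |>
    mutate(k = rpois(n(), 4)) |>
    filter(.data$k > 0) |>
    tidyr::uncount(.data$k) |>
    mutate(from = .data$copd_onset, to = pmin(.data$death_date - 1, horizon)) |>
    obs_dates(.data$from, .data$to) |>
    mutate(age = as.numeric(.data$date - .data$birth_date) / 365.25,
           pct_predicted = pmin(pmax(rnorm(n(), 55, 15), 15), 120),
           fev1 = .data$pct_predicted / 100 *
             predict_fev1(.data$sex, .data$age, .data$height_m),
           gp_pct_entered = runif(n()) < params$gp_pct_predicted_rate,
           bronchodilation = sample(c("pre", "post", "none"), n(),
                                    replace = TRUE, prob = c(0.25, 0.05, 0.7))) |>
    select("person_id", "date", "fev1", "pct_predicted", "gp_pct_entered",
           "bronchodilation") |>
    arrange(.data$person_id, .data$date)

  sched <- drug_schedule()
  prescriptions <- purrr::map_dfr(c("asthma", "copd"), function(d) {
    dp <- persons |>
      filter(.data[[d]]) |>
      transmute(.data$person_id, onset = .data[[paste0(d, "_onset")]],
                end_active = pmin(.data$death_date - 1, horizon)) |>
      filter(.data$onset <= .data$end_active)
    if (nrow(dp) == 0) return(NULL)
    yrs <- dp |>
      mutate(y_from = pmax(as.integer(format(.data$onset, "%Y")), 1995L),
             y_to = as.integer(format(.data$end_active, "%Y")),
             ny = .data$y_to - .data$y_from + 1L) |>
      filter(.data$ny > 0) |>
      tidyr::uncount(.data$ny, .id = "i") |>
      mutate(rx_year = .data$y_from + .data$i - 1L)
    purrr::map_dfr(seq_len(nrow(sched |> filter(.data$disease == d))),
                   function(j) {
      row <- sched |> filter(.data$disease == d) |> slice(j)
      cand <- yrs |> filter(.data$rx_year >= row$min_year,
                            runif(n()) < row$prob)
      if (nrow(cand) == 0) return(NULL)
      cand |>
        mutate(win_start = pmax(.data$onset,
                                as.Date(paste0(.data$rx_year, "-01-01"))),
               win_end = pmin(.data$end_active,
                              as.Date(paste0(.data$rx_year, "-12-31")))) |>
        filter(.data$win_end >= .data$win_start) |>
        mutate(date = .data$win_start +
                 floor(runif(n()) *
                         (as.numeric(.data$win_end - .data$win_start) + 1)),
               category = row$category) |>
        select("person_id", "date", "category")
    })
  })
  if (nrow(prescriptions) == 0) {
    prescriptions <- tibble(person_id = character(),
                            date = as.Date(character()),
                            category = character())
  }
  prescriptions <- prescriptions |> arrange(.data$person_id, .data$date)

  eth_dates <- function(rate) {
    persons |>
      filter(runif(n()) < rate) |>
      mutate(from = pmax(.data$birth_date + 365, as.Date("1995-01-01")),
             to = pmin(.data$death_date - 1, horizon)) |>
      obs_dates(.data$from, .data$to) |>
      select("person_id", "date")
  }
  ethnicity_obs <- bind_rows(
    eth_dates(params$gp_ethnicity_rate) |> mutate(source = "gp"),
    eth_dates(params$hospital_ethnicity_rate) |> mutate(source = "hospital")) |>
    arrange(.data$person_id, .data$date)

  structure(list(params = params,
                 persons = persons |>
                   select(-"bmi_base", -"smoking_start_age",
                          -"smoking_quit_age", -"smoking_type"),
                 moves = moves,
                 diagnosis_events = diagnosis_events,
                 smoking_obs = smoking_obs,
                 bmi_obs = bmi_obs,
                 spirometry_obs = spirometry_obs,
                 prescriptions = prescriptions,
                 ethnicity_obs = ethnicity_obs),
            class = "latent_population")
}

#' @export
print.latent_population <- function(x, ...) {
  cat("<latent_population: ", nrow(x$persons), " persons, ",
      nrow(x$diagnosis_events), " diagnosis events, ",
      nrow(x$prescriptions), " prescriptions>\n", sep = "")
  invisible(x)
}
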