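test_that("events outside the registration period are dropped only in the CPRD-like dialect", {
  regs <- tibble::tibble(patient_id = "p1",
                         reg_start = as.Date("2010-01-01"),
                         reg_end = as.Date("2015-12-31"))
  ev <- tibble::tibble(patient_id = "p1",
                       date = as.Date(c("2009-06-01", "2012-06-01")),
                       code = "D1", system = "medcode", value = NA_real_)
  out <- restrict_events_to_registration(ev, regs, "cprd_like")
  expect_equal(out$date, as.Date("2012-06-01"))
  # the rule applies to the CPRD-like dialect only
  out_sail <- restrict_events_to_registration(ev, regs, "sail_like")
  expect_equal(nrow(out_sail), 2)
  # an event between two registrations is retained in per-person dialects
  regs2 <- tibble::tibble(patient_id = "p1",
                          reg_start = as.Date(c("2000-01-01", "2007-01-01")),
                          reg_end = as.Date(c("2005-12-31", "2015-12-31")))
  gap_ev <- tibble::tibble(patient_id = "p1", date = as.Date("2006-06-01"),
                           code = "D1", system = "medcode",
                           value = NA_real_)
  expect_equal(nrow(restrict_events_to_registration(gap_ev, regs2,
                                                    "sail_like")), 1)
  expect_equal(nrow(restrict_events_to_registration(gap_ev, regs2,
                                                    "cprd_like")), 0)
  # integrity: unknown patient id
  bad <- tibble::tibble(patient_id = "ghost", date = as.Date("2012-01-01"),
                        code = "D1", system = "medcode", value = NA_real_)
  expect_error(restrict_events_to_registration(bad, regs, "cprd_like"),
               class = "respcohort_integrity_error")
})

test_that("follow-up windows follow the dialect rules", {
  # CPRD-like: earliest of death, last collection and registration end
  regs <- tibble::tibble(patient_id = "p1",
                         reg_start = as.Date("2005-01-01"),
                         reg_end = as.Date("2020-03-01"))
  deaths <- tibble::tibble(patient_id = "p1",
                           death_date = as.Date("2018-05-01"))
  fu <- compute_followup(regs, deaths, "cprd_like",
                         admin_dates = list(last_collection = "2019-01-01"))
  expect_equal(fu$followup_start, as.Date("2005-01-01"))
  expect_equal(fu$followup_end, as.Date("2018-05-01"))
  expect_true(fu$valid_followup)

  # SAIL-like: min registration start to earliest of death, max
  # registration end and extraction
  regs2 <- tibble::tibble(patient_id = "p2",
                          reg_start = as.Date(c("2000-03-01", "2007-01-01")),
                          reg_end = as.Date(c("2005-12-31", NA)))
  fu2 <- compute_followup(regs2, NULL, "sail_like",
                          admin_dates = list(extraction = "2022-03-07"))
  expect_equal(fu2$followup_start, as.Date("2000-03-01"))
  expect_equal(fu2$followup_end, as.Date("2022-03-07"))

  # death before registration start flags invalid follow-up
  deaths3 <- tibble::tibble(patient_id = "p1",
                            death_date = as.Date("2004-06-01"))
  fu3 <- compute_followup(regs, deaths3, "cprd_like")
  expect_false(fu3$valid_followup)

  expect_error(compute_followup(regs[0, ], NULL, "cprd_like"),
               class = "respcohort_precondition_error")
})

test_that("earliest mention and date of incidence follow the masking rule", {
  # earliest (incident) mention within the first registration year masks
  # the date of incidence
  ev1 <- tibble::tibble(patient_id = "p1", date = as.Date("2010-06-01"),
                        classification = "incident_and_prevalent")
  out1 <- derive_diagnosis_dates(ev1, as.Date("2010-01-01"))
  expect_equal(out1$earliest_mention, as.Date("2010-06-01"))
  expect_true(is.na(out1$date_of_incidence))

  # single incident code outside the first year: both dates equal
  out2 <- derive_diagnosis_dates(
    ev1 |> dplyr::mutate(patient_id = "p2"), as.Date("2005-03-01"))
  expect_equal(out2$earliest_mention, as.Date("2010-06-01"))
  expect_equal(out2$date_of_incidence, as.Date("2010-06-01"))

  # prevalent-only code sets the earliest mention, incident code the
  # date of incidence
  ev3 <- tibble::tibble(
    patient_id = "p3",
    date = as.Date(c("2008-02-01", "2009-09-01")),
    classification = c("prevalent_only", "incident_and_prevalent"))
  out3 <- derive_diagnosis_dates(ev3, as.Date("2005-01-01"))
  expect_equal(out3$earliest_mention, as.Date("2008-02-01"))
  expect_equal(out3$date_of_incidence, as.Date("2009-09-01"))

  # prevalent-only mentions alone leave incidence missing
  ev4 <- ev3[1, ]
  out4 <- derive_diagnosis_dates(ev4, as.Date("2005-01-01"))
  expect_true(is.na(out4$date_of_incidence))

  expect_error(derive_diagnosis_dates(ev1[0, ], as.Date("2005-01-01")),
               class = "respcohort_precondition_error")
})

test_that("diagnosis dates match a brute-force scan on randomised patients", {
  set.seed(77)
  n_pat <- 300
  fu <- tibble::tibble(
    patient_id = sprintf("p%03d", seq_len(n_pat)),
    followup_start = as.Date("1998-01-01") + sample.int(6000, n_pat))
  ev <- fu |>
    dplyr::mutate(k = sample(1:6, n_pat, replace = TRUE)) |>
    tidyr::uncount(.data$k) |>
    dplyr::mutate(
      date = .data$followup_start + sample.int(5000, dplyr::n(),
                                               replace = TRUE) - 1500,
      classification = sample(c("incident_and_prevalent", "prevalent_only"),
                              dplyr::n(), replace = TRUE)) |>
    dplyr::select("patient_id", "date", "classification")
  out <- derive_diagnosis_dates(ev, fu)
  expect_equal(nrow(out), n_pat)
  for (pid in sample(fu$patient_id, 100)) {
    sub <- ev[ev$patient_id == pid, ]
    oracle <- brute_force_dates(sub$date, sub$classification,
                                fu$followup_start[fu$patient_id == pid])
    row <- out[out$patient_id == pid, ]
    expect_equal(row$earliest_mention, oracle$earliest_mention)
    expect_equal(row$date_of_incidence, oracle$date_of_incidence)
  }
})

test_that("cohort criteria exclude per the harmonised rules, in order", {
  cl <- mini_diag_codelist()
  patients <- tibble::tibble(
    patient_id = c("young", "dead2003", "prebirth", "nosex", "ok"),
    sex = c("male", "female", "male", "unknown", "female"),
    birth = c("1980", "1940", "1980", "1960", "1950"))
  regs <- tibble::tibble(
    patient_id = patients$patient_id,
    reg_start = as.Date(c("1990-01-01", "1950-01-01", "1990-01-01",
                          "1970-01-01", "1960-01-01")),
    reg_end = as.Date("2021-12-31"))
  events <- tibble::tibble(
    patient_id = c("young", "dead2003", "prebirth", "nosex", "ok"),
    date = as.Date(c("2014-06-01",   # age 33 at event: below COPD threshold
                     "2001-06-01",   # valid event but dead before 2004
                     "1975-06-01",   # before (imputed) birth
                     "2010-06-01",   # valid event but unknown sex
                     "2010-06-01")),
    code = "D1", system = "medcode", value = NA_real_)
  deaths <- tibble::tibble(patient_id = "dead2003",
                           primary_death_date = as.Date("2003-06-01"),
                           primary_registration_date = as.Date(NA),
                           internal_death_date = as.Date(NA))
  bundle <- make_bundle("cprd_like", patients, regs, events,
                        deaths = deaths)
  co <- apply_cohort_criteria(bundle, cohort_spec("copd"), cl)
  expect_equal(tidy(co)$patient_id, "ok")
  tally <- setNames(co$exclusions$n, co$exclusions$criterion)
  expect_equal(unname(tally["sex_not_male_or_female"]), 1L)  # nosex
  expect_equal(unname(tally["no_valid_disease_event"]), 2L)  # young, prebirth
  expect_equal(unname(tally["no_followup_from_study_start"]), 1L)
  # conservation: tally + included = input
  expect_equal(sum(co$exclusions$n) + nrow(co$members), co$n_input)
  # a patient failing several criteria is tallied once, under the first
  expect_equal(sum(co$exclusions$n), 4L)
})

test_that("raising the minimum event age never adds members", {
  run <- cached_cohort("sail_like", "copd", n = 2000, seed = 55,
                       render_seed = 56)
  r <- cached_render("sail_like", n = 2000, seed = 55, render_seed = 56)
  cls <- fixture_codelists()
  strict <- apply_cohort_criteria(r$bundle, cohort_spec("copd",
                                                        min_event_age_years = 60),
                                  cls$copd)
  expect_true(all(strict$members$patient_id %in%
                    run$cohort$members$patient_id))
  expect_lte(nrow(strict$members), nrow(run$cohort$members))
})

test_that("ILD subtype flags are independent booleans", {
  cl <- fixture_codelists()$ild
  ev <- tibble::tibble(
    patient_id = c("a", "b", "c", "c"),
    date = as.Date("2015-01-01"),
    code = c("300001",   # narrow-definition IPF
             "300004",   # sarcoidosis
             "300001", "300003"),  # IPF plus hypersensitivity pneumonitis
    system = "medcode")
  out <- classify_ild_subtypes(ev, cl)
  a <- out[out$patient_id == "a", ]
  expect_true(a$ipf_narrow && a$ipf_broad)
  expect_false(a$autoimmune_related)
  b <- out[out$patient_id == "b", ]
  expect_true(b$autoimmune_related)
  expect_false(b$ipf_broad)
  cc <- out[out$patient_id == "c", ]
  # both flags true; no single exclusive classification exists
  expect_true(cc$ipf_narrow && cc$exposure_related)
})
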