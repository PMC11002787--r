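test_that("generation is reproducible and rejects bad parameters", {
  p <- population_params(n = 120)
  a <- generate_population(p, seed = 5)
  b <- generate_population(p, seed = 5)
  expect_identical(a$persons, b$persons)
  expect_identical(a$diagnosis_events, b$diagnosis_events)
  expect_identical(a$prescriptions, b$prescriptions)
  c <- generate_population(p, seed = 6)
  expect_false(identical(a$persons, c$persons))

  expect_error(population_params(n = 0), class = "respcohort_argument_error")
  expect_error(population_params(prevalence = list(asthma = 1.2, copd = 0,
                                                   ild = 0)),
               class = "respcohort_argument_error")
  expect_error(population_params(mover_fraction = -0.1),
               class = "respcohort_argument_error")
  expect_error(generate_population(p), class = "respcohort_argument_error")
})

test_that("empirical prevalence tracks the parameter", {
  # binomial oracle: sd = sqrt(n p (1-p)) = 30 at n = 10,000, p = 0.1, so
  # the diseased count should fall within 3 sd of 1,000. Disease status is
  # only retained when onset fits inside the lifetime, which removes a few
  # late-onset draws, so the check allows that one-sided shortfall.
  pop <- cached_population(n = 10000, seed = 101)
  n_asthma <- sum(pop$persons$asthma)
  expect_gt(n_asthma, 1000 - 4 * 30)
  expect_lt(n_asthma, 1000 + 3 * 30)

  none <- generate_population(
    population_params(n = 500, prevalence = list(asthma = 0, copd = 0,
                                                 ild = 0)), seed = 9)
  expect_equal(sum(none$persons$asthma), 0)
  expect_equal(sum(none$persons$copd), 0)
  expect_equal(nrow(none$diagnosis_events), 0)
})

test_that("rendered birth information has exactly the profile granularity", {
  pop <- generate_population(population_params(n = 80), seed = 21)
  cls <- fixture_codelists(); m <- fixture_mapping()
  pats_cprd <- render_dialect(pop, "cprd_like", cls, m, seed = 1)$bundle$patients
  expect_true(all(grepl("^\\d{4}$", pats_cprd$birth)))
  pats_sail <- render_dialect(pop, "sail_like", cls, m, seed = 1)$bundle$patients
  expect_true(all(grepl("^\\d{4}-W\\d{2}$", pats_sail$birth)))
  pats_dl <- render_dialect(pop, "dataloch_like", cls, m, seed = 1)$bundle$patients
  expect_true(all(grepl("^\\d{4}-\\d{2}$", pats_dl$birth)))
})

test_that("movers split into multiple ids only in the per-registration dialect", {
  pop <- generate_population(population_params(n = 200, mover_fraction = 1),
                             seed = 31)
  cls <- fixture_codelists(); m <- fixture_mapping()
  r <- render_dialect(pop, "cprd_like", cls, m, seed = 2)
  moved <- unique(pop$moves$person_id)
  ids_per_person <- r$manifest$id_map |>
    dplyr::filter(.data$person_id %in% moved) |>
    dplyr::count(.data$person_id)
  expect_true(all(ids_per_person$n >= 2))
  # disjoint registration windows per person
  regs <- r$manifest$id_map |>
    dplyr::arrange(.data$person_id, .data$reg_start) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::mutate(overlap = .data$reg_start <= dplyr::lag(.data$reg_end)) |>
    dplyr::ungroup()
  expect_false(any(regs$overlap, na.rm = TRUE))
  # per-person dialects keep one id per person
  r2 <- render_dialect(pop, "sail_like", cls, m, seed = 2)
  expect_equal(nrow(r2$bundle$patients), nrow(pop$persons))
})

test_that("every dialect patient id maps to exactly one latent person", {
  for (d in c("cprd_like", "sail_like", "dataloch_like")) {
    r <- cached_render(d)
    map <- dplyr::distinct(r$manifest$id_map, .data$patient_id,
                           .data$person_id)
    expect_equal(anyDuplicated(map$patient_id), 0)
    expect_setequal(unique(map$person_id), r$manifest$persons$person_id)
    # every table references known patient ids
    for (tb in c("clinical_events", "prescriptions", "deaths",
                 "deprivation")) {
      expect_true(all(r$bundle[[tb]]$patient_id %in% map$patient_id))
    }
  }
})

test_that("dispensed-only prescriptions start at the coverage year", {
  r <- cached_render("dataloch_like")
  yrs <- as.integer(format(r$bundle$prescriptions$date, "%Y"))
  expect_true(all(yrs >= 2009))
  # the drop is attributed to a named rule and conserves counts
  log <- render_log(r$bundle)
  dropped <- log$n[log$rule == "dispensed_before_start_year"]
  expect_length(dropped, 1)
  pop <- cached_population()
  expect_equal(nrow(r$bundle$prescriptions),
               nrow(pop$prescriptions) - dropped)
})

test_that("post-2016 combination inhalers render as same-day components in Read dialects", {
  pop <- cached_population()
  cls <- fixture_codelists()
  triple_rx <- pop$prescriptions |> dplyr::filter(.data$category == "triple_therapy")
  expect_gt(nrow(triple_rx), 0)
  sail <- cached_render("sail_like")$bundle
  # no single triple-therapy or LABA-LAMA code appears
  combo_codes <- cls$drugs$code[cls$drugs$category %in%
                                  c("triple_therapy", "LABA_LAMA")]
  expect_false(any(sail$prescriptions$code %in% combo_codes))
  # the component Read codes appear on the prescription day
  one <- triple_rx[1, ]
  comp_codes <- cls$drugs |>
    dplyr::filter(.data$system == "read_v2",
                  .data$category %in% c("LABA", "LAMA", "ICS")) |>
    dplyr::pull("code")
  day <- sail$prescriptions |>
    dplyr::filter(.data$patient_id == one$person_id, .data$date == one$date)
  expect_true(all(comp_codes %in% day$code))
  # whereas the product-coded dialect keeps the single product code
  cprd <- cached_render("cprd_like")$bundle
  triple_dmd <- cls$drugs$code[cls$drugs$category == "triple_therapy" &
                                 cls$drugs$system == "dmd"]
  expect_true(triple_dmd %in% cprd$prescriptions$code)
})

test_that("a configuration gap in the codelists is a named error", {
  pop <- generate_population(population_params(n = 60), seed = 8)
  cls <- fixture_codelists()
  broken <- cls
  broken$copd <- codelist(
    as.data.frame(cls$copd)[cls$copd$system == "medcode", ],
    "diagnosis", "copd")
  if (any(pop$persons$copd)) {
    expect_error(render_dialect(pop, "sail_like", broken, fixture_mapping(),
                                seed = 3),
                 class = "respcohort_configuration_error")
  }
})
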