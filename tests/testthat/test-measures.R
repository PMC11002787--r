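smoke_events <- function(pid, dates, codes) {
  tibble::tibble(patient_id = pid, date = as.Date(dates), code = codes,
                 system = "medcode")
}

test_that("smoking records are cleaned into a consistent longitudinal series", {
  cl <- fixture_codelists()$smoking
  # consistent sequence passes through: never then current
  out <- build_smoking_record(
    smoke_events("p1", c("2010-01-01", "2012-01-01"),
                 c("500001", "500002")), cl)
  expect_equal(out$status, c("never", "current"))
  # a 'never' dated after a current/ex observation is re-coded to 'ex'
  out2 <- build_smoking_record(
    smoke_events("p2", c("2010-01-01", "2014-01-01"),
                 c("500002", "500001")), cl)
  expect_equal(out2$status, c("current", "ex"))
  # same-day conflicts resolve by precedence current > ex > never
  out3 <- build_smoking_record(
    smoke_events("p3", rep("2011-05-01", 2), c("500001", "500002")), cl)
  expect_equal(out3$status, "current")
  # empty input and unmappable codes
  expect_equal(nrow(build_smoking_record(smoke_events(character(),
                                                      character(),
                                                      character()), cl)), 0)
  expect_equal(nrow(build_smoking_record(
    smoke_events("p4", "2010-01-01", "nonsense"), cl)), 0)
})

test_that("cleaned smoking records never contain 'never' after an ever-smoker status", {
  cl <- fixture_codelists()$smoking
  codes <- c("500001", "500002", "500003")
  set.seed(404)
  for (i in 1:25) {
    k <- sample(2:8, 1)
    ev <- smoke_events(paste0("p", i),
                       as.Date("2000-01-01") + sort(sample.int(7000, k)),
                       sample(codes, k, replace = TRUE))
    out <- build_smoking_record(ev, cl)
    ever <- cumsum(out$status %in% c("current", "ex")) > 0
    after_ever <- dplyr::lag(ever, default = FALSE)
    expect_false(any(out$status == "never" & after_ever))
  }
})

bmi_events <- function(pid, date, kind, value) {
  code <- c(bmi = "600001", weight = "600002", height = "600003")[kind]
  tibble::tibble(patient_id = pid, date = as.Date(date), code = unname(code),
                 system = "medcode", value = value)
}

test_that("BMI records keep in-range values and derive from weight and height", {
  cl <- fixture_codelists()$bmi
  ev <- dplyr::bind_rows(
    bmi_events("p1", "2010-01-01", "bmi", 27.5),
    bmi_events("p2", "2011-01-01", "weight", 80),
    bmi_events("p2", "2011-01-01", "height", 1.80),
    bmi_events("p3", "2012-01-01", "bmi", 500))
  out <- build_bmi_record(ev, cl, "cprd_like")
  p1 <- out[out$patient_id == "p1", ]
  expect_equal(p1$bmi, 27.5)
  expect_equal(p1$provenance, "recorded")
  # derived: 80 / 1.80^2 = 24.69 kg/m2
  p2 <- out[out$patient_id == "p2", ]
  expect_equal(p2$bmi, 24.69, tolerance = 1e-3)
  expect_equal(p2$provenance, "derived_from_height_weight")
  # implausible recorded value dropped and logged with a rule name
  expect_false("p3" %in% out$patient_id)
  drops <- measure_drops(out)
  expect_equal(drops$rule[drops$patient_id == "p3"], "bmi_out_of_range")
  # the DataLoch-like dialect derives nothing from weight/height
  out_dl <- build_bmi_record(ev, cl, "dataloch_like")
  expect_false("p2" %in% out_dl$patient_id)
  # a recorded BMI on the same day wins over derivation
  ev2 <- dplyr::bind_rows(
    bmi_events("p4", "2011-01-01", "bmi", 30),
    bmi_events("p4", "2011-01-01", "weight", 80),
    bmi_events("p4", "2010-06-01", "height", 1.80))
  out2 <- build_bmi_record(ev2, cl, "cprd_like")
  expect_equal(nrow(out2), 1)
  expect_equal(out2$provenance, "recorded")
  # weight without any usable height: no derivation
  out3 <- build_bmi_record(bmi_events("p5", "2011-01-01", "weight", 80),
                           cl, "sail_like")
  expect_equal(nrow(out3), 0)
})

test_that("predicted FEV1 matches the reference equations", {
  # male, 50 y, 1.75 m: 4.30*1.75 - 0.029*50 - 2.49 = 3.585 L
  expect_equal(predict_fev1("male", 50, 1.75), 3.585, tolerance = 1e-9)
  # female, 40 y, 1.60 m: 3.95*1.60 - 0.025*40 - 2.60 = 2.720 L
  expect_equal(predict_fev1("female", 40, 1.60), 2.720, tolerance = 1e-9)
  # pure function; unknown sex cannot be predicted
  expect_identical(predict_fev1("male", 50, 1.75),
                   predict_fev1("male", 50, 1.75))
  expect_true(is.na(predict_fev1("unknown", 50, 1.75)))
})

test_that("GOLD stages partition percent-predicted with boundaries upward", {
  expect_equal(gold_stage(85), 1L)
  expect_equal(gold_stage(80), 1L)   # boundary belongs to the higher stage
  expect_equal(gold_stage(79.99), 2L)
  expect_equal(gold_stage(50), 2L)
  expect_equal(gold_stage(40), 3L)
  expect_equal(gold_stage(30), 3L)
  expect_equal(gold_stage(29.9), 4L)
  expect_error(gold_stage(5), class = "respcohort_argument_error")
  expect_error(gold_stage(200), class = "respcohort_argument_error")
  # monotone, gap-free partition of the valid range
  grid <- seq(10, 150, by = 0.25)
  stages <- gold_stage(grid)
  expect_true(all(diff(stages) <= 0))
  expect_setequal(unique(stages), 1:4)
})

spiro_events <- function(pid, date, kind, value = NA_real_) {
  code <- c(fev1 = "700001", pct = "700002", pre = "700003",
            post = "700004")[kind]
  tibble::tibble(patient_id = pid, date = as.Date(date), code = unname(code),
                 system = "medcode", value = value)
}

test_that("spirometry records take the highest same-day FEV1 and derive percent-predicted", {
  cl <- fixture_codelists()$spirometry
  pats <- tibble::tibble(patient_id = c("p1", "p2", "p3", "p4"),
                         sex = c("female", "female", "male", "unknown"),
                         birth_date = as.Date(c("1975-06-01", "1975-06-01",
                                                "1950-01-01", "1960-01-01")))
  hts <- tibble::tibble(patient_id = c("p1", "p2"),
                        date = as.Date("2010-01-01"),
                        height = 1.60)
  ev <- dplyr::bind_rows(
    # p1: two same-day values, highest kept
    spiro_events("p1", "2015-06-01", "fev1", 2.1),
    spiro_events("p1", "2015-06-01", "fev1", 2.3),
    # p2: FEV1 2.0 L at age 40, female, 1.60 m: derived pct = 2.0/2.720*100
    spiro_events("p2", "2015-06-01", "fev1", 2.0),
    # p3: GP-entered percent-predicted on the same day is retained
    spiro_events("p3", "2015-06-01", "fev1", 2.0),
    spiro_events("p3", "2015-06-01", "pct", 68),
    spiro_events("p3", "2015-06-01", "post"),
    # p4: unknown sex, derivation impossible
    spiro_events("p4", "2015-06-01", "fev1", 2.0))
  out <- build_spirometry_record(ev, pats, cl, heights = hts)
  p1 <- out[out$patient_id == "p1", ]
  expect_equal(nrow(p1), 1)
  expect_equal(p1$fev1, 2.3)
  p2 <- out[out$patient_id == "p2", ]
  expect_equal(p2$fev1_pct_predicted, 2.0 / 2.720 * 100, tolerance = 1e-6)
  expect_equal(p2$pct_predicted_provenance, "derived")
  expect_equal(p2$gold_stage, 2L)
  expect_equal(p2$bronchodilation, "unknown")
  p3 <- out[out$patient_id == "p3", ]
  expect_equal(p3$fev1_pct_predicted, 68)
  expect_equal(p3$pct_predicted_provenance, "gp_entered")
  expect_equal(p3$bronchodilation, "post")
  p4 <- out[out$patient_id == "p4", ]
  expect_equal(nrow(p4), 1)
  expect_true(is.na(p4$fev1_pct_predicted))
  # implausible FEV1 dropped and logged
  out2 <- build_spirometry_record(
    spiro_events("p1", "2016-01-01", "fev1", 12), pats, cl)
  expect_equal(nrow(out2), 0)
  expect_equal(measure_drops(out2)$rule, "fev1_out_of_range")
})

test_that("derived percent-predicted is self-consistent on synthetic records", {
  r <- cached_render("cprd_like", n = 2000, seed = 55, render_seed = 56)
  cls <- fixture_codelists()
  pats <- r$bundle$patients |>
    dplyr::transmute(.data$patient_id, .data$sex,
                     birth_date = impute_birth_date(.data$birth, "year"))
  hts <- r$bundle$clinical_events |>
    dplyr::inner_join(dplyr::filter(cls$bmi, .data$category == "height"),
                      by = c("code", "system")) |>
    dplyr::transmute(.data$patient_id, .data$date, height = .data$value)
  rec <- build_spirometry_record(r$bundle$clinical_events, pats,
                                 cls$spirometry, heights = hts)
  derived <- rec |>
    dplyr::filter(.data$pct_predicted_provenance == "derived")
  expect_gt(nrow(derived), 0)
  check <- derived |>
    dplyr::left_join(pats, by = "patient_id") |>
    dplyr::left_join(hts |> dplyr::rename(height_date = "date"),
                     by = "patient_id", relationship = "many-to-many") |>
    dplyr::filter(.data$height_date <= .data$date) |>
    dplyr::group_by(.data$patient_id, .data$date) |>
    dplyr::slice_max(.data$height_date, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      age = as.numeric(.data$date - .data$birth_date) / 365.25,
      recomputed = .data$fev1 /
        predict_fev1(.data$sex, .data$age, .data$height) * 100)
  expect_true(all(abs(check$recomputed - check$fev1_pct_predicted) < 0.01))
  # every emitted value is inside the configured plausible ranges
  cfg <- measure_config()
  expect_true(all(rec$fev1 >= cfg$fev1_range[1] &
                    rec$fev1 <= cfg$fev1_range[2]))
  ok_pct <- !is.na(rec$fev1_pct_predicted)
  expect_true(all(rec$fev1_pct_predicted[ok_pct] >=
                    cfg$pct_predicted_range[1] &
                    rec$fev1_pct_predicted[ok_pct] <=
                    cfg$pct_predicted_range[2]))
})

test_that("latest_in_window returns the most recent in-window observation", {
  rec <- tibble::tibble(patient_id = "p1",
                        date = as.Date(c("2013-05-01", "2016-05-01",
                                         "2018-05-01")),
                        value = 1:3)
  out <- latest_in_window(rec, as.Date("2019-12-31"),
                          as.Date("2015-01-01"))
  expect_equal(out$date, as.Date("2018-05-01"))
  # nothing in window
  out2 <- latest_in_window(rec[1, ], as.Date("2019-12-31"),
                           as.Date("2015-01-01"))
  expect_equal(nrow(out2), 0)
  # both bounds inclusive
  edge <- tibble::tibble(patient_id = "p1", date = as.Date("2019-12-31"),
                         value = 9)
  expect_equal(nrow(latest_in_window(edge, as.Date("2019-12-31"),
                                     as.Date("2015-01-01"))), 1)
  expect_error(latest_in_window(rec, as.Date("2015-01-01"),
                                as.Date("2019-12-31")),
               class = "respcohort_argument_error")
})
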