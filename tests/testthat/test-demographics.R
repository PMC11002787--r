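test_that("birth dates impute per the dialect rules", {
  expect_equal(impute_birth_date("1980", "year"), as.Date("1980-07-01"))
  # 1975-03-12 is a Wednesday in ISO week 1975-W11; its Monday is 03-10
  expect_equal(format(as.Date("1975-03-12"), "%u"), "3")
  expect_equal(impute_birth_date("1975-W11", "week"), as.Date("1975-03-10"))
  expect_equal(impute_birth_date("1990-05", "month"), as.Date("1990-05-01"))
  expect_equal(impute_birth_date("1990-05-21", "exact"),
               as.Date("1990-05-21"))
  expect_error(impute_birth_date("1980-05", "year"),
               class = "respcohort_argument_error")
})

test_that("birth imputation error is bounded by the granularity", {
  set.seed(11)
  truth <- as.Date("1925-01-01") + sample.int(30000, 1000)
  # year: 1st July of the year
  err_y <- abs(as.numeric(impute_birth_date(format(truth, "%Y"), "year") -
                            truth))
  expect_true(all(err_y <= 366))
  # week: the ISO week's Monday is at most 6 days before the true date
  imp_w <- impute_birth_date(vapply(truth, function(d)
    format(d, "%G-W%V"), character(1)), "week")
  err_w <- as.numeric(truth - imp_w)
  expect_true(all(err_w >= 0 & err_w <= 6))
  # month: 1st of the month is at most 30 days before the true date
  err_m <- as.numeric(truth - impute_birth_date(format(truth, "%Y-%m"),
                                                "month"))
  expect_true(all(err_m >= 0 & err_m <= 30))
})

test_that("death dates resolve by dialect precedence", {
  deaths <- tibble::tibble(
    patient_id = c("a", "b", "c", "d"),
    primary_death_date = as.Date(c("2018-05-01", NA, NA, NA)),
    primary_registration_date = as.Date(c(NA, "2018-05-20", NA, NA)),
    internal_death_date = as.Date(c(NA, NA, "2021-06-01", "2020-01-01")))
  out <- resolve_death_date(deaths, "cprd_like")
  # direct primary source
  expect_equal(out$death_date[out$patient_id == "a"], as.Date("2018-05-01"))
  # register record with missing death date: registration date used
  expect_equal(out$death_date[out$patient_id == "b"], as.Date("2018-05-20"))
  # internal date after register coverage end (2021-03-31) is used
  expect_equal(out$death_date[out$patient_id == "c"], as.Date("2021-06-01"))
  # internal date inside coverage with no register record: not trusted
  expect_true(is.na(out$death_date[out$patient_id == "d"]))

  out_dl <- resolve_death_date(deaths, "dataloch_like")
  expect_equal(out_dl$death_date[out_dl$patient_id == "d"],
               as.Date("2020-01-01"))
  expect_true(is.na(out_dl$death_date[out_dl$patient_id == "a"]))

  out_sail <- resolve_death_date(deaths, "sail_like")
  expect_equal(out_sail$death_date[out_sail$patient_id == "a"],
               as.Date("2018-05-01"))

  # death before imputed birth is flagged but retained
  births <- tibble::tibble(patient_id = c("a", "b", "c", "d"),
                           birth_date = as.Date(c("2019-07-01", "1950-01-01",
                                                  "1950-01-01", "1950-01-01")))
  expect_warning(out_fl <- resolve_death_date(deaths, "cprd_like", births))
  expect_true(out_fl$death_before_birth[out_fl$patient_id == "a"])
  expect_equal(out_fl$death_date[out_fl$patient_id == "a"],
               as.Date("2018-05-01"))
})

test_that("deprivation harmonisation reverses opposite-numbered scales", {
  expect_equal(as.character(harmonise_deprivation(1, "imd_england_2019")),
               "least deprived")
  expect_equal(as.character(harmonise_deprivation(1, "wimd_2019")),
               "most deprived")
  expect_equal(as.character(harmonise_deprivation(5, "simd_2020v2")),
               "least deprived")
  # all 15 (scheme, quintile) pairs; bijection per scheme and order
  # reversal between IMD and the Welsh/Scottish schemes
  for (scheme in c("imd_england_2019", "wimd_2019", "simd_2020v2")) {
    labs <- harmonise_deprivation(1:5, scheme)
    expect_setequal(as.character(labs), deprivation_labels())
  }
  for (q in 1:5) {
    expect_equal(harmonise_deprivation(q, "wimd_2019"),
                 harmonise_deprivation(6 - q, "imd_england_2019"))
    expect_equal(harmonise_deprivation(q, "simd_2020v2"),
                 harmonise_deprivation(q, "wimd_2019"))
  }
  expect_error(harmonise_deprivation(0, "wimd_2019"),
               class = "respcohort_argument_error")
  expect_error(harmonise_deprivation(6, "imd_england_2019"),
               class = "respcohort_argument_error")
  expect_error(harmonise_deprivation(3, "townsend"),
               class = "respcohort_argument_error")
})

test_that("ethnicity prefers GP codes and resolves conflicts by mode", {
  cl <- fixture_codelists()$ethnicity
  gp1 <- tibble::tibble(patient_id = "p1", date = as.Date("2010-01-01"),
                        code = "400003", system = "medcode")
  out <- derive_ethnicity(gp1, NULL, cl)
  expect_equal(out$ethnicity_broad, "Asian")
  expect_equal(out$ethnicity_ew2011, "Indian")
  expect_equal(out$ethnicity_source, "gp")

  # hospital used only when GP yields nothing
  hosp <- tibble::tibble(patient_id = "p2", date = as.Date("2012-01-01"),
                         code = "400006", system = "medcode")
  out2 <- derive_ethnicity(NULL, hosp, cl)
  expect_equal(out2$ethnicity_broad, "Black")
  expect_equal(out2$ethnicity_source, "hospital")

  # GP presence suppresses hospital even when hospital disagrees
  both <- derive_ethnicity(gp1, hosp |> dplyr::mutate(patient_id = "p1"), cl)
  expect_equal(both$ethnicity_broad, "Asian")
  expect_equal(both$ethnicity_source, "gp")

  # mode wins; ties broken by the most recent record
  gp_mode <- tibble::tibble(
    patient_id = "p3",
    date = as.Date(c("2010-01-01", "2011-01-01", "2012-01-01")),
    code = c("400001", "400001", "400006"), system = "medcode")
  expect_equal(derive_ethnicity(gp_mode, NULL, cl)$ethnicity_broad, "White")
  gp_tie <- tibble::tibble(
    patient_id = "p4", date = as.Date(c("2010-01-01", "2015-06-01")),
    code = c("400001", "400006"), system = "medcode")
  expect_equal(derive_ethnicity(gp_tie, NULL, cl)$ethnicity_broad, "Black")
  # no codes anywhere: patient simply absent from the result
  expect_equal(nrow(derive_ethnicity(NULL, NULL, cl)), 0)
})
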