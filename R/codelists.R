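#' Recognised clinical coding systems
#'
#' The terminology dialects that codelists, mapping tables and
#' event/prescription tables may use: CPRD Aurum medcodes, SNOMED-CT concept
#' IDs, Read V2 codes, dm+d product identifiers, full BNF codes and ATC codes.
#'
#' @return Character vector of system identifiers.
#' @export
code_systems <- function() {
  c("medcode", "snomed_concept", "read_v2", "dmd", "bnf", "atc")
}

#' Recognised codelist purposes
#' @return Character vector of purpose identifiers.
#' @export
codelist_purposes <- function() {
  c("diagnosis", "medication", "ethnicity", "smoking", "bmi", "spirometry",
    "ild_subtype")
}

parse_codelist_bool <- function(x, col) {
  if (is.logical(x)) return(x)
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(lx))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  if (any(is.na(out) & !is.na(lx))) {
    abort(paste0("column '", col, "' contains values that are not true/false"),
          class = "respcohort_validation_error")
  }
  out
}

new_codelist <- function(entries, name, purpose) {
  structure(entries, class = c("codelist", class(tibble())),
            codelist_name = name, purpose = purpose)
}

#' Load and validate a codelist from CSV
#'
#' A codelist is a curated set of terminology codes that defines a disease,
#' clinical variable or drug class for phenotyping. The file must be a UTF-8
#' CSV with a header row and at least the columns `code`, `system`,
#' `description`, `incident`, `prevalent`, `category` (booleans written as
#' `true`/`false`). Extra columns (for example the per-scheme categorisations
#' carried by ethnicity codelists) are preserved.
#'
#' Diagnosis codelists must flag every entry as incident and/or prevalent:
#' codes that can mark a new diagnosis are classified as both incident and
#' prevalent, while disease-management codes (annual reviews, care plans) are
#' prevalent only. Category codelists (smoking, BMI, ethnicity, drugs) may
#' leave both flags false and use `category` to label each code.
#'
#' @param path Path to the CSV file.
#' @param purpose One of [codelist_purposes()].
#' @param name Optional codelist name; defaults to the file stem.
#' @return A `codelist`: a tibble of entries with attributes `codelist_name`
#'   and `purpose`.
#' @examples
#' cl <- load_codelist(respcohort_example("codelists/asthma.csv"), "diagnosis")
#' nrow(cl)
#' @export
load_codelist <- function(path, purpose, name = NULL) {
  purpose <- match.arg(purpose, codelist_purposes())
  if (!file.exists(path)) {
    abort(paste0("codelist file not found: ", path),
          class = "respcohort_argument_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_codelist(raw, purpose, name %||% sub("\\.[^.]+$", "", basename(path)))
}

#' Construct a codelist from a data frame
#'
#' In-memory counterpart of [load_codelist()], mostly useful in tests and
#' when assembling codelists programmatically.
#'
#' @param entries Data frame with the codelist schema.
#' @param purpose One of [codelist_purposes()].
#' @param name Codelist name.
#' @return A validated `codelist`.
#' @export
codelist <- function(entries, purpose, name = "codelist") {
  purpose <- match.arg(purpose, codelist_purposes())
  validate_codelist(entries, purpose, name)
}

validate_codelist <- function(raw, purpose, name) {
  assert_columns(raw, c("code", "system", "description", "incident",
                        "prevalent", "category"),
                 what = paste0("codelist '", name, "'"))
  entries <- as_tibble(raw) |>
    mutate(code = as.character(.data$code),
           system = as.character(.data$system),
           incident = parse_codelist_bool(.data$incident, "incident"),
           prevalent = parse_codelist_bool(.data$prevalent, "prevalent"))
  if (nrow(entries) == 0) {
    abort(paste0("codelist '", name, "' is empty"),
          class = "respcohort_validation_error")
  }
  if (any(is.na(entries$code) | entries$code == "")) {
    abort(paste0("codelist '", name, "' contains empty codes"),
          class = "respcohort_validation_error")
  }
  bad_sys <- setdiff(unique(entries$system), code_systems())
  if (length(bad_sys) > 0) {
    abort(paste0("codelist '", name, "' uses unknown coding system(s): ",
                 paste(bad_sys, collapse = ", ")),
          class = "respcohort_validation_error")
  }
  dup <- entries |> count(.data$code, .data$system) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("codelist '", name, "' has duplicate (code, system) entries: ",
                 paste(paste0(dup$code, "/", dup$system), collapse = ", ")),
          class = "respcohort_validation_error")
  }
  entries$incident[is.na(entries$incident)] <- FALSE
  entries$prevalent[is.na(entries$prevalent)] <- FALSE
  if (purpose == "diagnosis" && any(!entries$incident & !entries$prevalent)) {
    bad <- entries$code[!entries$incident & !entries$prevalent]
    abort(paste0("diagnosis codelist '", name, "' has entries that are ",
                 "neither incident nor prevalent: ",
                 paste(bad, collapse = ", ")),
          class = "respcohort_validation_error")
  }
  new_codelist(entries, name, purpose)
}

#' @export
print.codelist <- function(x, ...) {
  cat("<codelist '", attr(x, "codelist_name"), "', purpose: ",
      attr(x, "purpose"), ", ", nrow(x), " entries>\n", sep = "")
  NextMethod()
}

codelist_purpose <- function(codelist) attr(codelist, "purpose")

#' Load a cross-terminology code mapping from CSV
#'
#' The mapping is a relation: one-to-many translations are allowed in both
#' directions and unmapped codes are simply absent. Columns:
#' `source_system`, `source_code`, `target_system`, `target_code`.
#'
#' @param path Path to the CSV file.
#' @return A `code_mapping` tibble.
#' @export
load_code_mapping <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("mapping file not found: ", path),
          class = "respcohort_argument_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  code_mapping(raw)
}

#' Construct a code mapping from a data frame
#' @param rows Data frame with columns `source_system`, `source_code`,
#'   `target_system`, `target_code`.
#' @return A `code_mapping` tibble.
#' @export
code_mapping <- function(rows) {
  assert_columns(rows, c("source_system", "source_code", "target_system",
                         "target_code"), what = "code mapping")
  rows <- as_tibble(rows) |>
    mutate(across(everything(), as.character)) |>
    distinct()
  bad <- setdiff(unique(c(rows$source_system, rows$target_system)),
                 code_systems())
  if (length(bad) > 0) {
    abort(paste0("code mapping uses unknown coding system(s): ",
                 paste(bad, collapse = ", ")),
          class = "respcohort_validation_error")
  }
  structure(rows, class = c("code_mapping", class(tibble())))
}

#' Translate a code between coding systems
#'
#' Returns every target code reachable in a single mapping hop. Transitive
#' chains — for example dm+d to ATC to Read V2, the route used to attach Read
#' codes to product-coded drug lists — are performed by composing two calls.
#' The result may be empty: newer drugs (post-2016 combination inhalers)
#' typically have no ATC-to-Read row.
#'
#' @param code Code string to translate.
#' @param from_system,to_system Coding systems (see [code_systems()]); must
#'   differ.
#' @param mapping A `code_mapping`.
#' @return Character vector (possibly empty) of target codes.
#' @examples
#' m <- code_mapping(data.frame(
#'   source_system = "medcode", source_code = "m001",
#'   target_system = "snomed_concept", target_code = "195967001"))
#' translate_code("m001", "medcode", "snomed_concept", m)
#' @export
translate_code <- function(code, from_system, to_system, mapping) {
  from_system <- match.arg(from_system, code_systems())
  to_system <- match.arg(to_system, code_systems())
  if (identical(from_system, to_system)) {
    abort("from_system and to_system must differ",
          class = "respcohort_argument_error")
  }
  hits <- mapping$target_code[mapping$source_system == from_system &
                                mapping$source_code == as.character(code) &
                                mapping$target_system == to_system]
  sort(unique(hits))
}

# Vectorised translation used internally for joins: returns the mapping rows
# restricted to a (from, to) system pair.
mapping_edges <- function(mapping, from_system, to_system) {
  mapping |>
    filter(.data$source_system == from_system,
           .data$target_system == to_system) |>
    select(source_code = "source_code", target_code = "target_code") |>
    distinct()
}

#' Classify an event code against a diagnosis codelist
#'
#' Looks up `(code, system)` in a diagnosis codelist and reports whether the
#' code can mark a new diagnosis (`incident_and_prevalent`), only indicates
#' ongoing disease management (`prevalent_only`), or is not in the list.
#' Vectorised over `code` and `system`.
#'
#' @param code Character vector of codes.
#' @param system Coding system(s), recycled against `code`.
#' @param codelist A diagnosis `codelist`.
#' @return Character vector with values `incident_and_prevalent`,
#'   `prevalent_only` or `not_in_list`.
#' @export
classify_event_code <- function(code, system, codelist) {
  if (!identical(codelist_purpose(codelist), "diagnosis")) {
    abort("classify_event_code() requires a diagnosis codelist",
          class = "respcohort_argument_error")
  }
  key <- tibble(code = as.character(code), system = as.character(system))
  lookup <- codelist |>
    mutate(classification = if_else(.data$incident,
                                    "incident_and_prevalent",
                                    "prevalent_only")) |>
    select("code", "system", "classification")
  out <- key |> left_join(lookup, by = c("code", "system"))
  tidyr::replace_na(out$classification, "not_in_list")
}

#' Path to a packaged example/fixture file
#' @param file Relative path under the package's `extdata` directory; empty
#'   to list available files.
#' @return File path (or directory listing).
#' @export
respcohort_example <- function(file = "") {
  if (identical(file, "")) {
    return(dir(system.file("extdata", package = "respcohort"), recursive = TRUE))
  }
  path <- system.file("extdata", file, package = "respcohort")
  if (path == "") {
    abort(paste0("no packaged file '", file, "'"),
          class = "respcohort_argument_error")
  }
  path
}

#' Load the packaged synthetic codelists
#'
#' Returns the small synthetic code vocabulary shipped with the package: one
#' codelist per disease (asthma, COPD, ILD — the ILD list carries subtype
#' categories), plus ethnicity, smoking, BMI, spirometry and drug-category
#' lists. These are desk-scale stand-ins with the same schema as real
#' published codelists; real dictionary releases can be dropped in through
#' [load_codelist()].
#'
#' @return Named list of `codelist` objects.
#' @export
synthetic_codelists <- function() {
  purposes <- c(asthma = "diagnosis", copd = "diagnosis", ild = "diagnosis",
                ethnicity = "ethnicity", smoking = "smoking", bmi = "bmi",
                spirometry = "spirometry", drugs = "medication")
  out <- lapply(names(purposes), function(nm) {
    load_codelist(respcohort_example(file.path("codelists", paste0(nm, ".csv"))),
                  purpose = purposes[[nm]], name = nm)
  })
  setNames(out, names(purposes))
}

#' Load the packaged synthetic code mapping
#'
#' Cross-terminology rows for the synthetic vocabulary: medcode to SNOMED-CT
#' and Read V2, dm+d to BNF and ATC, and ATC to Read V2 (deliberately absent
#' for post-2016 combination inhalers, which therefore have no Read
#' translation).
#'
#' @return A `code_mapping`.
#' @export
synthetic_code_mapping <- function() {
  load_code_mapping(respcohort_example("mapping.csv"))
}
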