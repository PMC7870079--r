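#' Claims bundle data model
#'
#' A claims bundle is the package's in-memory representation of a hospital
#' claims extract: six tibbles with foreign keys into `patients` and
#' `hospitals`. On disk a bundle is a directory of six UTF-8 CSV files with
#' ISO-8601 dates: `patients.csv`, `hospitals.csv`, `diagnoses.csv`,
#' `prescriptions.csv`, `procedures.csv`, `assessments.csv`.
#'
#' Schemas (column order is stable):
#' * `patients`: `patient_id`, `sex` (`male`/`female`), `birth_year`,
#'   `hospital_id`, `data_end` (final date of data provided by the hospital;
#'   the per-patient follow-up horizon used by the 60-day rules).
#' * `hospitals`: `hospital_id`, `bed_class` (`<200`, `200-499`, `>=500`),
#'   `designated_cancer` (logical).
#' * `diagnoses`: `patient_id`, `date`, `icd10`, `confirmed` (logical;
#'   rows with `confirmed = FALSE` are rule-out diagnoses and are ignored by
#'   all downstream logic).
#' * `prescriptions`: `patient_id`, `date`, `drug_id`, `dose` (optional,
#'   consistent units per drug), `route` (`oral`/`intravenous`),
#'   `days_supplied` (optional integer, oral drugs).
#' * `procedures`: `patient_id`, `date`, `kind` (`colorectal_resection`,
#'   `proteinuria_qualitative`, `proteinuria_quantitative`).
#' * `assessments`: `patient_id`, `date`, `kind` (`bmi`/`barthel`), `value`
#'   (BMI in kg/m2, or Barthel total 0-100), `items` (for `barthel` rows an
#'   optional semicolon-joined vector of the 10 item scores summing to
#'   `value`).
#'
#' @name claims_bundle_format
NULL

BUNDLE_TABLES <- c("patients", "hospitals", "diagnoses", "prescriptions",
                   "procedures", "assessments")

BUNDLE_COLUMNS <- list(
  patients = c("patient_id", "sex", "birth_year", "hospital_id", "data_end"),
  hospitals = c("hospital_id", "bed_class", "designated_cancer"),
  diagnoses = c("patient_id", "date", "icd10", "confirmed"),
  prescriptions = c("patient_id", "date", "drug_id", "dose", "route", "days_supplied"),
  procedures = c("patient_id", "date", "kind"),
  assessments = c("patient_id", "date", "kind", "value", "items")
)

# Standard Barthel ADL item maxima (feeding, bathing, grooming, dressing,
# bowels, bladder, toilet use, transfers, mobility, stairs); total 100.
BARTHEL_ITEM_MAX <- c(10, 5, 5, 10, 10, 10, 10, 15, 15, 10)

empty_bundle_table <- function(name) {
  cols <- BUNDLE_COLUMNS[[name]]
  proto <- list(
    patient_id = character(), hospital_id = character(),
    sex = character(), birth_year = integer(), data_end = as.Date(character()),
    bed_class = character(), designated_cancer = logical(),
    date = as.Date(character()), icd10 = character(), confirmed = logical(),
    drug_id = character(), dose = numeric(), route = character(),
    days_supplied = integer(), kind = character(), value = numeric(),
    items = character()
  )
  tibble::as_tibble(proto[cols])
}

#' Construct and validate a claims bundle
#'
#' Missing event tables default to empty. Event tables are sorted by
#' `(patient_id, date)` and the full invariant set is checked: unique ids,
#' resolvable foreign keys, `data_end` at or after every event date, ICD-10
#' code shape, positive doses, closed `kind` sets, BMI and Barthel ranges.
#'
#' @param patients,hospitals,diagnoses,prescriptions,procedures,assessments
#'   tibbles per [claims_bundle_format].
#' @param validate run validation (default TRUE).
#' @return an object of class `claims_bundle` (a named list of six tibbles).
#' @export
claims_bundle <- function(patients, hospitals,
                          diagnoses = NULL, prescriptions = NULL,
                          procedures = NULL, assessments = NULL,
                          validate = TRUE) {
  bundle <- list(
    patients = tibble::as_tibble(patients),
    hospitals = tibble::as_tibble(hospitals),
    diagnoses = tibble::as_tibble(diagnoses %||% empty_bundle_table("diagnoses")),
    prescriptions = tibble::as_tibble(prescriptions %||% empty_bundle_table("prescriptions")),
    procedures = tibble::as_tibble(procedures %||% empty_bundle_table("procedures")),
    assessments = tibble::as_tibble(assessments %||% empty_bundle_table("assessments"))
  )
  for (nm in BUNDLE_TABLES) {
    missing <- setdiff(BUNDLE_COLUMNS[[nm]], names(bundle[[nm]]))
    if (length(missing) > 0) {
      # optional columns may be absent on input; fill with NA
      for (col in missing) {
        if (col %in% c("dose", "value")) bundle[[nm]][[col]] <- NA_real_
        else if (col == "days_supplied") bundle[[nm]][[col]] <- NA_integer_
        else if (col == "items") bundle[[nm]][[col]] <- NA_character_
        else abort(paste0("table '", nm, "' lacks required column '", col, "'"))
      }
    }
    bundle[[nm]] <- bundle[[nm]][, BUNDLE_COLUMNS[[nm]]]
    if ("date" %in% names(bundle[[nm]])) {
      bundle[[nm]] <- dplyr::arrange(bundle[[nm]], .data$patient_id, .data$date)
    }
  }
  class(bundle) <- "claims_bundle"
  if (validate) validate_bundle(bundle)
  bundle
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  for (nm in BUNDLE_TABLES) {
    cat(sprintf("  %-13s %6d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Validate a claims bundle
#'
#' Every violated invariant raises an error naming the table and the
#' offending row identifiers; validation never silently drops rows.
#'
#' @param bundle a `claims_bundle`.
#' @return the bundle, invisibly, if valid.
#' @export
validate_bundle <- function(bundle) {
  p <- bundle$patients
  fail <- function(...) abort(paste0("invalid bundle: ", ...))
  if (anyDuplicated(p$patient_id)) {
    fail("duplicate patient_id: ",
         paste(unique(p$patient_id[duplicated(p$patient_id)]), collapse = ", "))
  }
  if (anyDuplicated(bundle$hospitals$hospital_id)) fail("duplicate hospital_id")
  if (!all(p$sex %in% c("male", "female"))) fail("patients$sex outside {male, female}")
  if (anyNA(p$data_end)) fail("patients$data_end has missing dates")
  bad_hosp <- setdiff(p$hospital_id, bundle$hospitals$hospital_id)
  if (length(bad_hosp) > 0) {
    fail("patients reference unknown hospital_id: ", paste(bad_hosp, collapse = ", "))
  }
  if (!all(bundle$hospitals$bed_class %in% c("<200", "200-499", ">=500"))) {
    fail("hospitals$bed_class outside {<200, 200-499, >=500}")
  }

  data_end <- setNames(p$data_end, p$patient_id)
  for (nm in c("diagnoses", "prescriptions", "procedures", "assessments")) {
    tbl <- bundle[[nm]]
    if (nrow(tbl) == 0) next
    unknown <- setdiff(tbl$patient_id, p$patient_id)
    if (length(unknown) > 0) {
      fail(nm, " reference unknown patient_id: ", paste(unknown, collapse = ", "))
    }
    if (anyNA(tbl$date)) fail(nm, " has missing/unparseable dates")
    late <- tbl$date > data_end[tbl$patient_id]
    if (any(late)) {
      fail(nm, " has events after the patient's data_end (patient ",
           paste(unique(tbl$patient_id[late]), collapse = ", "), ")")
    }
  }

  d <- bundle$diagnoses
  if (nrow(d) > 0) {
    ok <- grepl("^[A-Z][0-9]{2}(\\.[0-9]{1,2})?$", d$icd10)
    if (!all(ok)) fail("malformed ICD-10 codes: ", paste(unique(d$icd10[!ok]), collapse = ", "))
    if (anyNA(d$confirmed)) fail("diagnoses$confirmed has missing values")
  }

  rx <- bundle$prescriptions
  if (nrow(rx) > 0) {
    if (!all(rx$route %in% c("oral", "intravenous"))) {
      fail("prescriptions$route outside {oral, intravenous}")
    }
    if (any(!is.na(rx$dose) & rx$dose <= 0)) fail("prescriptions$dose must be > 0 when present")
  }

  pr <- bundle$procedures
  if (nrow(pr) > 0 &&
      !all(pr$kind %in% c("colorectal_resection", "proteinuria_qualitative",
                          "proteinuria_quantitative"))) {
    fail("procedures$kind outside the closed set")
  }

  a <- bundle$assessments
  if (nrow(a) > 0) {
    if (!all(a$kind %in% c("bmi", "barthel"))) fail("assessments$kind outside {bmi, barthel}")
    bmi <- a$value[a$kind == "bmi"]
    if (any(is.na(bmi)) || any(bmi <= 5 | bmi >= 80)) fail("BMI values must lie in (5, 80)")
    bar <- a[a$kind == "barthel", ]
    if (nrow(bar) > 0) {
      if (any(is.na(bar$value)) || any(bar$value < 0 | bar$value > 100)) {
        fail("Barthel totals must lie in [0, 100]")
      }
      has_items <- !is.na(bar$items) & nzchar(bar$items)
      if (any(has_items)) {
        ok <- vapply(which(has_items), function(i) {
          items <- suppressWarnings(as.numeric(strsplit(bar$items[i], ";")[[1]]))
          length(items) == 10 && !anyNA(items) &&
            all(items >= 0 & items <= BARTHEL_ITEM_MAX) &&
            sum(items) == bar$value[i]
        }, logical(1))
        if (!all(ok)) fail("Barthel item vectors must be 10 in-range scores summing to value")
      }
    }
  }
  invisible(bundle)
}

#' Read a claims bundle from a directory of CSV files
#'
#' Rows whose `date` fails ISO-8601 parsing are rejected and their count is
#' reported via a warning; all other validation failures are fatal.
#'
#' @param directory_path directory containing the six schema files.
#' @return a validated `claims_bundle`.
#' @export
read_bundle <- function(directory_path) {
  paths <- file.path(directory_path, paste0(BUNDLE_TABLES, ".csv"))
  missing <- !file.exists(paths)
  if (any(missing)) {
    abort(paste0("missing bundle file(s): ", paste(basename(paths[missing]), collapse = ", ")))
  }
  tables <- purrr::map(setNames(paths, BUNDLE_TABLES), function(path) {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  })
  tables <- purrr::imap(tables, function(tbl, nm) {
    if (nrow(tbl) == 0) return(empty_bundle_table(nm))
    for (col in intersect(c("date", "data_end"), names(tbl))) {
      parsed <- as_iso_date(tbl[[col]])
      bad <- is.na(parsed) & !is.na(tbl[[col]])
      if (col == "date" && any(bad)) {
        warn(paste0(nm, ": rejected ", sum(bad), " row(s) with unparseable dates"))
        tbl <- tbl[!bad, , drop = FALSE]
        parsed <- parsed[!bad]
      } else if (any(bad)) {
        abort(paste0(nm, "$", col, " has unparseable dates"))
      }
      tbl[[col]] <- parsed
    }
    for (col in intersect(c("birth_year", "days_supplied"), names(tbl))) {
      tbl[[col]] <- as.integer(tbl[[col]])
    }
    for (col in intersect(c("dose", "value"), names(tbl))) tbl[[col]] <- as.numeric(tbl[[col]])
    for (col in intersect(c("confirmed", "designated_cancer"), names(tbl))) {
      tbl[[col]] <- as.logical(tbl[[col]])
    }
    tbl
  })
  claims_bundle(tables$patients, tables$hospitals, tables$diagnoses,
                tables$prescriptions, tables$procedures, tables$assessments)
}

#' Write a claims bundle to a directory of CSV files
#'
#' Emits the six schema files with stable column order and ISO-8601 dates;
#' `read_bundle()` on the result reproduces the bundle exactly.
#'
#' @param bundle a validated `claims_bundle`.
#' @param directory_path output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_bundle <- function(bundle, directory_path) {
  validate_bundle(bundle)
  if (!dir.exists(directory_path)) {
    ok <- dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory: ", directory_path))
  }
  for (nm in BUNDLE_TABLES) {
    out <- bundle[[nm]][, BUNDLE_COLUMNS[[nm]]]
    readr::write_csv(out, file.path(directory_path, paste0(nm, ".csv")), progress = FALSE)
  }
  invisible(directory_path)
}
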