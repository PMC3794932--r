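#' Assemble a validated EHR cohort
#'
#' Bundles the four flat tables the method consumes — prescriptions,
#' laboratory results, admissions, and diagnoses — into a single validated
#' cohort object. Rows that violate the domain invariants (a prescription
#' dated outside its admission, a lab row whose value is neither numeric nor
#' a positive/negative token, an unresolvable `admission_id`, ...) are
#' removed and reported, never silently dropped.
#'
#' @param prescriptions tibble with columns `patient_id`, `admission_id`,
#'   `drug_code`, `prescriber_id`, `admin_date` (Date).
#' @param labs tibble with columns `patient_id`, `admission_id`, `analyte`,
#'   `value` (character; numeric text for quantitative analytes, or
#'   `"positive"`/`"negative"` for nominal ones), `order_date`, `result_date`
#'   (Date; `order_date` may be `NA`).
#' @param admissions tibble with columns `patient_id`, `admission_id`,
#'   `admit_date`, `discharge_date` (Date).
#' @param diagnoses tibble with columns `patient_id`, `icd10_code`.
#' @return An object of class `pace_cohort`: a list of the four validated
#'   tibbles, with a `rejections` attribute tabulating every rejected row
#'   (table, row number in the input, reason).
#' @export
cohort_data <- function(prescriptions = NULL, labs = NULL, admissions = NULL,
                        diagnoses = NULL) {
  cohort <- list(
    prescriptions = as_tibble(prescriptions %||% empty_prescriptions()),
    labs          = as_tibble(labs %||% empty_labs()),
    admissions    = as_tibble(admissions %||% empty_admissions()),
    diagnoses     = as_tibble(diagnoses %||% empty_diagnoses())
  )
  validate_cohort(structure(cohort, class = "pace_cohort"))
}

empty_prescriptions <- function() {
  tibble(patient_id = character(), admission_id = character(),
         drug_code = character(), prescriber_id = character(),
         admin_date = as.Date(character()))
}
empty_labs <- function() {
  tibble(patient_id = character(), admission_id = character(),
         analyte = character(), value = character(),
         order_date = as.Date(character()), result_date = as.Date(character()))
}
empty_admissions <- function() {
  tibble(patient_id = character(), admission_id = character(),
         admit_date = as.Date(character()), discharge_date = as.Date(character()))
}
empty_diagnoses <- function() {
  tibble(patient_id = character(), icd10_code = character())
}

# letter + two digits, optional subdivision after a dot (covers the ".x"
# wildcard notation used in code lists)
ICD10_RE <- "^[A-Za-z][0-9]{2}(\\.[0-9A-Za-z]{1,4})?$"

#' Validate a cohort's invariants
#'
#' Re-checks every invariant on an assembled cohort: admission date spans and
#' uniqueness, referential integrity of prescriptions and labs, lab value
#' typing (numeric, or a normalized positive/negative token), `order_date <=
#' result_date`, and the lexical shape of ICD-10 codes. Violating rows are
#' removed; the full per-row report is attached as the `rejections`
#' attribute and summarised with a message when non-empty.
#'
#' @param cohort a `pace_cohort` or a plain list with the four tables.
#' @param quiet suppress the rejection-summary message.
#' @return The cleaned `pace_cohort`.
#' @export
validate_cohort <- function(cohort, quiet = FALSE) {
  rej <- list()
  note <- function(table, row, reason) {
    tibble(table = table, row = row, reason = reason)
  }

  adm <- as_tibble(cohort$admissions)
  require_columns(adm, c("patient_id", "admission_id", "admit_date",
                         "discharge_date"), "admissions")
  bad_span <- which(is.na(adm$admit_date) | is.na(adm$discharge_date) |
                      adm$admit_date > adm$discharge_date)
  dup <- which(duplicated(adm$admission_id))
  if (length(bad_span)) rej[["adm_span"]] <-
    note("admissions", bad_span, "admit_date after discharge_date or missing")
  if (length(dup)) rej[["adm_dup"]] <-
    note("admissions", dup, "duplicated admission_id")
  drop <- union(bad_span, dup)
  if (length(drop)) adm <- adm[-drop, ]

  rx <- as_tibble(cohort$prescriptions)
  require_columns(rx, c("patient_id", "admission_id", "drug_code",
                        "admin_date"), "prescriptions")
  if (!"prescriber_id" %in% names(rx)) rx$prescriber_id <- NA_character_
  idx <- match(rx$admission_id, adm$admission_id)
  bad_ref <- which(is.na(idx))
  in_span <- !is.na(idx) & !is.na(rx$admin_date) &
    rx$admin_date >= adm$admit_date[idx] &
    rx$admin_date <= adm$discharge_date[idx]
  bad_date <- setdiff(which(!in_span), bad_ref)
  bad_drug <- which(is.na(rx$drug_code) | rx$drug_code == "")
  if (length(bad_ref)) rej[["rx_ref"]] <-
    note("prescriptions", bad_ref, "admission_id not found")
  if (length(bad_date)) rej[["rx_date"]] <-
    note("prescriptions", bad_date, "admin_date outside admission span")
  if (length(bad_drug)) rej[["rx_drug"]] <-
    note("prescriptions", bad_drug, "empty drug_code")
  drop <- Reduce(union, list(bad_ref, bad_date, bad_drug))
  if (length(drop)) rx <- rx[-drop, ]

  lab <- as_tibble(cohort$labs)
  require_columns(lab, c("patient_id", "admission_id", "analyte", "value",
                         "result_date"), "labs")
  if (!"order_date" %in% names(lab)) lab$order_date <- as.Date(NA)
  lab$value <- as.character(lab$value)
  value_num <- suppressWarnings(as.numeric(lab$value))
  token <- tolower(trimws(lab$value))
  nominal <- is.na(value_num) & token %in% c("positive", "negative")
  lab$value[nominal] <- token[nominal]
  lab$value_num <- value_num
  bad_val <- which(is.na(value_num) & !nominal)
  bad_ref <- which(is.na(match(lab$admission_id, adm$admission_id)))
  bad_ord <- which(!is.na(lab$order_date) & !is.na(lab$result_date) &
                     lab$order_date > lab$result_date)
  if (length(bad_val)) rej[["lab_val"]] <-
    note("labs", bad_val, "value neither numeric nor positive/negative")
  if (length(bad_ref)) rej[["lab_ref"]] <-
    note("labs", bad_ref, "admission_id not found")
  if (length(bad_ord)) rej[["lab_ord"]] <-
    note("labs", bad_ord, "order_date after result_date")
  drop <- Reduce(union, list(bad_val, bad_ref, bad_ord))
  if (length(drop)) lab <- lab[-drop, ]

  dx <- as_tibble(cohort$diagnoses)
  require_columns(dx, c("patient_id", "icd10_code"), "diagnoses")
  bad_code <- which(!grepl(ICD10_RE, dx$icd10_code))
  if (length(bad_code)) rej[["dx_code"]] <-
    note("diagnoses", bad_code, "icd10_code not ICD-10 shaped")
  if (length(bad_code)) dx <- dx[-bad_code, ]

  rejections <- if (length(rej)) bind_rows(rej) else
    tibble(table = character(), row = integer(), reason = character())
  if (nrow(rejections) && !quiet) {
    inform(sprintf("cohort validation rejected %d row(s); see attr(x, \"rejections\")",
                   nrow(rejections)))
  }
  structure(list(prescriptions = rx, labs = lab, admissions = adm,
                 diagnoses = dx),
            class = "pace_cohort", rejections = rejections)
}

require_columns <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("schema error in %s: missing column(s) %s",
                  table, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' @export
print.pace_cohort <- function(x, ...) {
  cat("<pace_cohort>\n")
  cat(sprintf("  prescriptions: %d rows\n", nrow(x$prescriptions)))
  cat(sprintf("  labs:          %d rows\n", nrow(x$labs)))
  cat(sprintf("  admissions:    %d rows\n", nrow(x$admissions)))
  cat(sprintf("  diagnoses:     %d rows\n", nrow(x$diagnoses)))
  rej <- attr(x, "rejections")
  if (!is.null(rej) && nrow(rej)) {
    cat(sprintf("  rejected rows at load: %d\n", nrow(rej)))
  }
  invisible(x)
}

default_cohort_paths <- function(dir) {
  list(prescriptions = file.path(dir, "prescriptions.csv"),
       labs          = file.path(dir, "labs.csv"),
       admissions    = file.path(dir, "admissions.csv"),
       diagnoses     = file.path(dir, "diagnoses.csv"))
}

#' Read a cohort from delimited text files
#'
#' Loads the four tables from UTF-8 delimited files with a header row and
#' assembles them with [cohort_data()]. Dates are parsed with the supplied
#' format (ISO-8601 `%Y-%m-%d` by default); a row whose date does not parse
#' is rejected with its line number rather than aborting the load.
#'
#' @param paths either a directory containing `prescriptions.csv`,
#'   `labs.csv`, `admissions.csv`, `diagnoses.csv`, or a named list of the
#'   four file paths.
#' @param delim field delimiter, default comma.
#' @param date_format `strptime` format for date columns.
#' @param quiet suppress the rejection summary message.
#' @return A validated `pace_cohort`; date-parse failures are merged into the
#'   `rejections` attribute.
#' @export
read_cohort <- function(paths, delim = ",", date_format = "%Y-%m-%d",
                        quiet = FALSE) {
  if (is.character(paths) && length(paths) == 1 && dir.exists(paths)) {
    paths <- default_cohort_paths(paths)
  }
  for (p in unlist(paths)) {
    if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
  }
  read_one <- function(path) {
    readr::read_delim(path, delim = delim, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
  }
  date_cols <- list(prescriptions = "admin_date",
                    labs = c("order_date", "result_date"),
                    admissions = c("admit_date", "discharge_date"),
                    diagnoses = character())
  tables <- list()
  date_rej <- list()
  for (tb in names(date_cols)) {
    df <- read_one(paths[[tb]])
    bad <- integer()
    for (col in intersect(date_cols[[tb]], names(df))) {
      raw <- df[[col]]
      parsed <- as.Date(raw, format = date_format)
      failed <- which(!is.na(raw) & raw != "" & is.na(parsed))
      bad <- union(bad, failed)
      parsed[is.na(raw) | raw == ""] <- as.Date(NA)
      df[[col]] <- parsed
    }
    if (length(bad)) {
      date_rej[[tb]] <- tibble(table = tb, row = sort(bad),
                               reason = "unparseable date")
      df <- df[-bad, ]
    }
    tables[[tb]] <- df
  }
  cohort <- suppressMessages(
    cohort_data(prescriptions = tables$prescriptions, labs = tables$labs,
                admissions = tables$admissions, diagnoses = tables$diagnoses))
  rej <- bind_rows(c(date_rej, list(attr(cohort, "rejections"))))
  attr(cohort, "rejections") <- rej
  if (nrow(rej) && !quiet) {
    inform(sprintf("cohort load rejected %d row(s); see attr(x, \"rejections\")",
                   nrow(rej)))
  }
  cohort
}

#' Write a cohort to delimited text files
#'
#' Inverse of [read_cohort()]: writes the four tables as UTF-8 delimited
#' files with ISO-8601 dates. Writing then reading reproduces the cohort
#' record-for-record, and repeated writes of the same cohort are
#' byte-identical.
#'
#' @param cohort a `pace_cohort`.
#' @param dir output directory (created if absent); or pass `paths` directly.
#' @param paths optional named list of the four output paths, overrides `dir`.
#' @param delim field delimiter.
#' @return `paths`, invisibly.
#' @export
write_cohort <- function(cohort, dir = NULL, paths = NULL, delim = ",") {
  if (is.null(paths)) {
    if (is.null(dir)) abort("either dir or paths must be supplied")
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- default_cohort_paths(dir)
  }
  lab_out <- cohort$labs
  lab_out$value_num <- NULL
  out <- list(prescriptions = cohort$prescriptions,
              labs = lab_out,
              admissions = cohort$admissions,
              diagnoses = cohort$diagnoses)
  for (tb in names(out)) {
    readr::write_delim(out[[tb]], paths[[tb]], delim = delim, na = "")
  }
  invisible(paths)
}
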