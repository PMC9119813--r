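COHORT_FILES <- c(patients = "patients.csv", observations = "observations.csv",
                  clinical_events = "clinical_events.csv",
                  prescriptions = "prescriptions.csv", truth = "truth.csv")

COHORT_SCHEMAS <- list(
  patients = c(id = "character", ethnicity = "character", sex_male = "integer",
               age_at_diagnosis = "numeric", diagnosis_date = "date",
               registration_start = "date", follow_up_end = "date",
               deprivation_quintile = "integer"),
  observations = c(patient_id = "character", date = "date", code = "character",
                   value = "numeric", unit = "character"),
  clinical_events = c(patient_id = "character", condition = "character",
                      date = "date"),
  prescriptions = c(patient_id = "character", drug_class = "character",
                    date = "date"),
  truth = c(patient_id = "character", subgroup = "character")
)

#' Write a cohort to a directory of CSV files
#'
#' Writes `patients.csv`, `observations.csv`, `clinical_events.csv`,
#' `prescriptions.csv` and `truth.csv` with ISO-8601 dates and full numeric
#' precision, so that [read_cohort()] round-trips all values exactly.
#'
#' @param cohort a `t2d_cohort` (or a list with the same five tables).
#' @param directory output directory; created if absent.
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(COHORT_FILES)) {
    tab <- cohort[[nm]]
    if (is.null(tab)) stop("cohort is missing table: ", nm)
    out <- tab
    for (col in names(out)) {
      if (inherits(out[[col]], "Date")) out[[col]] <- format(out[[col]], "%Y-%m-%d")
      if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
        out[[col]] <- format(out[[col]], digits = 17, trim = TRUE, scientific = FALSE)
      }
    }
    utils::write.csv(out, file.path(directory, COHORT_FILES[[nm]]),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(directory)
}

#' Read a cohort from a directory of CSV files
#'
#' Reads the five tables written by [write_cohort()] (or user-supplied files
#' with the same schemas), validating column presence and types; a malformed
#' numeric or date cell is reported with its column name and line number.
#'
#' @param directory directory containing the five CSV files.
#' @return a `t2d_cohort` list.
#' @export
read_cohort <- function(directory) {
  cohort <- list()
  for (nm in names(COHORT_FILES)) {
    path <- file.path(directory, COHORT_FILES[[nm]])
    if (!file.exists(path)) stop("missing cohort file: ", path)
    cohort[[nm]] <- read_cohort_table(path, COHORT_SCHEMAS[[nm]])
  }
  ids <- cohort$patients$id
  for (nm in c("observations", "clinical_events", "prescriptions", "truth")) {
    orphan <- !(cohort[[nm]]$patient_id %in% ids)
    if (any(orphan)) {
      stop(sprintf("%s references unknown patient ids (e.g. %s)",
                   COHORT_FILES[[nm]], cohort[[nm]]$patient_id[which(orphan)[1]]))
    }
  }
  if (!setequal(cohort$truth$patient_id, ids)) {
    stop("truth.csv must cover exactly the patients in patients.csv")
  }
  class(cohort) <- "t2d_cohort"
  cohort
}

read_cohort_table <- function(path, schema) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s): %s", basename(path),
                 paste(missing_cols, collapse = ", ")))
  }
  out <- raw[names(schema)]
  for (col in names(schema)) {
    out[[col]] <- parse_column(out[[col]], schema[[col]], col, basename(path))
  }
  out
}

parse_column <- function(x, type, col, file) {
  check_bad <- function(parsed) {
    bad <- which(is.na(parsed) & !is.na(x) & nzchar(x))
    if (length(bad)) {
      # +1 for the header row so the number matches the file line
      stop(sprintf("%s: column '%s': malformed value '%s' at line %d",
                   file, col, x[bad[1]], bad[1] + 1L))
    }
    parsed
  }
  switch(type,
    character = x,
    numeric = check_bad(suppressWarnings(as.numeric(x))),
    integer = check_bad(suppressWarnings(as.integer(x))),
    date = check_bad(as.Date(x, format = "%Y-%m-%d", optional = TRUE)),
    stop("unknown schema type: ", type)
  )
}
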