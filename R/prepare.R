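CONDITION_VOCAB <- c("hypertension", "chd", "mi", "stroke", "heart_failure",
                     "ckd", "retinopathy", "neuropathy")
BASELINE_MEASURES <- c("hba1c", "bmi", "sbp", "dbp", "total_cholesterol", "egfr")

#' Apply cohort eligibility criteria
#'
#' Keeps adults (age at diagnosis >= 18 years) with at least 12 months
#' (>= 365 days, closed boundary) of registration before their diagnosis
#' date, reporting how many patients each criterion removed.
#'
#' @param patients patient table.
#' @return the eligible subset of `patients`.
#' @export
apply_eligibility <- function(patients) {
  ok_age <- patients$age_at_diagnosis >= 18
  reg_days <- as.numeric(patients$diagnosis_date - patients$registration_start)
  ok_reg <- reg_days >= 365
  message(sprintf("eligibility: removed %d under 18, %d with < 12 months registration",
                  sum(!ok_age), sum(ok_age & !ok_reg)))
  patients[ok_age & ok_reg, , drop = FALSE]
}

#' Derive baseline measures from the observation table
#'
#' For each patient and measure, baseline is the value of the latest
#' observation in the closed window from 365 days before diagnosis up to and
#' including the diagnosis date; measures with no observation in the window
#' are missing.  HbA1c is normalised to NGSP percent first.  Two observations
#' of the same measure on the tied latest date resolve deterministically to
#' the larger value, with a warning.
#'
#' @param observations observation table.
#' @param patients patient table (supplies `id` and `diagnosis_date`).
#' @return data.frame with one row per patient: `id` then one column per
#'   measure (`hba1c_pct`, `bmi`, `sbp`, `dbp`, `total_cholesterol`, `egfr`).
#' @export
derive_baseline_measures <- function(observations, patients) {
  obs <- normalise_hba1c(observations)
  diag <- patients$diagnosis_date[match(obs$patient_id, patients$id)]
  delta <- as.numeric(obs$date - diag)
  obs <- obs[!is.na(delta) & delta >= -365 & delta <= 0, , drop = FALSE]

  out <- data.frame(id = patients$id, stringsAsFactors = FALSE)
  tie_seen <- FALSE
  for (m in BASELINE_MEASURES) {
    sub <- obs[obs$code == m, , drop = FALSE]
    col <- rep(NA_real_, nrow(patients))
    if (nrow(sub)) {
      # latest date per patient; ties broken to the larger value
      ord <- order(sub$patient_id, sub$date, sub$value)
      sub <- sub[ord, , drop = FALSE]
      dup_date <- duplicated(sub[c("patient_id", "date")])
      if (any(dup_date)) tie_seen <- TRUE
      last <- !duplicated(sub$patient_id, fromLast = TRUE)
      col[match(sub$patient_id[last], patients$id)] <- sub$value[last]
    }
    out[[if (m == "hba1c") "hba1c_pct" else m]] <- col
  }
  if (tie_seen) {
    warning("same-day duplicate baseline measurements resolved to the larger value")
  }
  out
}

#' Flag conditions prevalent before diagnosis
#'
#' A condition is prevalent iff any event of that condition is dated strictly
#' before the patient's diagnosis date; events on the diagnosis day itself
#' count as incident.
#'
#' @param clinical_events clinical-event table.
#' @param patients patient table.
#' @return data.frame: `id` plus one logical column per condition in the
#'   vocabulary.
#' @export
flag_prevalent_conditions <- function(clinical_events, patients) {
  unknown <- setdiff(unique(clinical_events$condition), CONDITION_VOCAB)
  if (length(unknown)) stop("unknown condition code(s): ",
                            paste(unknown, collapse = ", "))
  diag <- patients$diagnosis_date[match(clinical_events$patient_id, patients$id)]
  prev <- clinical_events[!is.na(diag) & clinical_events$date < diag, , drop = FALSE]
  out <- data.frame(id = patients$id, stringsAsFactors = FALSE)
  for (cond in CONDITION_VOCAB) {
    out[[cond]] <- patients$id %in% prev$patient_id[prev$condition == cond]
  }
  out
}

#' Macro/microvascular composite status from condition flags
#'
#' Macrovascular = CHD, heart failure, myocardial infarction or stroke;
#' microvascular = CKD, neuropathy or retinopathy.  Hypertension belongs to
#' neither composite.
#'
#' @param flags data.frame of logical condition columns (as from
#'   [flag_prevalent_conditions()]) or a character vector of condition codes.
#' @return data.frame with logical columns `macro` and `micro` (one row per
#'   row of `flags`, or a single row for a code vector).
#' @export
composite_status <- function(flags) {
  if (is.character(flags)) {
    unknown <- setdiff(flags, CONDITION_VOCAB)
    if (length(unknown)) stop("unknown condition code(s): ",
                              paste(unknown, collapse = ", "))
    return(data.frame(macro = any(flags %in% MACRO_CONDITIONS),
                      micro = any(flags %in% MICRO_CONDITIONS)))
  }
  macro_cols <- intersect(MACRO_CONDITIONS, names(flags))
  micro_cols <- intersect(MICRO_CONDITIONS, names(flags))
  data.frame(
    macro = Reduce(`|`, flags[macro_cols], rep(FALSE, nrow(flags))),
    micro = Reduce(`|`, flags[micro_cols], rep(FALSE, nrow(flags)))
  )
}

#' Follow-up interval from diagnosis to end of follow-up
#'
#' Follow-up runs from diagnosis to the earliest of the patient's recorded
#' follow-up end (leaving the practice or death) and the administrative study
#' end; lengths are reported in years of 365.25 days.  Zero-length intervals
#' are retained with a warning.
#'
#' @param patients patient table.
#' @param study_end administrative study end date.
#' @return data.frame: `id`, `entry_date`, `end_date`, `followup_years`.
#' @export
follow_up_interval <- function(patients, study_end = as.Date("2018-01-01")) {
  end <- pmin(patients$follow_up_end, study_end)
  if (any(end < patients$diagnosis_date)) stop("follow-up ends before diagnosis")
  years <- as.numeric(end - patients$diagnosis_date) / DAYS_PER_YEAR
  if (any(years == 0)) {
    warning(sum(years == 0), " patient(s) with zero-length follow-up retained")
  }
  data.frame(id = patients$id, entry_date = patients$diagnosis_date,
             end_date = end, followup_years = years, stringsAsFactors = FALSE)
}

#' Build the analysis-ready baseline table
#'
#' Applies eligibility, derives baseline measures and prevalent-condition
#' flags, composites, and follow-up intervals, and joins them into one row
#' per eligible patient.  Rows missing any of the four latent-class
#' indicators (age, sex, HbA1c, BMI) are flagged `usable_for_clustering =
#' FALSE` but retained.  A per-measure completeness summary (percent of
#' eligible patients with a baseline value) is attached as attribute
#' `"completeness"`.
#'
#' @param cohort a `t2d_cohort` (truth table not required).
#' @param study_end administrative study end date.
#' @return the baseline table (one row per eligible patient).
#' @export
build_baseline_table <- function(cohort, study_end = as.Date("2018-01-01")) {
  if (anyDuplicated(cohort$patients$id)) stop("duplicate patient ids")
  pts <- apply_eligibility(cohort$patients)
  meas <- derive_baseline_measures(cohort$observations, pts)
  flags <- flag_prevalent_conditions(cohort$clinical_events, pts)
  comp <- composite_status(flags)
  fup <- suppressWarnings(follow_up_interval(pts, study_end))

  baseline <- data.frame(
    id = pts$id, ethnicity = pts$ethnicity, sex_male = pts$sex_male,
    age = pts$age_at_diagnosis,
    deprivation_quintile = pts$deprivation_quintile,
    diagnosis_date = pts$diagnosis_date,
    stringsAsFactors = FALSE
  )
  baseline <- cbind(baseline, meas[-1], flags[-1],
                    macro_prevalent = comp$macro, micro_prevalent = comp$micro,
                    fup[c("end_date", "followup_years")])
  baseline$usable_for_clustering <- !is.na(baseline$age) &
    !is.na(baseline$sex_male) & !is.na(baseline$hba1c_pct) & !is.na(baseline$bmi)

  measure_cols <- c("age", "sex_male", "hba1c_pct", "bmi", "sbp", "dbp",
                    "total_cholesterol", "egfr")
  completeness <- data.frame(
    measure = measure_cols,
    complete_pct = vapply(measure_cols, function(cl) {
      percent_of(sum(!is.na(baseline[[cl]])), nrow(baseline), 1)
    }, numeric(1)),
    row.names = NULL
  )
  attr(baseline, "completeness") <- completeness
  baseline
}
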