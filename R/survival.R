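#' Build the incident vascular-outcome analysis set
#'
#' Among patients free of the corresponding prevalent composite at baseline,
#' the event is the first qualifying incident event (macrovascular: CHD,
#' heart failure, MI, stroke; microvascular: CKD, neuropathy, retinopathy)
#' on or after the diagnosis date and within follow-up; otherwise the
#' patient is censored at follow-up end.  Competing events are treated as
#' censoring (cause-specific hazards).  Zero-duration intervals are shifted
#' to half a day with a warning.
#'
#' @param baseline baseline table from [build_baseline_table()].
#' @param clinical_events clinical-event table.
#' @param assignments data.frame with `id` and `label`.
#' @param outcome `"macro"` or `"micro"`.
#' @return data.frame of survival records: `id`, `time` (years), `event`,
#'   `age`, `male`, `label`.
#' @export
build_vascular_analysis_set <- function(baseline, clinical_events, assignments,
                                        outcome = c("macro", "micro")) {
  outcome <- match.arg(outcome)
  prev_col <- paste0(outcome, "_prevalent")
  conds <- if (outcome == "macro") MACRO_CONDITIONS else MICRO_CONDITIONS
  keep <- !baseline[[prev_col]]
  b <- baseline[keep, , drop = FALSE]

  ev <- clinical_events[clinical_events$condition %in% conds, , drop = FALSE]
  diag <- b$diagnosis_date[match(ev$patient_id, b$id)]
  ev <- ev[!is.na(diag) & ev$date >= diag, , drop = FALSE]
  first <- tapply(as.numeric(ev$date), ev$patient_id, min)
  first_date <- as.Date(as.numeric(first[match(b$id, names(first))]),
                        origin = "1970-01-01")
  has_event <- !is.na(first_date) & first_date <= b$end_date

  time <- ifelse(has_event,
                 as.numeric(first_date - b$diagnosis_date) / DAYS_PER_YEAR,
                 b$followup_years)
  if (any(time <= 0)) {
    warning(sum(time <= 0), " zero-duration interval(s) shifted to half a day")
    time[time <= 0] <- 0.5 / DAYS_PER_YEAR
  }
  data.frame(id = b$id, time = time, event = as.integer(has_event),
             age = b$age, male = b$sex_male,
             label = assignments$label[match(b$id, assignments$id)],
             ethnicity = b$ethnicity, stringsAsFactors = FALSE)
}

#' Build the treatment-initiation analysis set
#'
#' Patients with a prescription of the class earlier than 30 days before
#' diagnosis are prevalent users and excluded ("free from treatment at
#' baseline").  A first prescription within the 30 days up to diagnosis is a
#' baseline initiator, analysed as initiating 1 day after diagnosis;
#' otherwise the event is the first prescription after diagnosis within
#' follow-up, else censoring at follow-up end.
#'
#' @param baseline baseline table.
#' @param prescriptions prescription table.
#' @param assignments data.frame with `id` and `label`.
#' @param drug_class `"noninsulin_antidiabetic"` or `"insulin"`.
#' @return survival-record data.frame as in [build_vascular_analysis_set()].
#' @export
build_initiation_analysis_set <- function(baseline, prescriptions, assignments,
                                          drug_class = c("noninsulin_antidiabetic",
                                                         "insulin")) {
  drug_class <- match.arg(drug_class)
  rx <- prescriptions[prescriptions$drug_class == drug_class, , drop = FALSE]
  diag <- baseline$diagnosis_date[match(rx$patient_id, baseline$id)]
  rx <- rx[!is.na(diag), , drop = FALSE]
  diag <- diag[!is.na(diag)]
  delta <- as.numeric(rx$date - diag)

  prevalent_ids <- unique(rx$patient_id[delta < -30])
  b <- baseline[!(baseline$id %in% prevalent_ids), , drop = FALSE]

  in_window <- delta >= -30 & delta <= 0
  baseline_ids <- unique(rx$patient_id[in_window])
  after <- rx[delta > 0, , drop = FALSE]
  first <- tapply(as.numeric(after$date), after$patient_id, min)
  first_date <- as.Date(as.numeric(first[match(b$id, names(first))]),
                        origin = "1970-01-01")

  is_baseline_init <- b$id %in% baseline_ids
  has_event <- is_baseline_init |
    (!is.na(first_date) & first_date <= b$end_date)
  time <- b$followup_years
  post_event <- !is_baseline_init & has_event
  time[post_event] <- as.numeric(first_date[post_event] - b$diagnosis_date[post_event]) /
    DAYS_PER_YEAR
  time[is_baseline_init] <- 1 / DAYS_PER_YEAR
  time[time <= 0] <- 0.5 / DAYS_PER_YEAR

  data.frame(id = b$id, time = time, event = as.integer(has_event),
             age = b$age, male = b$sex_male,
             label = assignments$label[match(b$id, assignments$id)],
             ethnicity = b$ethnicity, stringsAsFactors = FALSE)
}

#' Age- and sex-adjusted Cox proportional-hazards fit
#'
#' Fits a Cox model with Breslow tie handling via [survival::coxph()] on a
#' survival-record table, with subgroup entered as indicator covariates
#' against the MARD reference, adjusted for age and sex.  Wald 95%
#' confidence intervals use z = 1.959964; p-values are two-sided.
#'
#' @param records survival-record data.frame (`time`, `event`, `age`,
#'   `male`, `label`).
#' @param adjust covariates to adjust for besides the subgroup indicators.
#' @param reference reference subgroup label.
#' @return data.frame of class `cox_fit`: one row per coefficient with
#'   `term`, `beta`, `se`, `hr`, `ci_lo`, `ci_hi`, `p`; attributes `n`,
#'   `n_events`, `loglik`, `converged`, `ties`.
#' @export
cox_fit <- function(records, adjust = c("age", "male"), reference = "MARD") {
  records <- records[!is.na(records$label), , drop = FALSE]
  if (sum(records$event) < 1) stop("no events in the analysis set")
  records$label <- stats::relevel(factor(records$label), ref = reference)
  covars <- c(adjust, "label")
  covars <- covars[vapply(covars, function(v) {
    length(unique(records[[v]])) > 1
  }, logical(1))]
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(covars, collapse = " + ")))
  fit <- survival::coxph(f, data = records, ties = "breslow")
  s <- summary(fit)
  z <- 1.959964
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  out <- data.frame(
    term = sub("^label", "", names(beta)),
    beta = unname(beta), se = unname(se),
    hr = exp(unname(beta)),
    ci_lo = exp(unname(beta) - z * unname(se)),
    ci_hi = exp(unname(beta) + z * unname(se)),
    p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
    stringsAsFactors = FALSE
  )
  attr(out, "n") <- s$n
  attr(out, "n_events") <- s$nevent
  attr(out, "loglik") <- fit$loglik[2]
  attr(out, "converged") <- fit$info %||% TRUE
  attr(out, "ties") <- "breslow"
  class(out) <- c("cox_fit", "data.frame")
  out
}

#' Treatment-initiation summary table
#'
#' For each population stratum (overall plus each modelled ethnic group),
#' subgroup and drug class: patients eligible to initiate, number and
#' percent initiating (1 d.p.), mean and SD of years to initiation among
#' initiators, and the age- and sex-adjusted hazard ratio vs MARD with 95%
#' CI and p-value.  Stratum hazard ratios come from models refitted within
#' the stratum.
#'
#' @param baseline baseline table.
#' @param prescriptions prescription table.
#' @param assignments data.frame with `id` and `label`.
#' @param strata ethnic strata reported besides `"overall"`.
#' @return long data.frame, one row per stratum x subgroup x drug class
#'   (subgroup `"all"` rows give stratum totals).
#' @export
initiation_summary <- function(baseline, prescriptions, assignments,
                               strata = c("white", "south_asian", "black")) {
  rows <- list()
  for (cls in c("noninsulin_antidiabetic", "insulin")) {
    rec_all <- build_initiation_analysis_set(baseline, prescriptions,
                                             assignments, cls)
    rec_all <- rec_all[!is.na(rec_all$label), , drop = FALSE]
    for (st in c("overall", strata)) {
      rec <- if (st == "overall") rec_all else
        rec_all[rec_all$ethnicity == st, , drop = FALSE]
      if (!nrow(rec)) next
      hr <- tryCatch(cox_fit(rec), error = function(e) NULL)
      subgroups <- c("all", sort(unique(rec$label)))
      for (sg in subgroups) {
        r <- if (sg == "all") rec else rec[rec$label == sg, , drop = FALSE]
        n_init <- sum(r$event)
        t_init <- r$time[r$event == 1]
        hr_row <- if (!is.null(hr) && sg %in% hr$term) hr[hr$term == sg, ] else NULL
        rows[[length(rows) + 1L]] <- data.frame(
          drug_class = cls, stratum = st, subgroup = sg,
          n_eligible = nrow(r), n_initiating = n_init,
          pct_initiating = if (nrow(r)) percent_of(n_init, nrow(r), 1) else NA_real_,
          mean_years_to_initiation = if (n_init) mean(t_init) else NA_real_,
          sd_years_to_initiation = if (n_init > 1) stats::sd(t_init) else NA_real_,
          hr = if (sg == "MARD") 1 else hr_row$hr %||% NA_real_,
          ci_lo = hr_row$ci_lo %||% NA_real_,
          ci_hi = hr_row$ci_hi %||% NA_real_,
          p = hr_row$p %||% NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Incident vascular-outcome hazard-ratio report
#'
#' For each composite outcome and stratum (overall plus each modelled
#' ethnic group): crude incident proportions per subgroup and the age- and
#' sex-adjusted hazard ratios of MOD and SHD against the MARD reference,
#' refitted within each stratum.
#'
#' @param baseline baseline table.
#' @param clinical_events clinical-event table.
#' @param assignments data.frame with `id` and `label`.
#' @param strata ethnic strata reported besides `"overall"`.
#' @return long data.frame, one row per outcome x stratum x subgroup.
#' @export
vascular_report <- function(baseline, clinical_events, assignments,
                            strata = c("white", "south_asian", "black")) {
  rows <- list()
  for (outcome in c("macro", "micro")) {
    rec_all <- build_vascular_analysis_set(baseline, clinical_events,
                                           assignments, outcome)
    rec_all <- rec_all[!is.na(rec_all$label), , drop = FALSE]
    for (st in c("overall", strata)) {
      rec <- if (st == "overall") rec_all else
        rec_all[rec_all$ethnicity == st, , drop = FALSE]
      if (!nrow(rec)) next
      hr <- tryCatch(cox_fit(rec), error = function(e) NULL)
      for (sg in sort(unique(rec$label))) {
        r <- rec[rec$label == sg, , drop = FALSE]
        hr_row <- if (!is.null(hr) && sg %in% hr$term) hr[hr$term == sg, ] else NULL
        rows[[length(rows) + 1L]] <- data.frame(
          outcome = outcome, stratum = st, subgroup = sg,
          n = nrow(r), n_events = sum(r$event),
          crude_pct = percent_of(sum(r$event), nrow(r), 1),
          hr = if (sg == "MARD") 1 else hr_row$hr %||% NA_real_,
          ci_lo = hr_row$ci_lo %||% NA_real_,
          ci_hi = hr_row$ci_hi %||% NA_real_,
          p = hr_row$p %||% NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
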