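MACRO_CONDITIONS <- c("chd", "mi", "stroke", "heart_failure")
MICRO_CONDITIONS <- c("ckd", "retinopathy", "neuropathy")

#' Sample the patient table and latent subgroup truth
#'
#' Each patient draws an ethnicity from the configured mix, a latent subgroup
#' from that ethnicity's shares, and then diagnosis-time indicators from the
#' subgroup profile: age, HbA1c and BMI as truncated normals (lower bounds
#' 18 years, 3.5 percent, 13 kg/m2) and sex as Bernoulli.  Indicators are
#' conditionally independent given the subgroup, matching the latent-class
#' model fitted downstream.  HbA1c and BMI are masked unrecorded completely
#' at random at the configured fractions; the latent values are kept (with an
#' `*_observed` flag) because they also seed the post-diagnosis HbA1c
#' trajectory.  Diagnosis dates are uniform over the study window, with at
#' least 12 months of registration before diagnosis, and follow-up ends at
#' the earlier of exponential loss to follow-up and the study end date.
#'
#' @param config a `t2d_generator_config`.
#' @param seed integer seed; identical (config, seed) gives identical output.
#' @return list with `patients`, `truth` (patient_id, subgroup) and
#'   `indicators` (latent indicator draws plus observed-at-baseline flags).
#' @export
sample_patients <- function(config, seed = config$seed) {
  validate_generator_config(config)
  n <- config$n_patients
  if (n <= 0) stop("n_patients must be positive")
  set.seed(derive_seed(seed, 1L))

  id <- sprintf("P%06d", seq_len(n))
  ethnicity <- sample(names(config$ethnicity_mix), n, replace = TRUE,
                      prob = config$ethnicity_mix)
  prof <- config$profiles
  subgroup <- character(n)
  for (eth in unique(ethnicity)) {
    rows <- prof$ethnicity == eth
    idx <- ethnicity == eth
    subgroup[idx] <- sample(prof$subgroup[rows], sum(idx), replace = TRUE,
                            prob = prof$share[rows])
  }
  cell <- match(paste(ethnicity, subgroup), paste(prof$ethnicity, prof$subgroup))

  age <- rtnorm_lower(n, prof$age_mean[cell], prof$age_sd[cell], 18)
  hba1c <- rtnorm_lower(n, prof$hba1c_mean[cell], prof$hba1c_sd[cell], 3.5)
  bmi <- rtnorm_lower(n, prof$bmi_mean[cell], prof$bmi_sd[cell], 13)
  sex_male <- as.integer(stats::runif(n) < prof$male_prob[cell])
  hba1c_observed <- stats::runif(n) >= config$missing_frac_hba1c
  bmi_observed <- stats::runif(n) >= config$missing_frac_bmi

  span_days <- as.numeric(config$study_end - config$study_start)
  diagnosis_date <- config$study_start + floor(stats::runif(n) * span_days)
  registration_start <- diagnosis_date - (365L + floor(stats::runif(n) * 4000))

  # loss-to-follow-up rate chosen so the configured fraction reaches the
  # administrative study end (averaged over a uniform diagnosis window)
  lam <- dropout_rate_for_admin_frac(config$admin_end_frac, config$followup_max_years)
  dropout_years <- stats::rexp(n, lam)
  follow_up_end <- pmin(config$study_end,
                        diagnosis_date + round(dropout_years * DAYS_PER_YEAR))

  patients <- data.frame(
    id = id,
    ethnicity = ethnicity,
    sex_male = sex_male,
    age_at_diagnosis = age,
    diagnosis_date = diagnosis_date,
    registration_start = registration_start,
    follow_up_end = follow_up_end,
    deprivation_quintile = sample(1:5, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(patient_id = id, subgroup = subgroup,
                      stringsAsFactors = FALSE)
  indicators <- data.frame(
    patient_id = id, age = age, sex_male = sex_male,
    hba1c = hba1c, bmi = bmi,
    hba1c_observed = hba1c_observed, bmi_observed = bmi_observed,
    stringsAsFactors = FALSE
  )
  list(patients = patients, truth = truth, indicators = indicators)
}

# Solve (1 - exp(-lambda*T)) / (lambda*T) = admin_frac for the dropout rate.
dropout_rate_for_admin_frac <- function(admin_frac, max_years) {
  stopifnot(admin_frac > 0, admin_frac < 1)
  f <- function(l) (1 - exp(-l * max_years)) / (l * max_years) - admin_frac
  stats::uniroot(f, c(1e-8, 50), tol = 1e-10)$root
}

#' Sample post-diagnosis HbA1c observation series
#'
#' Visit times follow a jittered regular schedule at the subgroup's
#' visits-per-year over each patient's follow-up.  The latent mean at time
#' `t` years after diagnosis is
#' `asymptote + (baseline + start_offset - asymptote) * exp(-decay_rate * t)`;
#' observations add Gaussian noise and are floored at 3.5 percent.  Under the
#' default configuration the severe-hyperglycaemia subgroup starts above 12
#' percent, falls steeply in the first year, and settles above target
#' control, while the two mild subgroups stay near their baseline.  A
#' configured fraction of observations is recorded on the IFCC mmol/mol
#' scale to exercise downstream unit handling.
#'
#' @param patients patient table (id, diagnosis_date, follow_up_end).
#' @param truth truth table (patient_id, subgroup).
#' @param baseline_hba1c numeric vector of baseline HbA1c percent, aligned
#'   with `patients` rows.
#' @param config generator configuration.
#' @param seed integer seed.
#' @return observation table rows (patient_id, date, code, value, unit).
#' @export
sample_hba1c_series <- function(patients, truth, baseline_hba1c, config,
                                seed = config$seed) {
  stopifnot(nrow(patients) == length(baseline_hba1c))
  set.seed(derive_seed(seed, 2L))
  traj <- config$hba1c_trajectory
  sub <- truth$subgroup[match(patients$id, truth$patient_id)]
  ti <- match(sub, traj$subgroup)

  fup_years <- as.numeric(patients$follow_up_end - patients$diagnosis_date) / DAYS_PER_YEAR
  if (any(fup_years < 0)) stop("negative follow-up")
  vpy <- traj$visits_per_year[ti]
  n_visits <- pmax(0L, floor(vpy * fup_years))

  idx <- rep(seq_len(nrow(patients)), n_visits)
  if (length(idx) == 0) {
    return(data.frame(patient_id = character(0), date = as.Date(character(0)),
                      code = character(0), value = numeric(0),
                      unit = character(0), stringsAsFactors = FALSE))
  }
  k <- sequence(n_visits) - 1L
  t_years <- (k + stats::runif(length(k))) / vpy[idx]
  t_years <- pmin(t_years, fup_years[idx])

  asym <- traj$asymptote[ti][idx]
  amp <- baseline_hba1c[idx] + traj$start_offset[ti][idx] - asym
  latent <- asym + amp * exp(-traj$decay_rate[ti][idx] * t_years)
  value <- pmax(3.5, latent + stats::rnorm(length(latent),
                                           sd = traj$obs_noise_sd[ti][idx]))

  unit <- rep("percent", length(value))
  in_mmol <- stats::runif(length(value)) < config$hba1c_mmol_frac
  value[in_mmol] <- hba1c_percent_to_mmol(value[in_mmol])
  unit[in_mmol] <- "mmol_per_mol"

  data.frame(
    patient_id = patients$id[idx],
    date = patients$diagnosis_date[idx] + pmax(1, round(t_years * DAYS_PER_YEAR)),
    code = "hba1c",
    value = value,
    unit = unit,
    stringsAsFactors = FALSE
  )
}

#' Sample treatment initiation and vascular events
#'
#' Each of the four processes (non-insulin initiation, insulin initiation,
#' incident macrovascular event, incident microvascular event) draws a
#' time-to-event from an exponential law with rate
#' `base_rate * exp(subgroup log-HR + age_log_hr_per_year * (age - centre) +
#' male_log_hr * male)`; events after follow-up end are dropped (censoring).
#' Configured fractions of patients are prevalent drug users (first
#' prescription earlier than 30 days before diagnosis), baseline initiators
#' (first non-insulin prescription within the 30 days before diagnosis), or
#' carry prevalent macro/microvascular disease (component event dated before
#' diagnosis).  Prevalent hypertension is added as a non-composite
#' comorbidity.
#'
#' @param patients patient table.
#' @param truth truth table.
#' @param config generator configuration.
#' @param seed integer seed.
#' @return list with `prescriptions` and `clinical_events` tables.
#' @export
sample_treatment_and_events <- function(patients, truth, config,
                                        seed = config$seed) {
  set.seed(derive_seed(seed, 3L))
  n <- nrow(patients)
  sub <- truth$subgroup[match(patients$id, truth$patient_id)]
  diag <- patients$diagnosis_date
  fup_years <- as.numeric(patients$follow_up_end - diag) / DAYS_PER_YEAR
  covar_lp <- config$age_log_hr_per_year * (patients$age_at_diagnosis - config$age_centre) +
    config$male_log_hr * patients$sex_male

  event_time <- function(base_rate, log_hr_by_subgroup) {
    rate <- base_rate * exp(log_hr_by_subgroup[sub] + covar_lp)
    stats::rexp(n) / rate
  }
  rx_rows <- function(keep, dates, drug_class) {
    data.frame(patient_id = patients$id[keep],
               drug_class = rep(drug_class, sum(keep)),
               date = dates[keep], stringsAsFactors = FALSE)
  }

  prescriptions <- list()
  for (cls in c("noninsulin", "insulin")) {
    base <- if (cls == "noninsulin") config$initiation_base_rate_noninsulin
            else config$initiation_base_rate_insulin
    t_ev <- event_time(base, config$initiation_log_hr[[cls]])
    prevalent <- stats::runif(n) < config$prevalent_rx_prob[[cls]]
    baseline_init <- !prevalent & cls == "noninsulin" &
      stats::runif(n) < config$baseline_initiator_frac
    drug <- if (cls == "noninsulin") "noninsulin_antidiabetic" else "insulin"

    prev_dates <- diag - 31L - floor(stats::runif(n) * 700)
    prescriptions[[paste0(cls, "_prev")]] <- rx_rows(prevalent, prev_dates, drug)
    base_dates <- diag - floor(stats::runif(n) * 31)
    prescriptions[[paste0(cls, "_base")]] <- rx_rows(baseline_init, base_dates, drug)
    incident <- !prevalent & !baseline_init & t_ev <= fup_years
    inc_dates <- diag + pmax(1, round(t_ev * DAYS_PER_YEAR))
    prescriptions[[paste0(cls, "_inc")]] <- rx_rows(incident, inc_dates, drug)
  }
  prescriptions <- do.call(rbind, prescriptions)
  rownames(prescriptions) <- NULL

  events <- list()
  prev_prob <- list(macro = config$prevalent_macro_prob,
                    micro = config$prevalent_micro_prob)
  conds <- list(macro = MACRO_CONDITIONS, micro = MICRO_CONDITIONS)
  base_rates <- list(macro = config$vascular_base_rate_macro,
                     micro = config$vascular_base_rate_micro)
  for (comp in c("macro", "micro")) {
    prevalent <- stats::runif(n) < prev_prob[[comp]][sub]
    prev_dates <- diag - 1L - floor(stats::runif(n) * 3650)
    events[[paste0(comp, "_prev")]] <- data.frame(
      patient_id = patients$id[prevalent],
      condition = sample(conds[[comp]], sum(prevalent), replace = TRUE),
      date = prev_dates[prevalent], stringsAsFactors = FALSE)
    t_ev <- event_time(base_rates[[comp]], config$vascular_log_hr[[comp]])
    incident <- t_ev <= fup_years
    events[[paste0(comp, "_inc")]] <- data.frame(
      patient_id = patients$id[incident],
      condition = sample(conds[[comp]], sum(incident), replace = TRUE),
      date = (diag + pmax(1, round(t_ev * DAYS_PER_YEAR)))[incident],
      stringsAsFactors = FALSE)
  }
  htn <- stats::runif(n) < 0.4
  events$hypertension <- data.frame(
    patient_id = patients$id[htn], condition = rep("hypertension", sum(htn)),
    date = (diag - 1L - floor(stats::runif(n) * 3650))[htn],
    stringsAsFactors = FALSE)
  clinical_events <- do.call(rbind, events)
  rownames(clinical_events) <- NULL

  list(prescriptions = prescriptions, clinical_events = clinical_events)
}

#' Simulate a complete synthetic primary-care cohort
#'
#' Runs [sample_patients()], writes diagnosis-window baseline observations
#' for the recorded indicators and auxiliary measures (blood pressure, total
#' cholesterol, eGFR at their configured completeness), then
#' [sample_hba1c_series()] and [sample_treatment_and_events()], returning the
#' five linked tables every downstream stage consumes.
#'
#' @param config a `t2d_generator_config`; `default_generator_config()` gives
#'   the study-calibrated defaults.
#' @param seed integer seed; the full cohort is reproducible from
#'   (config, seed).
#' @return list of class `t2d_cohort` with elements `patients`,
#'   `observations`, `clinical_events`, `prescriptions`, `truth`.
#' @export
simulate_cohort <- function(config = default_generator_config(),
                            seed = config$seed) {
  drawn <- sample_patients(config, seed)
  patients <- drawn$patients
  ind <- drawn$indicators
  n <- nrow(patients)

  set.seed(derive_seed(seed, 4L))
  obs <- list()
  # baseline indicator observations (within the year before diagnosis)
  h_obs <- ind$hba1c_observed
  h_unit <- ifelse(stats::runif(n) < config$hba1c_mmol_frac, "mmol_per_mol", "percent")
  h_val <- ifelse(h_unit == "mmol_per_mol", hba1c_percent_to_mmol(ind$hba1c), ind$hba1c)
  obs$hba1c <- data.frame(
    patient_id = patients$id[h_obs],
    date = (patients$diagnosis_date - floor(stats::runif(n) * 90))[h_obs],
    code = "hba1c", value = h_val[h_obs], unit = h_unit[h_obs],
    stringsAsFactors = FALSE)
  b_obs <- ind$bmi_observed
  obs$bmi <- data.frame(
    patient_id = patients$id[b_obs],
    date = (patients$diagnosis_date - floor(stats::runif(n) * 90))[b_obs],
    code = "bmi", value = ind$bmi[b_obs], unit = "kg_per_m2",
    stringsAsFactors = FALSE)
  aux_units <- c(sbp = "mmHg", dbp = "mmHg", total_cholesterol = "mmol_per_l",
                 egfr = "ml_per_min")
  for (i in seq_len(nrow(config$aux_measures))) {
    a <- config$aux_measures[i, ]
    rec <- stats::runif(n) < a$complete_frac
    obs[[a$code]] <- data.frame(
      patient_id = patients$id[rec],
      date = (patients$diagnosis_date - floor(stats::runif(n) * 365))[rec],
      code = a$code,
      value = rtnorm_lower(n, a$mean, a$sd, a$lower)[rec],
      unit = aux_units[[a$code]], stringsAsFactors = FALSE)
  }
  baseline_obs <- do.call(rbind, obs)

  series <- sample_hba1c_series(patients, drawn$truth, ind$hba1c, config, seed)
  observations <- rbind(baseline_obs, series)
  observations <- observations[order(observations$patient_id, observations$date,
                                     observations$code), ]
  rownames(observations) <- NULL

  ev <- sample_treatment_and_events(patients, drawn$truth, config, seed)

  cohort <- list(patients = patients,
                 observations = observations,
                 clinical_events = ev$clinical_events,
                 prescriptions = ev$prescriptions,
                 truth = drawn$truth)
  class(cohort) <- "t2d_cohort"
  cohort
}
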