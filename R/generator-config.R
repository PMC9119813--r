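#' Subgroup indicator profiles used by the synthetic cohort generator
#'
#' One row per ethnicity x subgroup cell: the subgroup share within the
#' ethnic group and the diagnosis-time indicator distributions (age, HbA1c
#' percent, BMI as truncated normals; sex as Bernoulli).  Defaults are the
#' published baseline characteristics of a large multi-ethnic UK primary-care
#' T2DM cohort; the mixed/other stratum, for which no stratified table is
#' published, reuses the overall-cohort subgroup profiles.
#'
#' @return data.frame with columns `ethnicity`, `subgroup`, `share`,
#'   `age_mean`, `age_sd`, `hba1c_mean`, `hba1c_sd`, `bmi_mean`, `bmi_sd`,
#'   `male_prob`.
#' @export
default_subgroup_profiles <- function() {
  prof <- rbind(
    # ethnicity, subgroup, share, age m/sd, hba1c m/sd, bmi m/sd, male
    data.frame(ethnicity = "south_asian",
               subgroup = c("MARD", "MOD", "SHD"),
               share = c(0.842, 0.085, 0.073),
               age_mean = c(50.1, 44.9, 44.1), age_sd = c(13.1, 12.4, 11.2),
               hba1c_mean = c(7.2, 7.3, 11.8), hba1c_sd = c(0.9, 1.1, 1.5),
               bmi_mean = c(27.6, 38.5, 28.1), bmi_sd = c(3.5, 3.5, 4.5),
               male_prob = c(0.566, 0.196, 0.732)),
    data.frame(ethnicity = "white",
               subgroup = c("MARD", "MOD", "SHD"),
               share = c(0.377, 0.537, 0.086),
               age_mean = c(71.7, 50.7, 53.0), age_sd = c(8.2, 9.1, 11.7),
               hba1c_mean = c(6.9, 7.3, 11.9), hba1c_sd = c(0.7, 1.0, 1.5),
               bmi_mean = c(29.5, 34.6, 32.7), bmi_sd = c(4.7, 6.1, 6.4),
               male_prob = c(0.514, 0.599, 0.670)),
    data.frame(ethnicity = "black",
               subgroup = c("MARD", "MOD", "SHD"),
               share = c(0.762, 0.134, 0.104),
               age_mean = c(56.0, 50.7, 46.9), age_sd = c(12.8, 11.8, 12.3),
               hba1c_mean = c(7.2, 7.3, 12.8), hba1c_sd = c(0.9, 1.1, 1.8),
               bmi_mean = c(30.0, 41.1, 30.9), bmi_sd = c(4.1, 3.6, 5.7),
               male_prob = c(0.541, 0.075, 0.672)),
    data.frame(ethnicity = "mixed_other",
               subgroup = c("MARD", "MOD", "SHD"),
               share = c(0.823, 0.096, 0.081),
               age_mean = c(53.9, 50.6, 47.7), age_sd = c(13.9, 12.8, 12.1),
               hba1c_mean = c(7.2, 7.3, 12.1), hba1c_sd = c(0.9, 1.1, 1.6),
               bmi_mean = c(28.9, 41.3, 30.2), bmi_sd = c(4.2, 3.4, 5.6),
               male_prob = c(0.563, 0.228, 0.690))
  )
  rownames(prof) <- NULL
  prof
}

#' Default synthetic-cohort generator configuration
#'
#' Returns the full configuration of the synthetic primary-care T2DM cohort
#' generator, calibrated to the published multi-ethnic study population:
#' 31 931 patients; ethnicity mix 47% South Asian / 26% white / 20% black /
#' 8% mixed-other; per-ethnicity subgroup shares and indicator profiles from
#' [default_subgroup_profiles()]; diagnosis-time HbA1c missing for 39.7% and
#' BMI for 10.9% of patients (completely at random); treatment-initiation
#' hazard ratios vs MARD of 1.92 (SHD) and 1.16 (MOD) for non-insulin drugs
#' and 2.02 / 1.02 for insulin; vascular hazard ratios of 1.50 (MOD) for the
#' macrovascular and 1.38 (SHD) for the microvascular composite.
#'
#' Event processes are exponential given covariates (proportional hazards
#' with log-linear age and sex effects, age centred at 53.1 years).  Loss to
#' follow-up is exponential with `admin_end_frac` giving the fraction whose
#' follow-up instead ends administratively at the study end date.
#'
#' @param n_patients number of patients to simulate.
#' @param seed default integer seed recorded in the config.
#' @return a list of class `t2d_generator_config`.
#' @export
default_generator_config <- function(n_patients = 31931, seed = 1) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    ethnicity_mix = c(white = 8154, south_asian = 14884, black = 6423,
                      mixed_other = 2470) / 31931,
    profiles = default_subgroup_profiles(),
    missing_frac_hba1c = 0.397,
    missing_frac_bmi = 0.109,
    # latent HbA1c trajectory after diagnosis:
    # mean(t) = asymptote + (baseline + start_offset - asymptote) * exp(-decay_rate * t)
    hba1c_trajectory = data.frame(
      subgroup = c("MARD", "MOD", "SHD"),
      start_offset = c(0.0, 0.0, 0.6),   # percent above recorded baseline
      decay_rate = c(0.6, 0.6, 2.5),     # 1/years
      asymptote = c(7.0, 7.1, 7.8),      # percent; SHD never reaches target
      obs_noise_sd = c(0.5, 0.5, 0.7),   # percent
      visits_per_year = c(2L, 2L, 3L)
    ),
    initiation_base_rate_noninsulin = 0.8,  # events/person-year for MARD ref
    initiation_base_rate_insulin = 0.02,
    initiation_log_hr = list(
      noninsulin = c(MARD = 0, MOD = log(1.16), SHD = log(1.92)),
      insulin    = c(MARD = 0, MOD = log(1.02), SHD = log(2.02))
    ),
    vascular_base_rate_macro = 0.015,
    vascular_base_rate_micro = 0.11,
    vascular_log_hr = list(
      macro = c(MARD = 0, MOD = log(1.50), SHD = log(1.30)),
      micro = c(MARD = 0, MOD = log(1.10), SHD = log(1.38))
    ),
    age_log_hr_per_year = 0.01,
    male_log_hr = 0.10,
    age_centre = 53.1,
    prevalent_macro_prob = c(MARD = 0.104, MOD = 0.079, SHD = 0.057),
    prevalent_micro_prob = c(MARD = 0.052, MOD = 0.050, SHD = 0.018),
    prevalent_rx_prob = c(noninsulin = 0.17, insulin = 0.14),
    baseline_initiator_frac = 0.05,
    hba1c_mmol_frac = 0.5,   # fraction of HbA1c observations recorded in mmol/mol
    aux_measures = data.frame(
      code = c("sbp", "dbp", "total_cholesterol", "egfr"),
      mean = c(134.7, 81.5, 5.2, 80.6),
      sd = c(18.3, 12.6, 1.2, 16.5),
      lower = c(60, 30, 1, 5),
      complete_frac = c(0.863, 0.863, 0.838, 0.721)
    ),
    study_start = as.Date("2008-01-01"),
    study_end = as.Date("2018-01-01"),
    followup_max_years = 10,
    admin_end_frac = 0.58,
    seed = as.integer(seed)
  )
  class(cfg) <- "t2d_generator_config"
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' @param config a `t2d_generator_config`.
#' @return the config, invisibly, if valid; otherwise an error.
#' @export
validate_generator_config <- function(config) {
  stopifnot(config$n_patients > 0)
  if (abs(sum(config$ethnicity_mix) - 1) > 1e-9) {
    stop("ethnicity_mix must sum to 1")
  }
  shares <- tapply(config$profiles$share, config$profiles$ethnicity, sum)
  if (any(abs(shares - 1) > 1e-9)) {
    stop("subgroup shares must sum to 1 within each ethnicity")
  }
  sds <- c(config$profiles$age_sd, config$profiles$hba1c_sd, config$profiles$bmi_sd)
  stopifnot(all(sds > 0))
  stopifnot(all(config$profiles$male_prob >= 0 & config$profiles$male_prob <= 1))
  stopifnot(config$missing_frac_hba1c >= 0, config$missing_frac_hba1c <= 1,
            config$missing_frac_bmi >= 0, config$missing_frac_bmi <= 1)
  stopifnot(config$initiation_base_rate_noninsulin > 0,
            config$initiation_base_rate_insulin > 0,
            config$vascular_base_rate_macro > 0,
            config$vascular_base_rate_micro > 0)
  invisible(config)
}
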