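test_that("default configuration carries the published calibration values", {
  cfg <- default_generator_config()
  prof <- cfg$profiles
  row <- function(e, s) prof[prof$ethnicity == e & prof$subgroup == s, ]
  expect_equal(row("white", "MARD")$age_mean, 71.7)
  expect_equal(row("white", "MARD")$age_sd, 8.2)
  expect_equal(row("black", "MOD")$male_prob, 0.075)
  expect_equal(row("south_asian", "MARD")$share, 0.842)
  expect_equal(row("south_asian", "MOD")$share, 0.085)
  expect_equal(row("south_asian", "SHD")$share, 0.073)
  expect_equal(row("black", "SHD")$hba1c_mean, 12.8)
  expect_equal(row("white", "MOD")$bmi_mean, 34.6)
  expect_equal(cfg$initiation_log_hr$noninsulin[["SHD"]], log(1.92))
  expect_equal(cfg$initiation_log_hr$noninsulin[["MOD"]], log(1.16))
  expect_equal(cfg$vascular_log_hr$macro[["MOD"]], log(1.50))
  expect_equal(cfg$vascular_log_hr$micro[["SHD"]], log(1.38))
  expect_equal(cfg$n_patients, 31931L)
  expect_no_error(validate_generator_config(cfg))
})

test_that("invalid configurations are rejected", {
  cfg <- default_generator_config(n_patients = 10)
  cfg$ethnicity_mix[1] <- cfg$ethnicity_mix[1] + 0.05
  expect_error(validate_generator_config(cfg), "ethnicity_mix")
  cfg <- default_generator_config(n_patients = 10)
  cfg$profiles$share[1] <- cfg$profiles$share[1] * 2
  expect_error(validate_generator_config(cfg), "shares")
})

test_that("sampling is deterministic under a fixed seed", {
  cfg <- small_config(n = 400)
  a <- simulate_cohort(cfg, seed = 9)
  b <- simulate_cohort(cfg, seed = 9)
  expect_identical(a, b)
  c2 <- simulate_cohort(cfg, seed = 10)
  expect_false(identical(a$patients, c2$patients))
})

test_that("degenerate mixture collapses to identical patients up to sex", {
  cfg <- degenerate_config(n = 150)
  drawn <- sample_patients(cfg, seed = 3)
  ind <- drawn$indicators
  expect_lt(diff(range(ind$age)), 1e-6)
  expect_lt(diff(range(ind$hba1c)), 1e-6)
  expect_lt(diff(range(ind$bmi)), 1e-6)
  expect_true(all(drawn$truth$subgroup == "MARD"))
  expect_gt(length(unique(ind$sex_male)), 1)
})

test_that("empirical subgroup shares track configured shares at n = 30000", {
  cfg <- default_generator_config(n_patients = 30000)
  drawn <- sample_patients(cfg, seed = 1)
  eth <- drawn$patients$ethnicity
  for (e in unique(eth)) {
    emp <- table(factor(drawn$truth$subgroup[eth == e],
                        levels = c("MARD", "MOD", "SHD"))) / sum(eth == e)
    conf <- cfg$profiles[cfg$profiles$ethnicity == e, ]
    expect_lt(max(abs(as.numeric(emp) - conf$share[match(names(emp), conf$subgroup)])),
              0.015)
  }
})

test_that("per-cell indicator means are calibrated within 2% relative error", {
  # the generator draws truncated normals, so the exact target mean is the
  # truncated-normal mean; n is large enough that the smallest
  # ethnicity-by-subgroup cell holds ~2000 patients and 2% is >3.5 SE,
  # comfortably absorbing the worst of 36 cells
  truncated_mean <- function(mu, sd, lower) {
    a <- (lower - mu) / sd
    mu + sd * dnorm(a) / (1 - pnorm(a))
  }
  cfg <- default_generator_config(n_patients = 300000)
  drawn <- sample_patients(cfg, seed = 1)
  key <- paste(drawn$patients$ethnicity, drawn$truth$subgroup)
  prof <- cfg$profiles
  lower <- c(age = 18, hba1c = 3.5, bmi = 13)
  for (i in seq_len(nrow(prof))) {
    sel <- key == paste(prof$ethnicity[i], prof$subgroup[i])
    for (v in c("age", "hba1c", "bmi")) {
      target <- truncated_mean(prof[[paste0(v, "_mean")]][i],
                               prof[[paste0(v, "_sd")]][i], lower[[v]])
      expect_lt(abs(mean(drawn$indicators[[v]][sel]) - target) / target,
                0.02, label = paste(prof$ethnicity[i], prof$subgroup[i], v))
    }
  }
})

test_that("flat noiseless trajectories return baseline plus offset", {
  cfg <- small_config(n = 50)
  cfg$hba1c_trajectory$obs_noise_sd <- 0
  cfg$hba1c_trajectory$decay_rate <- 0
  cfg$hba1c_mmol_frac <- 0
  drawn <- sample_patients(cfg, seed = 2)
  series <- sample_hba1c_series(drawn$patients, drawn$truth,
                                drawn$indicators$hba1c, cfg, seed = 2)
  # with decay 0 the latent mean stays at baseline + start_offset forever
  ti <- match(drawn$truth$subgroup[match(series$patient_id, drawn$truth$patient_id)],
              cfg$hba1c_trajectory$subgroup)
  expected <- drawn$indicators$hba1c[match(series$patient_id, drawn$patients$id)] +
    cfg$hba1c_trajectory$start_offset[ti]
  expect_equal(series$value, expected, tolerance = 1e-12)
})

test_that("severe-hyperglycaemia defaults fall >= 2 points in year one", {
  cfg <- default_generator_config(n_patients = 4000)
  drawn <- sample_patients(cfg, seed = 5)
  shd <- drawn$truth$subgroup == "SHD"
  series <- sample_hba1c_series(drawn$patients, drawn$truth,
                                drawn$indicators$hba1c, cfg, seed = 5)
  series <- normalise_hba1c(series)
  diag <- drawn$patients$diagnosis_date[match(series$patient_id, drawn$patients$id)]
  yr1 <- as.numeric(series$date - diag) < 365.25
  in_shd <- series$patient_id %in% drawn$patients$id[shd]
  baseline_mean <- mean(drawn$indicators$hba1c[shd])
  expect_gt(baseline_mean, 12)
  expect_lt(mean(series$value[yr1 & in_shd]), baseline_mean - 2)
})

test_that("zero visits per year yields an empty series", {
  cfg <- small_config(n = 30)
  cfg$hba1c_trajectory$visits_per_year <- 0L
  drawn <- sample_patients(cfg, seed = 2)
  series <- sample_hba1c_series(drawn$patients, drawn$truth,
                                drawn$indicators$hba1c, cfg, seed = 2)
  expect_equal(nrow(series), 0)
})

test_that("null hazards produce no incident events", {
  cfg <- small_config(n = 300)
  cfg$initiation_base_rate_noninsulin <- 1e-12
  cfg$initiation_base_rate_insulin <- 1e-12
  cfg$vascular_base_rate_macro <- 1e-12
  cfg$vascular_base_rate_micro <- 1e-12
  cfg$prevalent_rx_prob[] <- 0
  cfg$baseline_initiator_frac <- 0
  cfg$prevalent_macro_prob[] <- 0
  cfg$prevalent_micro_prob[] <- 0
  drawn <- sample_patients(cfg, seed = 4)
  ev <- sample_treatment_and_events(drawn$patients, drawn$truth, cfg, seed = 4)
  expect_equal(nrow(ev$prescriptions), 0)
  expect_equal(sum(ev$clinical_events$condition != "hypertension"), 0)
})

test_that("crude initiation is higher for SHD than MARD at configured rates", {
  cfg <- default_generator_config(n_patients = 20000)
  drawn <- sample_patients(cfg, seed = 6)
  ev <- sample_treatment_and_events(drawn$patients, drawn$truth, cfg, seed = 6)
  rx <- ev$prescriptions[ev$prescriptions$drug_class == "noninsulin_antidiabetic", ]
  diag <- drawn$patients$diagnosis_date[match(rx$patient_id, drawn$patients$id)]
  initiated <- unique(rx$patient_id[as.numeric(rx$date - diag) > -31])
  sub <- drawn$truth$subgroup
  p_init <- function(sg) {
    ids <- drawn$patients$id[sub == sg]
    mean(ids %in% initiated)
  }
  expect_gt(p_init("SHD"), p_init("MARD"))
})

test_that("crude event counts match the exponential-model expectation", {
  # binomial check of the generator's hazard calibration: expected event
  # probability per patient is 1 - exp(-rate * followup)
  cfg <- default_generator_config(n_patients = 20000)
  drawn <- sample_patients(cfg, seed = 8)
  ev <- sample_treatment_and_events(drawn$patients, drawn$truth, cfg, seed = 8)
  sub <- drawn$truth$subgroup
  fup <- as.numeric(drawn$patients$follow_up_end - drawn$patients$diagnosis_date) / 365.25
  lp <- cfg$age_log_hr_per_year * (drawn$patients$age_at_diagnosis - cfg$age_centre) +
    cfg$male_log_hr * drawn$patients$sex_male
  rate <- cfg$vascular_base_rate_macro * exp(cfg$vascular_log_hr$macro[sub] + lp)
  p <- 1 - exp(-rate * fup)
  macro <- ev$clinical_events[ev$clinical_events$condition %in%
                                c("chd", "mi", "stroke", "heart_failure"), ]
  diag <- drawn$patients$diagnosis_date[match(macro$patient_id, drawn$patients$id)]
  observed <- length(unique(macro$patient_id[macro$date > diag]))
  expected <- sum(p)
  expect_lt(abs(observed - expected), 3 * sqrt(sum(p * (1 - p))))
})

test_that("cohorts round-trip through CSV exactly", {
  cfg <- small_config(n = 1000)
  co <- simulate_cohort(cfg, seed = 11)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(co, dir)
  back <- read_cohort(dir)
  for (nm in c("patients", "observations", "clinical_events",
               "prescriptions", "truth")) {
    expect_equal(back[[nm]], co[[nm]], ignore_attr = TRUE, label = nm)
  }
  unlink(dir, recursive = TRUE)
})

test_that("an empty cohort writes five header-only files", {
  cfg <- small_config(n = 5)
  co <- simulate_cohort(cfg, seed = 1)
  empty <- lapply(co, function(t) t[0, , drop = FALSE])
  class(empty) <- "t2d_cohort"
  dir <- file.path(tempdir(), "cohort_empty")
  write_cohort(empty, dir)
  files <- list.files(dir)
  expect_setequal(files, c("patients.csv", "observations.csv",
                           "clinical_events.csv", "prescriptions.csv",
                           "truth.csv"))
  expect_true(all(vapply(file.path(dir, files),
                         function(f) length(readLines(f)) == 1, logical(1))))
  unlink(dir, recursive = TRUE)
})

test_that("malformed rows are reported with column and line number", {
  cfg <- small_config(n = 20)
  co <- simulate_cohort(cfg, seed = 1)
  dir <- file.path(tempdir(), "cohort_bad")
  write_cohort(co, dir)
  path <- file.path(dir, "observations.csv")
  lines <- readLines(path)
  parts <- strsplit(lines[3], ",")[[1]]
  parts[4] <- "not-a-number"
  lines[3] <- paste(parts, collapse = ",")
  writeLines(lines, path)
  expect_error(read_cohort(dir), "value.*line 3|column 'value'")
  unlink(dir, recursive = TRUE)
})

test_that("reading a directory with a missing table fails by name", {
  dir <- file.path(tempdir(), "cohort_missing")
  dir.create(dir, showWarnings = FALSE)
  expect_error(read_cohort(dir), "patients.csv")
  unlink(dir, recursive = TRUE)
})
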