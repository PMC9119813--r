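#' Per-patient yearly mean HbA1c over the five years after diagnosis
#'
#' Year `y` covers the half-open window
#' `[diagnosis + (y-1)*365.25, diagnosis + y*365.25)` days.  The yearly value
#' is the mean of all HbA1c observations (normalised to percent) falling in
#' the window; years with no observation are `NA`.  Observations after the
#' patient's follow-up end are excluded.
#'
#' @param observations observation table.
#' @param patients patient table (id, diagnosis_date, follow_up_end).
#' @param years how many post-diagnosis years to summarise.
#' @return data.frame: `id` then `year1` ... `year5` mean HbA1c percent,
#'   plus `n_obs_year1` ... counts.
#' @export
yearly_means <- function(observations, patients, years = 5) {
  obs <- normalise_hba1c(observations)
  obs <- obs[obs$code == "hba1c", , drop = FALSE]
  pidx <- match(obs$patient_id, patients$id)
  diag <- patients$diagnosis_date[pidx]
  fend <- patients$follow_up_end[pidx]
  days <- as.numeric(obs$date - diag)
  keep <- !is.na(days) & days >= 0 & obs$date <= fend
  obs <- obs[keep, , drop = FALSE]
  yr <- floor(days[keep] / DAYS_PER_YEAR) + 1

  out <- data.frame(id = patients$id, stringsAsFactors = FALSE)
  for (y in seq_len(years)) {
    sel <- yr == y
    sums <- tapply(obs$value[sel], obs$patient_id[sel], mean)
    cnts <- tapply(obs$value[sel], obs$patient_id[sel], length)
    out[[paste0("year", y)]] <- as.numeric(sums[match(patients$id, names(sums))])
    cnt <- as.integer(cnts[match(patients$id, names(cnts))])
    out[[paste0("n_obs_year", y)]] <- ifelse(is.na(cnt), 0L, cnt)
  }
  out
}

#' Subgroup-by-ethnicity HbA1c trajectory table
#'
#' Aggregates per-patient yearly means into the published figure's layout:
#' for each subgroup label, ethnicity panel (the three modelled ethnic
#' groups plus an `overall` panel) and year since diagnosis, the unweighted
#' mean over patients of their yearly means, on both the percent and
#' mmol/mol scales, with contributing patient and observation counts.
#' Averaging patient means (rather than pooling observations) stops
#' frequently measured patients dominating a cell.
#'
#' @param cohort a `t2d_cohort` (uses `observations` and `patients`).
#' @param assignments data.frame with `id` and `label` columns (subgroup
#'   labels for each patient).
#' @param years number of post-diagnosis years.
#' @return data.frame: `ethnicity`, `label`, `year`, `mean_hba1c_pct`,
#'   `mean_hba1c_mmol`, `n_patients`, `n_observations`.
#' @export
trajectory_table <- function(cohort, assignments, years = 5) {
  ym <- yearly_means(cohort$observations, cohort$patients, years)
  lab <- assignments$label[match(ym$id, assignments$id)]
  eth <- cohort$patients$ethnicity[match(ym$id, cohort$patients$id)]

  rows <- list()
  panels <- c("overall", sort(unique(eth)))
  for (panel in panels) {
    in_panel <- if (panel == "overall") rep(TRUE, nrow(ym)) else eth == panel
    for (l in sort(unique(stats::na.omit(lab)))) {
      sel <- in_panel & !is.na(lab) & lab == l
      for (y in seq_len(years)) {
        v <- ym[[paste0("year", y)]][sel]
        nobs <- ym[[paste0("n_obs_year", y)]][sel]
        ok <- !is.na(v)
        rows[[length(rows) + 1L]] <- data.frame(
          ethnicity = panel, label = l, year = y,
          mean_hba1c_pct = if (any(ok)) mean(v[ok]) else NA_real_,
          mean_hba1c_mmol = if (any(ok)) hba1c_percent_to_mmol(mean(v[ok])) else NA_real_,
          n_patients = sum(ok), n_observations = sum(nobs[ok]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
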