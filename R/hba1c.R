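#' Convert HbA1c between NGSP percent and IFCC mmol/mol
#'
#' Uses the standard NGSP/IFCC master equation
#' \eqn{mmol/mol = 10.929 \times (\% - 2.15)}.  The two conversions compose to
#' the identity on the valid domain.
#'
#' @param x_pct HbA1c on the NGSP percent scale; must be positive.
#' @return HbA1c on the IFCC mmol/mol scale.
#' @examples
#' hba1c_percent_to_mmol(12.1) # ~108.7
#' @export
hba1c_percent_to_mmol <- function(x_pct) {
  if (any(x_pct <= 0, na.rm = TRUE)) {
    stop("HbA1c percent values must be positive")
  }
  10.929 * (x_pct - 2.15)
}

#' @rdname hba1c_percent_to_mmol
#' @param x_mmol HbA1c on the IFCC mmol/mol scale; must be positive.
#' @export
hba1c_mmol_to_percent <- function(x_mmol) {
  if (any(x_mmol <= 0, na.rm = TRUE)) {
    stop("HbA1c mmol/mol values must be positive")
  }
  x_mmol / 10.929 + 2.15
}

#' Normalise HbA1c observations to the percent scale
#'
#' Observation tables may record HbA1c either as NGSP percent
#' (`unit == "percent"`) or IFCC mmol/mol (`unit == "mmol_per_mol"`); every
#' analysis in this package works on the percent scale.  Non-HbA1c rows are
#' passed through unchanged.
#'
#' @param observations observation table with columns `code`, `value`, `unit`.
#' @return the same table with all HbA1c rows in percent.
#' @export
normalise_hba1c <- function(observations) {
  is_mmol <- observations$code == "hba1c" & observations$unit == "mmol_per_mol"
  if (any(is_mmol)) {
    observations$value[is_mmol] <- hba1c_mmol_to_percent(observations$value[is_mmol])
    observations$unit[is_mmol] <- "percent"
  }
  bad <- observations$code == "hba1c" & observations$unit != "percent"
  if (any(bad)) {
    stop("unrecognised HbA1c unit: ", paste(unique(observations$unit[bad]), collapse = ", "))
  }
  observations
}
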