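#' Fit an external-standard calibration line
#'
#' Ordinary least squares of detector response on amount,
#' `area = slope * amount + intercept` (set `through_origin = TRUE` to force
#' a zero intercept). The valid range is the span of the standard amounts;
#' [quantify()] flags extrapolation beyond it.
#'
#' @param amount Numeric vector of standard amounts (at least 2 distinct).
#' @param area Numeric vector of detector responses, same length.
#' @param through_origin Force the intercept to zero.
#' @return Object of class `calibration_curve` with `slope`, `intercept`,
#'   `r_squared`, `range`, `n`.
#' @export
fit_calibration <- function(amount, area, through_origin = FALSE) {
  amount <- as.numeric(amount)
  area <- as.numeric(area)
  if (length(amount) != length(area)) {
    na_stop("amount and area lengths differ.", "bad_columns")
  }
  if (length(unique(amount)) < 2) {
    na_stop("calibration needs at least 2 distinct amounts.",
            "insufficient_data")
  }
  fit <- if (through_origin) stats::lm(area ~ 0 + amount) else
    stats::lm(area ~ amount)
  cf <- stats::coef(fit)
  slope <- unname(cf[["amount"]])
  intercept <- if (through_origin) 0 else unname(cf[["(Intercept)"]])
  if (slope == 0) {
    na_stop("fitted slope is zero; responses carry no amount signal.",
            "degenerate_input")
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((area - mean(area))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(slope = slope, intercept = intercept,
         r_squared = r2, range = range(amount), n = length(amount)),
    class = "calibration_curve"
  )
}

#' Predicted response of a calibration curve
#' @param curve A `calibration_curve`.
#' @param amount Amounts to predict at.
#' @return Predicted responses.
#' @export
predict_response <- function(curve, amount) {
  stopifnot(inherits(curve, "calibration_curve"))
  curve$slope * amount + curve$intercept
}

#' Invert a calibration curve to quantify an unknown
#'
#' `amount = (area - intercept) / slope`. Amounts outside the calibrated
#' range are returned but flagged via the `extrapolated` attribute and a
#' warning.
#'
#' @param area Detector response(s).
#' @param curve A `calibration_curve`.
#' @return Numeric amounts with logical attribute `extrapolated`.
#' @export
quantify <- function(area, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  amount <- (as.numeric(area) - curve$intercept) / curve$slope
  outside <- amount < curve$range[1] | amount > curve$range[2]
  if (any(outside)) {
    na_warn(paste0(sum(outside),
                   " amount(s) fall outside the calibrated range [",
                   curve$range[1], ", ", curve$range[2], "]."),
            "extrapolation")
  }
  attr(amount, "extrapolated") <- outside
  amount
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve> area = ", format(x$slope), " * amount + ",
      format(x$intercept), " (R2 = ", format(x$r_squared, digits = 4),
      ", n = ", x$n, ", range [", x$range[1], ", ", x$range[2], "])\n",
      sep = "")
  invisible(x)
}

#' Encapsulation efficiency from the process mass balance
#'
#' `EE% = 100 * (mif - muf) / mi0`, where `mi0` is the mass of compound
#' initially added, `mif` the mass recovered in the nanoparticle suspension,
#' and `muf` the mass found in the filtrate (the free, non-encapsulated
#' fraction). When the filtrate is below the detection limit pass
#' `muf = NA`: it is treated as zero and the result is flagged as a lower
#' bound (the true EE can only be larger).
#'
#' @param mi0 Initial mass (mg or any consistent unit), `> 0`.
#' @param mif Mass in the suspension, same unit.
#' @param muf Mass in the filtrate; `NA` means not detected.
#' @return EE in percent, with attribute `lower_bound` (TRUE when the
#'   filtrate was not detected).
#' @examples
#' encapsulation_efficiency(mi0 = 100, mif = 72, muf = NA)  # >= 72 %
#' @export
encapsulation_efficiency <- function(mi0, mif, muf = 0) {
  if (!is.finite(mi0) || mi0 <= 0) {
    na_stop("mi0 must be > 0 (division by the initial mass).",
            "division_by_zero")
  }
  lower_bound <- is.na(muf)
  if (lower_bound) muf <- 0
  if (mif < 0 || muf < 0) {
    na_stop("masses must be >= 0.", "invalid_mass")
  }
  if (mif > mi0 + 1e-9) {
    na_warn("mif exceeds mi0: mass balance is physically inconsistent.",
            "mass_balance")
  }
  if (muf > mif) {
    na_warn("muf exceeds mif: EE is negative; check the mass balance.",
            "mass_balance")
  }
  ee <- 100 * (mif - muf) / mi0
  attr(ee, "lower_bound") <- lower_bound
  ee
}

#' DPPH radical-scavenging percentage
#'
#' `%SR = 100 * (ABScontrol - ABSsample) / ABScontrol`, from absorbances at
#' 515 nm. The control is the blank formulation measured alongside each
#' sample.
#'
#' @param abs_sample Sample absorbance(s), dimensionless.
#' @param abs_control Control absorbance(s), `> 0`.
#' @return Scavenging percentage(s).
#' @export
dpph_scavenging <- function(abs_sample, abs_control) {
  if (any(!is.finite(abs_control)) || any(abs_control <= 0)) {
    na_stop("abs_control must be > 0.", "invalid_control")
  }
  100 * (abs_control - abs_sample) / abs_control
}

#' Coefficient of variation
#'
#' `CV% = 100 * sd / mean`. When `mean` and `sd` are supplied directly (as
#' in published mean +/- sd tables) they are used as given; compute `sd`
#' with the sample convention when starting from replicates.
#'
#' @param mean Mean value(s), nonzero.
#' @param sd Standard deviation(s), `>= 0`.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(mean, sd) {
  if (any(!is.finite(mean)) || any(mean == 0)) {
    na_stop("mean must be nonzero.", "division_by_zero")
  }
  if (any(!is.finite(sd)) || any(sd < 0)) {
    na_stop("sd must be >= 0.", "invalid_sd")
  }
  100 * sd / mean
}
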