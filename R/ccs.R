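# Traveling-wave ion-mobility CCS calibration.
#
# The calibration relation is the standard TWIMS power law
#   Omega = A * t_D^B * z * sqrt(1/m_ion + 1/m_gas)
# with A the calibration constant, B the experimentally determined
# exponential factor, t_D the corrected drift time, and m_gas the mass of
# the drift gas (N2).  Fitting is linear regression of log(Omega') on
# log(t_D), where Omega' = Omega / (z * sqrt(1/m_ion + 1/m_gas)).

.N2_GAS_MASS <- 28.0134  # average molecular mass of N2, Da

#' Fit a TWIMS CCS calibration
#'
#' @param calibrants data.frame with columns `t_d` (corrected drift time,
#'   any consistent unit), `z` (charge), `m_ion` (ion mass, Da), `ccs_ref`
#'   (reference collision cross section, A^2).
#' @param gas_mass drift-gas molecular mass in Da (N2 default).
#' @return object of class `ccs_calibration` with fields `A`, `B`,
#'   `gas_mass`, `calibrants`, `residuals` (relative, on the CCS scale).
#' @export
fit_ccs_calibration <- function(calibrants, gas_mass = .N2_GAS_MASS) {
  req <- c("t_d", "z", "m_ion", "ccs_ref")
  missing_cols <- setdiff(req, names(calibrants))
  if (length(missing_cols))
    stop("calibrant table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(calibrants) < 2L) stop("need at least 2 calibrants")
  if (any(calibrants$t_d <= 0)) stop("non-positive drift time in calibrants")
  if (any(calibrants$ccs_ref <= 0)) stop("non-positive reference CCS")
  red <- calibrants$ccs_ref /
    (calibrants$z * sqrt(1 / calibrants$m_ion + 1 / gas_mass))
  fit <- stats::lm(log(red) ~ log(calibrants$t_d))
  A <- exp(unname(coef(fit)[1L]))
  B <- unname(coef(fit)[2L])
  pred <- ccs_from_drift(calibrants$t_d, calibrants$z, calibrants$m_ion,
                         structure(list(A = A, B = B, gas_mass = gas_mass),
                                   class = "ccs_calibration"))
  structure(list(A = A, B = B, gas_mass = gas_mass,
                 calibrants = calibrants,
                 residuals = pred / calibrants$ccs_ref - 1),
            class = "ccs_calibration")
}

#' Apply a CCS calibration to corrected drift times
#'
#' @param t_d corrected drift time(s), positive.
#' @param z charge state(s).
#' @param m_ion ion mass(es), Da.
#' @param calibration a [fit_ccs_calibration()] object (or any list with
#'   `A`, `B`, `gas_mass`).
#' @return CCS in A^2.
#' @export
ccs_from_drift <- function(t_d, z, m_ion, calibration) {
  if (any(t_d <= 0)) stop("non-positive drift time")
  calibration$A * t_d^calibration$B * z *
    sqrt(1 / m_ion + 1 / calibration$gas_mass)
}

#' @export
print.ccs_calibration <- function(x, ...) {
  cat(sprintf("TWIMS CCS calibration: A = %.6g, B = %.6g (gas %.4f Da)\n",
              x$A, x$B, x$gas_mass))
  cat(sprintf("  %d calibrants, max |relative residual| = %.3g\n",
              nrow(x$calibrants), max(abs(x$residuals))))
  invisible(x)
}
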