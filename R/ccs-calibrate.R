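## Traveling-wave IMS CCS calibration: EDC-corrected drift times, reduced
## literature CCS, power-law log-log fit, and application to assigned
## features with first-order uncertainty propagation.

#' EDC-corrected drift time
#'
#' Removes the mass-dependent transit delay outside the mobility cell:
#' `t' = t_D - c * sqrt(m/z) / 1000`.
#'
#' @param t_d Measured drift time (ms), positive.
#' @param mz m/z of the ion (Th).
#' @param edc_coefficient Instrument EDC delay coefficient (default 1.41).
#' @return Corrected drift time t' (ms). Errors if the correction exceeds
#'   the drift time.
#' @export
corrected_drift <- function(t_d, mz, edc_coefficient = 1.41) {
  stopifnot(all(t_d > 0), all(mz > 0))
  tp <- t_d - edc_coefficient * sqrt(mz) / 1000
  if (any(tp <= 0)) stop("EDC correction exceeds drift time")
  tp
}

#' Reduced (charge/mass-normalized) CCS
#'
#' `Omega' = Omega / (z * sqrt(1/m_ion + 1/m_gas))`, the quantity that
#' follows the power law in corrected drift time.
#'
#' @param ccs Literature CCS (Angstrom^2).
#' @param z Charge.
#' @param ion_mass Ion mass (Da).
#' @param gas_mass Drift gas mass (Da); default nitrogen.
#' @return Reduced CCS.
#' @export
reduced_ccs <- function(ccs, z, ion_mass, gas_mass = N2_MASS) {
  stopifnot(all(ccs > 0), all(z > 0), all(ion_mass > 0), gas_mass > 0)
  ccs / (z * sqrt(1 / ion_mass + 1 / gas_mass))
}

#' Calibrant table constructor
#'
#' @param name Calibrant identifiers.
#' @param z Charge states.
#' @param mass_da Ion masses (Da).
#' @param ccs_a2 Literature CCS values (Angstrom^2).
#' @param td_ms Measured drift times (ms).
#' @param gas Drift-gas tag (default `"N2"`).
#' @return Data frame of class `"calibrant_table"`.
#' @export
calibrant_table <- function(name, z, mass_da, ccs_a2, td_ms, gas = "N2") {
  stopifnot(all(z > 0), all(mass_da > 0), all(ccs_a2 > 0), all(td_ms > 0))
  out <- data.frame(name = name, z = z, mass_da = mass_da,
                    ccs_a2 = ccs_a2, td_ms = td_ms, gas = gas)
  class(out) <- c("calibrant_table", "data.frame")
  out
}

#' Read a calibrant table from CSV
#'
#' Expected columns: `name, z, mass_da, ccs_a2, td_ms` (optional `gas`).
#' @param path CSV path.
#' @return A [calibrant_table()].
#' @export
read_calibrants <- function(path) {
  tab <- utils::read.csv(path)
  calibrant_table(tab$name, tab$z, tab$mass_da, tab$ccs_a2, tab$td_ms,
                  gas = if ("gas" %in% names(tab)) tab$gas else "N2")
}

#' Fit the traveling-wave power-law calibration
#'
#' Ordinary least squares of `ln Omega'` on `ln t'` across the calibrants,
#' giving `Omega' = A * t'^B`.
#'
#' @param entries A [calibrant_table()] (>= 3 rows spanning distinct
#'   corrected drift times).
#' @param edc_coefficient EDC delay coefficient applied to the drift times.
#' @param gas_mass Drift gas mass (Da).
#' @return An object of class `"ccs_calibration"`: coefficients `A`, `B`,
#'   the EDC coefficient and gas mass used, `r2` of the log-log fit,
#'   per-calibrant residuals (in ln Omega'), and the coefficient covariance.
#' @export
fit_calibration <- function(entries, edc_coefficient = 1.41, gas_mass = N2_MASS) {
  stopifnot(inherits(entries, "data.frame"))
  if (nrow(entries) < 3) stop("need at least 3 calibrant entries")
  tp <- corrected_drift(entries$td_ms, (entries$mass_da + entries$z * PROTON_MASS) / entries$z,
                        edc_coefficient)
  if (length(unique(tp)) < 3) stop("calibrants must span at least 3 distinct corrected drift times")
  om <- reduced_ccs(entries$ccs_a2, entries$z, entries$mass_da, gas_mass)
  if (any(!is.finite(log(tp))) || any(!is.finite(log(om)))) {
    stop("non-finite values in the log-log calibration")
  }
  fit <- stats::lm(log(om) ~ log(tp))
  coefs <- stats::coef(fit)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(
    A = exp(unname(coefs[1])), B = unname(coefs[2]),
    edc_coefficient = edc_coefficient, gas_mass = gas_mass,
    r2 = r2, residuals = stats::setNames(stats::residuals(fit), entries$name),
    vcov = suppressWarnings(stats::vcov(fit)), n_calibrants = nrow(entries)
  ), class = "ccs_calibration")
}

#' @export
print.ccs_calibration <- function(x, ...) {
  cat(sprintf("TWIMS CCS calibration: Omega' = %.6g * t'^%.6g  (R^2 = %.6f, %d calibrants, EDC %.3g)\n",
              x$A, x$B, x$r2, x$n_calibrants, x$edc_coefficient))
  invisible(x)
}

#' @export
coef.ccs_calibration <- function(object, ...) {
  c(A = object$A, B = object$B)
}

#' Predict CCS from a fitted calibration
#'
#' @param object A `"ccs_calibration"`.
#' @param td_ms Measured drift times (ms).
#' @param mz m/z values (for the EDC correction).
#' @param z Charges.
#' @param ion_mass Ion masses (Da).
#' @param ... Unused.
#' @return CCS values (Angstrom^2):
#'   `A * t'^B * z * sqrt(1/m_ion + 1/m_gas)`.
#' @export
predict.ccs_calibration <- function(object, td_ms, mz, z, ion_mass, ...) {
  tp <- corrected_drift(td_ms, mz, object$edc_coefficient)
  object$A * tp^object$B * z * sqrt(1 / ion_mass + 1 / object$gas_mass)
}

#' Apply a calibration to assigned features
#'
#' Converts each assigned feature's drift centroid to a calibrated CCS with
#' first-order propagated uncertainty from the drift-centroid uncertainty
#' and the fit's coefficient covariance.
#'
#' @param fit A `"ccs_calibration"`; refused (configurably) when its R^2 is
#'   below `min_r2`.
#' @param features Assigned feature table (needs columns `drift_ms`, `mz`,
#'   `z`, `n`).
#' @param peptide Monomer sequence or composition (for ion masses).
#' @param td_sigma_ms Drift-centroid uncertainty (ms), scalar or per
#'   feature.
#' @param min_r2 Minimum acceptable calibration R^2 (default 0.98); set to
#'   0 to disable the guard.
#' @param mass_convention Mass convention for ion masses.
#' @return The feature table with `ccs_a2` and `ccs_sigma` columns added.
#'   Unassigned features error.
#' @export
apply_calibration <- function(fit, features, peptide, td_sigma_ms = 0,
                              min_r2 = 0.98,
                              mass_convention = "monoisotopic") {
  stopifnot(inherits(fit, "ccs_calibration"))
  if (fit$r2 < min_r2) {
    stop(sprintf("calibration R^2 = %.4f below the acceptance floor %.2f", fit$r2, min_r2))
  }
  if (any(is.na(features$n)) || any(is.na(features$z))) {
    stop("all features must be assigned before calibration is applied")
  }
  comp <- if (is.character(peptide)) composition_from_sequence(peptide) else as_composition(peptide)
  m1 <- if (mass_convention == "average") average_mass(comp) else monoisotopic_mass(comp)
  ion_mass <- features$n * m1
  tp <- corrected_drift(features$drift_ms, features$mz, fit$edc_coefficient)
  scale <- features$z * sqrt(1 / ion_mass + 1 / fit$gas_mass)
  ccs <- fit$A * tp^fit$B * scale
  ## d(ln Omega) = d(ln A) + ln(t') dB + B/t' dt'
  td_sigma_ms <- rep_len(td_sigma_ms, nrow(features))
  g <- cbind(1, log(tp))  # gradient wrt (ln A, B)
  var_fit <- rowSums((g %*% fit$vcov) * g)
  var_td <- (fit$B / tp)^2 * td_sigma_ms^2
  features$ccs_a2 <- ccs
  features$ccs_sigma <- ccs * sqrt(var_fit + var_td)
  features
}

#' Serialize / restore a calibration fit as JSON
#' @param fit A `"ccs_calibration"`.
#' @param path JSON path.
#' @export
write_calibration <- function(fit, path) {
  jsonlite::write_json(list(A = fit$A, B = fit$B,
                            edc_coefficient = fit$edc_coefficient,
                            gas_mass = fit$gas_mass, r2 = fit$r2,
                            vcov = fit$vcov,
                            n_calibrants = fit$n_calibrants),
                       path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(A = x$A, B = x$B, edc_coefficient = x$edc_coefficient,
                 gas_mass = x$gas_mass, r2 = x$r2,
                 residuals = NULL, vcov = matrix(unlist(x$vcov), 2, 2),
                 n_calibrants = x$n_calibrants),
            class = "ccs_calibration")
}

#' Unit converters for CCS values
#' @param x CCS in Angstrom^2 (or nm^2 for the inverse).
#' @return Converted value.
#' @export
a2_to_nm2 <- function(x) x / 100

#' @rdname a2_to_nm2
#' @export
nm2_to_a2 <- function(x) x * 100
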