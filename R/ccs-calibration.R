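# Travelling-wave ion mobility CCS calibration: power-law fit between
# corrected drift time and reduced CCS from calibrant proteins of known
# cross section, and its application (with uncertainty) to analytes.

.N2_MASS <- 28.013  # average mass of the N2 drift gas, Da

#' Correct a measured drift time for m/z-dependent flight time
#'
#' t' = t_D - c * sqrt(m/z) / 1000, with the enhanced-duty-cycle constant
#' c in the instrument-conventional unit such that the correction comes
#' out in ms for m/z in Thomson.
#'
#' @param t_d Measured drift time, ms.
#' @param mz m/z in Thomson.
#' @param c Instrument constant (default 1.41; always check against the
#'   value of the instrument that produced the data).
#' @return Corrected drift time t' in ms.
#' @export
correct_drift <- function(t_d, mz, c = 1.41) {
  stopifnot(all(t_d > 0), all(mz > 0), c >= 0)
  tp <- t_d - c * sqrt(mz) / 1000
  if (any(tp <= 0))
    stop("corrected drift time <= 0 (non-physical); check c and units")
  tp
}

#' Reduce a CCS for charge and reduced mass
#'
#' Omega' = ccs / (z * sqrt(1/m_ion + 1/gas_mass)). Strictly increasing
#' in ccs; inverts exactly with [unreduce_ccs()].
#'
#' @param ccs Cross section in Angstrom^2.
#' @param z Integer charge.
#' @param m_ion Ion mass in Da.
#' @param gas_mass Drift gas mass in Da (default N2, 28.013).
#' @return Reduced CCS Omega'.
#' @export
reduce_ccs <- function(ccs, z, m_ion, gas_mass = .N2_MASS) {
  stopifnot(all(ccs > 0), all(z > 0), all(m_ion > 0), gas_mass > 0)
  ccs / (z * sqrt(1 / m_ion + 1 / gas_mass))
}

#' @rdname reduce_ccs
#' @param ccs_reduced Reduced CCS Omega'.
#' @export
unreduce_ccs <- function(ccs_reduced, z, m_ion, gas_mass = .N2_MASS) {
  stopifnot(all(ccs_reduced > 0), all(z > 0), all(m_ion > 0), gas_mass > 0)
  ccs_reduced * z * sqrt(1 / m_ion + 1 / gas_mass)
}

#' Fit the travelling-wave power-law calibration
#'
#' Unweighted least squares of ln(Omega') on ln(t') over the calibrant
#' entries, giving Omega' = A * t'^B. Calibrants are typically the lower
#' charge states of native protein standards spanning the analyte m/z
#' range (e.g. beta-lactoglobulin through glutamate dehydrogenase,
#' 18-336 kDa).
#'
#' @param entries data.frame with columns `mass` (neutral, Da), `z`,
#'   `reference_ccs` (Angstrom^2) and `drift` (measured t_D, ms); an
#'   optional `name` column is carried through to the residual table.
#' @param c Drift-time correction constant, see [correct_drift()].
#' @param gas_mass Drift gas mass in Da.
#' @return Object of class `calibration_fit` with fields `A`, `B`, `c`,
#'   `gas_mass`, `r_squared`, `residuals` (per-calibrant table) and
#'   `tprime_range`.
#' @export
fit_calibration <- function(entries, c = 1.41, gas_mass = .N2_MASS) {
  need <- c("mass", "z", "reference_ccs", "drift")
  if (!all(need %in% names(entries)))
    stop("calibrant table must have columns: ", paste(need, collapse = ", "))
  if (nrow(entries) < 2)
    stop("need at least 2 calibrant entries, got ", nrow(entries))
  if (any(entries$z <= 0) || any(entries$reference_ccs <= 0) ||
      any(entries$mass <= 0) || any(entries$drift <= 0))
    stop("non-physical calibrant row (mass, z, reference_ccs, drift must be > 0)")
  m_ion <- entries$mass + entries$z * .PROTON_MASS
  tprime <- correct_drift(entries$drift, mz_of(entries$mass, z = entries$z), c = c)
  if (length(unique(signif(tprime, 12))) < 2)
    stop("calibrant corrected drift times are coincident; cannot fit")
  omega_red <- reduce_ccs(entries$reference_ccs, entries$z, m_ion, gas_mass)
  fit <- lm(log(omega_red) ~ log(tprime))
  A <- exp(unname(coef(fit)[1]))
  B <- unname(coef(fit)[2])
  res <- data.frame(
    name = if ("name" %in% names(entries)) entries$name else seq_len(nrow(entries)),
    tprime = tprime,
    reference_ccs = entries$reference_ccs,
    fitted_ccs = unreduce_ccs(A * tprime^B, entries$z, m_ion, gas_mass),
    stringsAsFactors = FALSE)
  res$residual_log <- log(omega_red) - (log(A) + B * log(tprime))
  ss_tot <- sum((log(omega_red) - mean(log(omega_red)))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res$residual_log^2) / ss_tot else 1
  structure(list(A = A, B = B, c = c, gas_mass = gas_mass,
                 r_squared = r2, residuals = res,
                 sigma_log = if (nrow(entries) > 2)
                   sqrt(sum(res$residual_log^2) / (nrow(entries) - 2)) else 0,
                 tprime_range = range(tprime)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> Omega' = %.4g * t'^%.4f  (r2 = %.6f, %d calibrants, t' in [%.3g, %.3g] ms)\n",
              x$A, x$B, x$r_squared, nrow(x$residuals),
              x$tprime_range[1], x$tprime_range[2]))
  invisible(x)
}

#' Apply a calibration to analyte drift times
#'
#' ccs = A * t'^B * z * sqrt(1/m_ion + 1/gas_mass). The relative
#' uncertainty is propagated from the residual spread of the fit on the
#' log scale. Analytes whose corrected drift time falls outside the
#' calibrant range are flagged `extrapolated` (returned, not rejected).
#'
#' @param fit A [fit_calibration()] result.
#' @param t_d Measured drift time(s), ms.
#' @param mz m/z of the analyte peak(s), Th.
#' @param z Charge(s).
#' @param m_ion Ion mass(es), Da; defaults to `z * mz` (adequate at high m/z).
#' @return data.frame with columns `ccs`, `ccs_se`, `tprime`, `extrapolated`.
#' @export
apply_calibration <- function(fit, t_d, mz, z, m_ion = NULL) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (is.null(m_ion)) m_ion <- z * mz
  tprime <- correct_drift(t_d, mz, c = fit$c)
  ccs <- unreduce_ccs(fit$A * tprime^fit$B, z, m_ion, fit$gas_mass)
  data.frame(
    ccs = ccs,
    ccs_se = ccs * fit$sigma_log,
    tprime = tprime,
    extrapolated = tprime < fit$tprime_range[1] | tprime > fit$tprime_range[2])
}

#' Predict a drift time from a true CCS (calibration inverse)
#'
#' Inverts the power law: t' = (Omega'/A)^(1/B), t_D = t' + c*sqrt(mz)/1000.
#' This is how the synthetic data generator turns ground-truth CCS values
#' into drift times, guaranteeing an exact round trip at zero noise.
#'
#' @param A,B Power-law scale and exponent.
#' @param ccs True CCS, Angstrom^2.
#' @param mz,z,m_ion Ion coordinates as in [apply_calibration()].
#' @param c,gas_mass Instrument constants.
#' @return Drift time t_D in ms.
#' @export
drift_from_ccs <- function(A, B, ccs, mz, z, m_ion = NULL,
                           c = 1.41, gas_mass = .N2_MASS) {
  stopifnot(A > 0, B > 0)
  if (is.null(m_ion)) m_ion <- z * mz
  omega_red <- reduce_ccs(ccs, z, m_ion, gas_mass)
  (omega_red / A)^(1 / B) + c * sqrt(mz) / 1000
}

#' Serialize / restore a calibration fit as JSON
#'
#' @param fit A `calibration_fit`.
#' @param path Output (input) file path.
#' @return `read_calibration()` returns the restored `calibration_fit`.
#' @export
write_calibration <- function(fit, path) {
  stopifnot(inherits(fit, "calibration_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$residuals <- as.data.frame(x$residuals)
  structure(x, class = "calibration_fit")
}
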