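#' Correct pH from analyzer temperature to animal temperature
#'
#' Applies the linear pH temperature correction
#' \deqn{pH(T) = pH_I - 0.0147 (T - 37) + 0.0065 (7.4 - pH_I)(T - 37)}
#' where `ph_i` is the analyzer reading at 37 degrees C and `ta` the target
#' temperature (conventionally the mean daily air temperature for field
#' samples; any temperature, e.g. cloacal, may be supplied).
#'
#' Missing inputs propagate to missing outputs. Values outside the
#' physiologic windows (pH in (0, 14), temperature in \[-10, 45\] degrees C)
#' raise a warning, not an error; non-finite inputs other than `NA` are
#' rejected.
#'
#' @param ph_i Numeric vector of analyzer pH values (37 degrees C scale).
#' @param ta Numeric vector of target temperatures, degrees C.
#' @return Numeric vector of temperature-corrected pH values.
#' @export
#' @examples
#' correct_ph(7.30, 20)
correct_ph <- function(ph_i, ta) {
  check_physiologic(ph_i, "ph_i", c(0, 14))
  check_physiologic(ta, "ta", c(-10, 45))
  cc <- correction_constants()
  dt <- ta - cc$analyzer_temp
  ph_i - cc$ph_coeffs[1] * dt + cc$ph_coeffs[2] * (cc$reference_ph - ph_i) * dt
}

#' Correct pO2 from analyzer temperature to animal temperature
#'
#' Applies the exponential pO2 correction
#' \eqn{pO_2(T) = pO_{2,I} \times 10^{-0.0058 (T - 37)}}. The exponent sign
#' follows the published sea-turtle correction as printed: corrected pO2
#' rises as temperature falls below 37 degrees C.
#'
#' @param po2_i Numeric vector of analyzer pO2 values, mmHg.
#' @inheritParams correct_ph
#' @return Numeric vector of temperature-corrected pO2, mmHg.
#' @export
correct_po2 <- function(po2_i, ta) {
  check_physiologic(po2_i, "po2_i", c(0, Inf))
  check_physiologic(ta, "ta", c(-10, 45))
  cc <- correction_constants()
  po2_i * 10^(cc$po2_exp_coeff * (ta - cc$analyzer_temp))
}

#' Correct pCO2 from analyzer temperature to animal temperature
#'
#' Applies \eqn{pCO_2(T) = pCO_{2,I} \times 10^{0.0019 (T - 37)}}.
#'
#' @param pco2_i Numeric vector of analyzer pCO2 values, mmHg.
#' @inheritParams correct_ph
#' @return Numeric vector of temperature-corrected pCO2, mmHg.
#' @export
correct_pco2 <- function(pco2_i, ta) {
  check_physiologic(pco2_i, "pco2_i", c(0, Inf))
  check_physiologic(ta, "ta", c(-10, 45))
  cc <- correction_constants()
  pco2_i * 10^(cc$pco2_exp_coeff * (ta - cc$analyzer_temp))
}

#' CO2 plasma solubility coefficient at a given temperature
#'
#' Cubic polynomial in temperature, derived for sea-turtle plasma; strictly
#' positive over 0--45 degrees C. At 37 degrees C it evaluates to about
#' 0.0307 mmol/l/mmHg, matching the accepted human plasma CO2 solubility.
#'
#' @inheritParams correct_ph
#' @return Numeric vector, mmol/l/mmHg.
#' @export
#' @examples
#' alpha_co2(37)
alpha_co2 <- function(ta) {
  check_physiologic(ta, "ta", c(-10, 45))
  eval_poly(correction_constants()$alpha_poly, ta)
}

#' Apparent carbonic-acid pKa at a given pH and temperature
#'
#' The pKa of the bicarbonate buffer system used in the
#' Henderson-Hasselbalch recomputation: a cubic polynomial in temperature
#' minus a base-10 logarithmic term in the (already temperature-corrected)
#' pH and temperature,
#' \deqn{pKa = P(T) - \log_{10}\frac{1.011 + 10^{pH + 0.011 T - 10.241}}
#'                                  {1 + 10^{pH + 0.001 T - 8.889}}.}
#' The quotient grouping of the log term is implemented in
#' [pka_log_quotient()] so it can be swapped independently if a different
#' reading of the source formula is preferred.
#'
#' @param ph_ta Numeric vector of temperature-corrected pH values.
#' @inheritParams correct_ph
#' @return Numeric vector of pKa values (dimensionless).
#' @export
#' @examples
#' pka_co2(7.50, 20)
pka_co2 <- function(ph_ta, ta) {
  check_physiologic(ta, "ta", c(-10, 45))
  eval_poly(correction_constants()$pka_poly, ta) -
    log10(pka_log_quotient(ph_ta, ta))
}

#' Quotient inside the pKa logarithmic term
#'
#' @inheritParams pka_co2
#' @return Numeric vector, the dimensionless quotient whose log10 is
#'   subtracted from the pKa polynomial.
#' @export
pka_log_quotient <- function(ph_ta, ta) {
  k <- correction_constants()$pka_log_constants
  (k[1] + 10^(ph_ta + k[2] * ta - k[3])) / (1 + 10^(ph_ta + k[4] * ta - k[5]))
}

#' Bicarbonate from the Henderson-Hasselbalch relation
#'
#' \eqn{HCO_3^- = \alpha_{CO_2} \, pCO_2 \, 10^{pH - pKa}}, all quantities at
#' the same (corrected) temperature.
#'
#' @param alpha CO2 solubility coefficient, mmol/l/mmHg.
#' @param pco2_c Temperature-corrected pCO2, mmHg.
#' @param ph_c Temperature-corrected pH.
#' @param pka_val Apparent pKa at the corrected pH and temperature.
#' @return Bicarbonate concentration, mmol/l.
#' @export
hco3_from_hh <- function(alpha, pco2_c, ph_c, pka_val) {
  alpha * pco2_c * 10^(ph_c - pka_val)
}

#' Total CO2 as bicarbonate plus dissolved CO2
#'
#' \eqn{TCO_2 = HCO_3^- + \alpha_{CO_2} \, pCO_2}.
#'
#' @param hco3_c Bicarbonate, mmol/l.
#' @inheritParams hco3_from_hh
#' @return Total CO2, mmol/l.
#' @export
tco2_from_hh <- function(hco3_c, alpha, pco2_c) {
  hco3_c + alpha * pco2_c
}

#' Temperature-correct the blood-gas panel of a cohort
#'
#' Takes a cohort data frame carrying analyzer-scale panel columns (`ph_i`,
#' `po2_i`, `pco2_i`, `be_i`, `lactate_i`) and a per-animal temperature
#' column, and appends the corrected panel: `ph_c`, `po2_c`, `pco2_c`,
#' `alpha_co2`, `pka`, `hco3_c`, `tco2_c`, `be`, `lactate`.
#'
#' Bicarbonate and total CO2 are recomputed from the corrected pH and pCO2
#' through the Henderson-Hasselbalch relation; they are not temperature
#' rescalings of the device's own (human-algorithm) HCO3/TCO2 output. Base
#' excess cannot be recomputed without a hemoglobin measurement, so `be` is
#' the raw analyzer value, and `lactate` is temperature-independent; both are
#' copied through. A corrected field is `NA` exactly when an analyzer field
#' it depends on is `NA`.
#'
#' @param data Data frame with analyzer panel columns and `ta_col`.
#' @param ta_col Name of the temperature column (degrees C). Default
#'   `"ta_c"`, the mean daily air temperature.
#' @return The input as a tibble with the nine corrected columns appended.
#' @export
#' @examples
#' df <- tibble::tibble(ph_i = 7.3, po2_i = 50, pco2_i = 40,
#'                      be_i = 2, lactate_i = 1.5, ta_c = 20)
#' correct_panel(df)
correct_panel <- function(data, ta_col = "ta_c") {
  stopifnot(is.data.frame(data))
  need <- c("ph_i", "po2_i", "pco2_i", "be_i", "lactate_i", ta_col)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("correct_panel(): missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ta <- data[[ta_col]]
  if (anyNA(ta)) {
    bad <- which(is.na(ta))
    stop("correct_panel(): temperature ('", ta_col, "') is missing for row(s) ",
         paste(head(bad, 10), collapse = ", "),
         "; a target temperature is required for every panel.", call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  out$ph_c <- correct_ph(out$ph_i, ta)
  out$po2_c <- correct_po2(out$po2_i, ta)
  out$pco2_c <- correct_pco2(out$pco2_i, ta)
  out$alpha_co2 <- alpha_co2(ta)
  out$pka <- pka_co2(out$ph_c, ta)
  out$hco3_c <- hco3_from_hh(out$alpha_co2, out$pco2_c, out$ph_c, out$pka)
  out$tco2_c <- tco2_from_hh(out$hco3_c, out$alpha_co2, out$pco2_c)
  out$be <- out$be_i
  out$lactate <- out$lactate_i
  out
}

#' Map a corrected panel back to analyzer (37 degrees C) scale
#'
#' Exact algebraic inverse of the correction equations, used by the
#' synthetic-cohort generator: true values are simulated on the corrected
#' (animal-temperature) scale and mapped to the instrument scale so that the
#' correction stage is exercised nontrivially.
#'
#' The pH inverse solves the linear correction for `ph_i`; pO2 and pCO2
#' divide out their decadic factors. Analyzer-scale bicarbonate and total
#' CO2 are regenerated at 37 degrees C from the inverted pH and pCO2 through
#' the same Henderson-Hasselbalch machinery (formula-consistent rather than
#' imitating the device's undisclosed human algorithm). `be` and `lactate`
#' are copied through.
#'
#' @param data Data frame with corrected columns `ph_c`, `po2_c`, `pco2_c`,
#'   `be`, `lactate` and the temperature column.
#' @inheritParams correct_panel
#' @return The input as a tibble with analyzer columns `ph_i`, `po2_i`,
#'   `pco2_i`, `hco3_i`, `tco2_i`, `be_i`, `lactate_i` appended.
#' @export
invert_panel <- function(data, ta_col = "ta_c") {
  stopifnot(is.data.frame(data))
  need <- c("ph_c", "po2_c", "pco2_c", "be", "lactate", ta_col)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("invert_panel(): missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cc <- correction_constants()
  ta <- data[[ta_col]]
  dt <- ta - cc$analyzer_temp
  denom <- 1 - cc$ph_coeffs[2] * dt
  if (any(abs(denom) < 1e-12, na.rm = TRUE)) {
    stop("invert_panel(): pH correction not invertible at the supplied ",
         "temperature (1 - 0.0065 * (ta - 37) = 0).", call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  out$ph_i <- (out$ph_c - (-cc$ph_coeffs[1] + cc$ph_coeffs[2] * cc$reference_ph) * dt) / denom
  out$po2_i <- out$po2_c / 10^(cc$po2_exp_coeff * dt)
  out$pco2_i <- out$pco2_c / 10^(cc$pco2_exp_coeff * dt)
  alpha37 <- alpha_co2(cc$analyzer_temp)
  pka37 <- pka_co2(out$ph_i, cc$analyzer_temp)
  out$hco3_i <- hco3_from_hh(alpha37, out$pco2_i, out$ph_i, pka37)
  out$tco2_i <- tco2_from_hh(out$hco3_i, alpha37, out$pco2_i)
  out$be_i <- out$be
  out$lactate_i <- out$lactate
  out
}

# ascending-coefficient polynomial evaluation (Horner)
eval_poly <- function(coefs, x) {
  acc <- rep(coefs[length(coefs)], length(x))
  for (i in rev(seq_len(length(coefs) - 1))) {
    acc <- acc * x + coefs[i]
  }
  acc
}

# physiologic windows are advisory (field data contain extremes): warn on
# out-of-window values, error only on non-finite non-NA input
check_physiologic <- function(x, name, window) {
  if (!is.numeric(x)) {
    stop("'", name, "' must be numeric.", call. = FALSE)
  }
  if (any(!is.na(x) & !is.finite(x))) {
    stop("'", name, "' contains non-finite values.", call. = FALSE)
  }
  out <- !is.na(x) & (x < window[1] | x > window[2])
  if (any(out)) {
    warning(sum(out), " value(s) of '", name, "' outside [",
            window[1], ", ", window[2], "]", call. = FALSE)
  }
  invisible(x)
}
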