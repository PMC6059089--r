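#' Constants of the blood-gas temperature-correction equation set
#'
#' The correction maps analyzer output (measured after warming the sample to
#' 37 degrees C, as handheld point-of-care analyzers do) to the value the
#' analyte would take at the animal's own temperature. pH and pCO2 use the
#' analyzer's built-in human-derived corrections, pO2 uses a correction from
#' the sea-turtle literature, and the CO2 solubility coefficient (alpha-CO2)
#' and apparent carbonic-acid pKa come from equations derived for Kemp's
#' ridley sea turtles. Bicarbonate and total CO2 are then recomputed through
#' the Henderson-Hasselbalch relation rather than taken from the device.
#'
#' @return A named list, read-only by convention:
#' \describe{
#'   \item{analyzer_temp}{37 (degrees C), the measurement temperature.}
#'   \item{reference_ph}{7.4, the reference pH in the pH correction.}
#'   \item{ph_coeffs}{c(0.0147, 0.0065), linear and interaction coefficients
#'     of the pH correction.}
#'   \item{po2_exp_coeff}{-0.0058, decadic exponent slope for pO2.}
#'   \item{pco2_exp_coeff}{0.0019, decadic exponent slope for pCO2.}
#'   \item{alpha_poly}{degree-3 polynomial coefficients (ascending) for
#'     alpha-CO2 in mmol/l/mmHg as a function of temperature.}
#'   \item{pka_poly}{degree-3 polynomial coefficients (ascending) for the
#'     polynomial part of pKa.}
#'   \item{pka_log_constants}{c(1.011, 0.011, 10.241, 0.001, 8.889), the
#'     constants of the pH- and temperature-dependent log10 quotient
#'     subtracted from the pKa polynomial.}
#' }
#' @export
#' @examples
#' correction_constants()$alpha_poly
correction_constants <- function() {
  list(
    analyzer_temp = 37,
    reference_ph = 7.4,
    ph_coeffs = c(0.0147, 0.0065),
    po2_exp_coeff = -0.0058,
    pco2_exp_coeff = 0.0019,
    alpha_poly = c(9.174e-2, -3.269e-3, 6.364e-5, -5.378e-7),
    pka_poly = c(6.398, -1.341e-2, 2.282e-4, -1.516e-6),
    pka_log_constants = c(1.011, 0.011, 10.241, 0.001, 8.889)
  )
}

# Analyte registry: instrument/corrected column names, units, and the decimal
# precision used when emitting report tables.
analyte_info <- function() {
  tibble::tibble(
    analyte = c("ph", "po2", "pco2", "hco3", "tco2", "lactate", "be"),
    unit = c("", "mmHg", "mmHg", "mmol/l", "mmol/l", "mmol/l", "mmol/l"),
    instrument_col = c("ph_i", "po2_i", "pco2_i", "hco3_i", "tco2_i",
                       "lactate_i", "be_i"),
    corrected_col = c("ph_c", "po2_c", "pco2_c", "hco3_c", "tco2_c",
                      "lactate", "be"),
    digits = c(2L, 0L, 1L, 1L, 0L, 2L, 1L)
  )
}

blood_gas_analytes <- function() analyte_info()$analyte

seasons <- function() c("spring", "summer", "fall")

corrected_col <- function(analyte) {
  info <- analyte_info()
  info$corrected_col[match(analyte, info$analyte)]
}

instrument_col <- function(analyte) {
  info <- analyte_info()
  info$instrument_col[match(analyte, info$analyte)]
}
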