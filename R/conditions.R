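# Experimental conditions shared by every rate calculation.

#' Gas constant in kcal/(mol K)
#'
#' Used throughout for free-energy conversions in kcal units.
#' @export
R_KCAL <- 1.987e-3

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hdxprotect_error")))
}

#' Convert a glass-electrode reading in D2O to pD
#'
#' The pH-meter reading (pH*) in D2O underestimates pD by a constant
#' electrode correction: pD = pH* + 0.4.
#'
#' @param pH_star numeric vector of uncorrected meter readings.
#' @return pD, same length as `pH_star`.
#' @examples
#' pd_from_ph_star(3.4) # 3.8
#' @export
pd_from_ph_star <- function(pH_star) {
  if (!is.numeric(pH_star) || any(!is.finite(pH_star)))
    abort("pH* reading must be finite numeric", "hdx_invalid_conditions")
  pH_star + 0.4
}

#' Exchange conditions
#'
#' Bundle of the solution conditions an intrinsic-rate calculation depends
#' on: pD (or the pH* reading it is derived from), temperature, denaturant
#' concentration and the ionization-constant exponent of D2O.
#'
#' @param pH_star glass-electrode reading; used to derive pD when `pD` is
#'   not supplied.
#' @param pD corrected pD; overrides `pH_star` when given.
#' @param temperature absolute temperature in kelvin. Default 288.15 K
#'   (15.0 C).
#' @param denaturant_conc GdmCl molarity (mol/L), >= 0.
#' @param pKw ionization-constant exponent of D2O; 15.24 at 15.0 C.
#' @return object of class `exchange_conditions` with fields `pH_star`,
#'   `pD`, `temperature`, `denaturant_conc`, `pKw`.
#' @examples
#' exchange_conditions(pH_star = 3.4)
#' @export
exchange_conditions <- function(pH_star = NULL, pD = NULL,
                                temperature = 288.15,
                                denaturant_conc = 6.0,
                                pKw = 15.24) {
  if (is.null(pD)) {
    if (is.null(pH_star))
      abort("supply pH_star or pD", "hdx_invalid_conditions")
    pD <- pd_from_ph_star(pH_star)
  }
  if (!is.finite(pD) || !is.finite(temperature) || temperature <= 0)
    abort("non-finite pD or non-positive temperature",
          "hdx_invalid_conditions")
  if (!is.finite(denaturant_conc) || denaturant_conc < 0)
    abort("denaturant concentration must be >= 0", "hdx_invalid_conditions")
  structure(
    list(pH_star = pH_star, pD = pD, temperature = temperature,
         denaturant_conc = denaturant_conc, pKw = pKw),
    class = "exchange_conditions"
  )
}

#' @export
print.exchange_conditions <- function(x, ...) {
  cat(sprintf(
    "Exchange conditions: pD %.2f, T %.2f K, [GdmCl] %.1f M, pKw %.2f\n",
    x$pD, x$temperature, x$denaturant_conc, x$pKw))
  invisible(x)
}

#' Deuteron and deuteroxide concentrations at given conditions
#'
#' @param conditions an [exchange_conditions()] object.
#' @return list with `d_plus` (= 10^-pD) and `od_minus` (= 10^(pD - pKw)),
#'   both in mol/L.
#' @export
ion_concentrations <- function(conditions) {
  list(d_plus = 10^(-conditions$pD),
       od_minus = 10^(conditions$pD - conditions$pKw))
}
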