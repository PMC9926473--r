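# Intrinsic (unprotected-chain) amide H/D-exchange rates.
#
# The chemistry: a backbone NH in a random coil exchanges with solvent
# deuterons through specific acid catalysis (rate constant A, per M D+ per
# min), specific base catalysis (B, per M OD- per min) and direct water
# catalysis (C, per min), calibrated on poly-DL-alanine (PDLA). Side chains
# flanking a peptide group perturb the acid and base channels by
# multiplicative factors tabulated by Bai and co-workers.

#' Acid/base/water catalysis parameters
#'
#' The three rate constants of the reference-polymer exchange rate law,
#' `k_ref = A*[D+] + B*[OD-] + C`, at a stated reference temperature.
#'
#' @param A specific acid catalysis constant, /M/min.
#' @param B specific base catalysis constant, /M/min.
#' @param C water catalysis constant, /min.
#' @param reference_temperature kelvin.
#' @param se optional named numeric vector of standard errors (A, B, C).
#' @return object of class `catalysis_params`.
#' @export
catalysis_params <- function(A, B, C, reference_temperature = 293.15,
                             se = NULL) {
  if (any(!is.finite(c(A, B, C))) || any(c(A, B, C) < 0))
    abort("catalysis constants must be finite and >= 0",
          "hdx_invalid_parameters")
  structure(list(A = A, B = B, C = C,
                 reference_temperature = reference_temperature, se = se),
            class = "catalysis_params")
}

#' @export
print.catalysis_params <- function(x, ...) {
  cat(sprintf(
    "Catalysis params (T_ref %.2f K): A %.4g /M/min, B %.4g /M/min, C %.4g /min\n",
    x$reference_temperature, x$A, x$B, x$C))
  invisible(x)
}

# Arrhenius activation energies per catalysis channel, kcal/mol
# (acid, base, water), as established for PDLA exchange.
EA_KCAL <- c(acid = 14, base = 17, water = 19)

#' Published poly-DL-alanine catalysis constants, temperature adjusted
#'
#' Reference constants for PDLA exchange in D2O: log10 A = 1.62,
#' log10 B = 10.18, log10 C = -1.5 at 20 C, moved to the requested
#' temperature by Arrhenius factors with activation energies of 14, 17 and
#' 19 kcal/mol for the acid, base and water channels.
#'
#' @param temperature target temperature in kelvin (default 288.15).
#' @return a [catalysis_params()] object at `temperature`.
#' @export
pdla_catalysis_defaults <- function(temperature = 288.15) {
  t_ref <- 293.15
  arr <- exp(-(EA_KCAL / R_KCAL) * (1 / temperature - 1 / t_ref))
  catalysis_params(A = 10^1.62 * arr[["acid"]],
                   B = 10^10.18 * arr[["base"]],
                   C = 10^(-1.5) * arr[["water"]],
                   reference_temperature = temperature)
}

#' Reference (poly-DL-alanine) exchange rate
#'
#' `k_ref = A*10^-pD + B*10^(pD - pKw) + C`. On a log scale the rate is
#' V-shaped in pD: an acid limb of slope -1, a base limb of slope +1, and a
#' minimum at pD = (pKw + log10(A/B))/2 when the water term is small.
#'
#' @param pD numeric vector.
#' @param params a [catalysis_params()] object.
#' @param pKw ionization exponent of D2O (15.24 at 15 C).
#' @return rate(s) in /min.
#' @export
k_ref <- function(pD, params, pKw = 15.24) {
  stopifnot(inherits(params, "catalysis_params"))
  params$A * 10^(-pD) + params$B * 10^(pD - pKw) + params$C
}

#' pD of the minimum of the reference rate law
#'
#' Closed form for the V minimum ignoring the water term:
#' `(pKw + log10(A/B)) / 2`.
#'
#' @inheritParams k_ref
#' @export
k_ref_minimum_pd <- function(params, pKw = 15.24) {
  (pKw + log10(params$A / params$B)) / 2
}

#' Fit acid/base/water catalysis constants to a pD series
#'
#' Least-squares fit of log10 k_ref against the three-channel rate law,
#' parameterized in log10(A), log10(B), log10(C) so the constants stay
#' positive. Standard errors are propagated from the log-scale covariance.
#'
#' @param pD_values,k_ref_values paired observations (>= 4 points spanning
#'   both limbs of the V).
#' @param pKw ionization exponent used in the rate law.
#' @return a [catalysis_params()] object with an `se` field and an
#'   `ill_conditioned` attribute flagging one-limb or flat data.
#' @export
fit_catalysis_params <- function(pD_values, k_ref_values, pKw = 15.24) {
  stopifnot(length(pD_values) == length(k_ref_values))
  if (length(pD_values) < 4)
    abort("need at least 4 (pD, k_ref) points", "hdx_ill_conditioned_fit")
  if (any(k_ref_values <= 0))
    abort("k_ref values must be positive", "hdx_invalid_parameters")

  # flat limit: no pD dependence resolvable
  if (diff(range(k_ref_values)) / mean(k_ref_values) < 1e-10) {
    out <- catalysis_params(0, 0, mean(k_ref_values))
    attr(out, "ill_conditioned") <- TRUE
    return(out)
  }

  df <- data.frame(pD = pD_values, lk = log10(k_ref_values))
  i_lo <- which.min(df$pD); i_hi <- which.max(df$pD)
  start <- list(
    la = log10(max(k_ref_values[i_lo] * 10^df$pD[i_lo], 1e-12)),
    lb = log10(max(k_ref_values[i_hi] * 10^(pKw - df$pD[i_hi]), 1e-12)),
    lc = log10(min(k_ref_values))
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      lk ~ log10(10^(la - pD) + 10^(lb + pD - pKw) + 10^lc),
      data = df, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    est <- stats::coef(fit)
    se_log <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                       error = function(e) rep(NA_real_, 3))
    vals <- 10^est
    se <- log(10) * vals * se_log
    names(se) <- c("A", "B", "C")
    out <- catalysis_params(vals[["la"]], vals[["lb"]], vals[["lc"]],
                            se = se)
  } else {
    # the rate law is linear in (A, B, C); fall back to a linear-basis
    # fit with non-negativity clamping when the log-scale fit is singular
    # (typically one-limb data)
    X <- cbind(10^(-df$pD), 10^(df$pD - pKw), 1)
    beta <- pmax(stats::lm.fit(X, k_ref_values)$coefficients, 0)
    out <- catalysis_params(beta[[1]], beta[[2]], beta[[3]],
                            se = c(A = NA_real_, B = NA_real_,
                                   C = NA_real_))
  }

  # one-limb data: the fitted V minimum falls outside the sampled range
  pd_min <- if (out$A > 0 && out$B > 0) k_ref_minimum_pd(out, pKw) else NA
  ill <- is.na(pd_min) || pd_min < min(pD_values) ||
    pd_min > max(pD_values)
  if (ill)
    warning("pD points sample only one limb of the V; A or B is poorly determined",
            call. = FALSE)
  attr(out, "ill_conditioned") <- ill
  out
}
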