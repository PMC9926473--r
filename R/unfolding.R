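# Two-state denaturant-unfolding analysis (linear-extrapolation model).
#
# N <=> U with dG_NU = dG0 - m*[den]; the observed ellipticity is the
# population-weighted average of two linearly sloping baselines
# (Santoro-Bolen six-parameter model).

#' Two-state ellipticity model
#'
#' `theta(c) = ((k0 + k1*c) + (k2 + k3*c) * K) / (1 + K)` with
#' `K = exp(-(dG0 - m*c) / (R*T))`. `(k0 + k1*c)` is the native baseline,
#' `(k2 + k3*c)` the unfolded baseline.
#'
#' @param conc denaturant molarity (vector ok).
#' @param dG0 unfolding free energy at 0 M, kcal/mol.
#' @param m denaturant dependence of dG, kcal/mol/M.
#' @param k0,k1 native-baseline intercept and slope.
#' @param k2,k3 unfolded-baseline intercept and slope.
#' @param temperature kelvin.
#' @return mean residue ellipticity, deg cm2/dmol.
#' @export
theta_two_state <- function(conc, dG0, m, k0, k1, k2, k3,
                            temperature = 288.15) {
  K <- exp(-(dG0 - m * conc) / (R_KCAL * temperature))
  ((k0 + k1 * conc) + (k2 + k3 * conc) * K) / (1 + K)
}

#' Fraction of unfolded protein
#'
#' `K / (1 + K)` with `K = exp(-(dG0 - m*conc)/(R*T))`; 0.5 at the
#' transition midpoint `conc = dG0/m`.
#'
#' @inheritParams theta_two_state
#' @export
fraction_unfolded <- function(conc, dG0, m, temperature = 288.15) {
  K <- exp(-(dG0 - m * conc) / (R_KCAL * temperature))
  K / (1 + K)
}

#' Fit the two-state unfolding model to an ellipticity transition
#'
#' Unweighted nonlinear least squares on the six-parameter model. Initial
#' guesses: baselines from the three lowest/highest-concentration points,
#' midpoint from the steepest local gradient, m from the apparent
#' transition width.
#'
#' @param concentrations denaturant molarities (>= 8 points spanning both
#'   baselines and the transition).
#' @param ellipticities observed mean residue ellipticities.
#' @param temperature kelvin.
#' @return object of class `two_state_fit`: `dG0`, `m`, `k0`..`k3`,
#'   `midpoint` (= dG0/m), `standard_errors` (named), `fitted`,
#'   `residuals`.
#' @export
fit_two_state <- function(concentrations, ellipticities,
                          temperature = 288.15) {
  if (length(concentrations) != length(ellipticities))
    abort("concentration and ellipticity vectors differ in length",
          "hdx_invalid_parameters")
  if (length(concentrations) < 8)
    abort("need >= 8 points to constrain six parameters",
          "hdx_ill_conditioned_fit")
  ord <- order(concentrations)
  conc <- concentrations[ord]; th <- ellipticities[ord]

  lo <- seq_len(3); hi <- seq(length(conc) - 2, length(conc))
  fit_lo <- stats::lm(th[lo] ~ conc[lo])
  fit_hi <- stats::lm(th[hi] ~ conc[hi])
  grad <- diff(th) / diff(conc)
  i_mid <- which.max(abs(grad))
  cm0 <- mean(conc[i_mid + 0:1])
  # a resolvable transition must stand out against the baseline slopes
  if (max(abs(grad)) < 2 * stats::median(abs(grad)) ||
      cm0 <= min(conc) + 1e-9 || cm0 >= max(conc) - 1e-9)
    abort("transition not bracketed by the data",
          "hdx_ill_conditioned_fit")
  width <- max(diff(range(conc)) / 4, 0.5)
  m0 <- 4 * R_KCAL * temperature / width   # ~full transition over `width`
  start <- list(dG0 = m0 * cm0, m = m0,
                k0 = unname(stats::coef(fit_lo)[1]),
                k1 = unname(stats::coef(fit_lo)[2]),
                k2 = unname(stats::coef(fit_hi)[1]),
                k3 = unname(stats::coef(fit_hi)[2]))
  RT <- R_KCAL * temperature
  fit <- minpack.lm::nlsLM(
    th ~ ((k0 + k1 * conc) + (k2 + k3 * conc) *
            exp(-(dG0 - m * conc) / RT)) /
         (1 + exp(-(dG0 - m * conc) / RT)),
    data = data.frame(conc = conc, th = th), start = start,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15))
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 6),
                                                     names(co)))
  structure(list(dG0 = co[["dG0"]], m = co[["m"]], k0 = co[["k0"]],
                 k1 = co[["k1"]], k2 = co[["k2"]], k3 = co[["k3"]],
                 midpoint = co[["dG0"]] / co[["m"]],
                 temperature = temperature, standard_errors = se,
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit)),
            class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf(
    "Two-state unfolding fit: dG0 %.2f +/- %.2f kcal/mol, m %.2f +/- %.2f kcal/mol/M, midpoint %.2f M\n",
    x$dG0, x$standard_errors[["dG0"]], x$m, x$standard_errors[["m"]],
    x$midpoint))
  invisible(x)
}

#' Mean residue ellipticity from raw CD signal
#'
#' `[theta] = theta_deg * MRW / (10 * path_cm * conc_g_ml)` where MRW is
#' the mean residue weight (molecular weight / number of peptide
#' residues).
#'
#' @param theta_deg observed ellipticity in degrees.
#' @param mrw mean residue weight, g/mol.
#' @param path_cm cuvette path length, cm.
#' @param conc_g_ml protein concentration, g/mL.
#' @return deg cm2/dmol.
#' @export
mean_residue_ellipticity <- function(theta_deg, mrw, path_cm, conc_g_ml) {
  theta_deg * mrw / (10 * path_cm * conc_g_ml)
}
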