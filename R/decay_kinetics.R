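# Single-exponential fitting of H/D-exchange decays.
#
# The observed signal (HSQC cross-peak volume in 2D, peak area in 1D) of a
# protonated amide decays as Y(t) = dY * exp(-k_obs * t) + Yinf; the
# plateau Yinf is non-zero when the exchange buffer retains residual H2O.

#' Exchange decay curve
#'
#' @param times sampling times in minutes; non-negative, strictly
#'   increasing, at least 4 points for the 3-parameter fit.
#' @param signals peak volumes or areas, same length as `times`.
#' @param residue_label identifier carried through to fit results.
#' @param post_exchange_reference optional signal measured after complete
#'   exchange (e.g. a heated control); used by [check_plateau()] only.
#' @return object of class `decay_curve`.
#' @export
decay_curve <- function(times, signals, residue_label = NA_character_,
                        post_exchange_reference = NULL) {
  if (length(times) != length(signals))
    abort("times and signals differ in length", "hdx_invalid_parameters")
  if (length(times) < 4)
    abort("need >= 4 time points for a 3-parameter fit",
          "hdx_invalid_parameters")
  if (any(times < 0) || any(diff(times) <= 0))
    abort("times must be non-negative and strictly increasing",
          "hdx_invalid_parameters")
  structure(list(times = as.numeric(times), signals = as.numeric(signals),
                 residue_label = residue_label,
                 post_exchange_reference = post_exchange_reference),
            class = "decay_curve")
}

#' Fit a single-exponential exchange decay
#'
#' Nonlinear least-squares fit of `Y(t) = dY*exp(-k*t) + Yinf`. Initial
#' guesses are taken from the data: plateau from the last point, amplitude
#' from first minus last, and the rate from the slope of a log-linear
#' regression of the plateau-subtracted signal.
#'
#' @param curve a [decay_curve()].
#' @return object of class `exponential_fit` with fields `amplitude`,
#'   `k_obs`, `plateau`, `standard_errors` (named vector), `converged`,
#'   `residue_label`, and the fitted `curve`.
#' @export
fit_single_exponential <- function(curve) {
  stopifnot(inherits(curve, "decay_curve"))
  t <- curve$times; y <- curve$signals
  if (stats::sd(y) < 1e-12 * max(abs(mean(y)), 1))
    abort("signal is constant; rate unidentifiable", "hdx_fit_failure")

  plateau0 <- y[length(y)]
  amp0 <- y[1] - plateau0
  if (abs(amp0) < 1e-12 * max(abs(y)))
    abort("no decay amplitude; rate unidentifiable", "hdx_fit_failure")
  dy <- y - plateau0
  pos <- which(dy * sign(amp0) > 0)
  k0 <- if (length(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(abs(dy[pos])) ~ t[pos]))[2]
    max(-sl, 1e-6)
  } else 1 / max(t[t > 0])

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ amp * exp(-k * t) + plateau,
      data = data.frame(t = t, y = y),
      start = list(amp = amp0, k = unname(k0), plateau = plateau0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) abort(paste("exponential fit failed:",
                                    conditionMessage(e)),
                              "hdx_fit_failure"))
  co <- stats::coef(fit)
  if (co[["k"]] <= 0)
    abort("fitted rate is non-positive", "hdx_fit_failure")
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  names(se) <- c("amplitude", "k_obs", "plateau")
  structure(list(amplitude = co[["amp"]], k_obs = co[["k"]],
                 plateau = co[["plateau"]], standard_errors = se,
                 converged = TRUE, residue_label = curve$residue_label,
                 curve = curve),
            class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential fit%s: k_obs %.4g +/- %.2g /min, amplitude %.4g, plateau %.4g\n",
    if (is.na(x$residue_label)) "" else paste0(" [", x$residue_label, "]"),
    x$k_obs, x$standard_errors[["k_obs"]], x$amplitude, x$plateau))
  invisible(x)
}

#' Average replicate rate fits
#'
#' Arithmetic mean of k_obs across replicates with the standard error of
#' the mean; for a single replicate the fit's own standard error is
#' reported instead.
#'
#' @param fits list of `exponential_fit` objects (or a single one).
#' @return list with `mean_k_obs`, `se`, `n`.
#' @export
aggregate_replicates <- function(fits) {
  if (inherits(fits, "exponential_fit")) fits <- list(fits)
  if (length(fits) == 0) abort("no replicates supplied", "hdx_no_data")
  ks <- vapply(fits, function(f) f$k_obs, numeric(1))
  if (length(ks) == 1) {
    return(list(mean_k_obs = ks, se = fits[[1]]$standard_errors[["k_obs"]],
                n = 1L))
  }
  list(mean_k_obs = mean(ks), se = stats::sd(ks) / sqrt(length(ks)),
       n = length(ks))
}

#' Check the fitted plateau against the expected residual protonation
#'
#' With a fraction h of residual H2O in the exchange buffer the plateau
#' should settle at `h` of the initial signal:
#' `plateau / (amplitude + plateau) ~ h`.
#'
#' @param fit an `exponential_fit`.
#' @param expected_residual_fraction expected `Yinf/Y(0)` (default 0.10).
#' @param tolerance absolute tolerance on the fraction.
#' @return list with `ok`, `fraction`, `expected`, `message`.
#' @export
check_plateau <- function(fit, expected_residual_fraction = 0.10,
                          tolerance = 0.05) {
  frac <- fit$plateau / (fit$amplitude + fit$plateau)
  if (fit$plateau < 0) {
    return(list(ok = FALSE, fraction = frac,
                expected = expected_residual_fraction,
                message = "negative plateau"))
  }
  ok <- abs(frac - expected_residual_fraction) <= tolerance
  list(ok = ok, fraction = frac, expected = expected_residual_fraction,
       message = if (ok) "plateau consistent with residual protonation"
                 else "plateau inconsistent with residual protonation")
}

#' Fit every residue/replicate decay in a long-format table
#'
#' @param table data.frame with columns `residue`, `replicate`,
#'   `time_min`, `volume` (the dialect written by [gen_decay_table()]).
#' @return data.frame with one row per residue: `residue`, `k_obs`, `se`,
#'   `n_replicates`.
#' @export
fit_decay_table <- function(table) {
  need <- c("residue", "replicate", "time_min", "volume")
  if (!all(need %in% names(table)))
    abort(paste("decay table needs columns:", paste(need, collapse = ", ")),
          "hdx_invalid_parameters")
  res <- lapply(split(table, table$residue), function(d) {
    fits <- lapply(split(d, d$replicate), function(r) {
      r <- r[order(r$time_min), ]
      fit_single_exponential(decay_curve(r$time_min, r$volume,
                                         residue_label = d$residue[1]))
    })
    agg <- aggregate_replicates(fits)
    data.frame(residue = d$residue[1], k_obs = agg$mean_k_obs,
               se = agg$se, n_replicates = agg$n)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
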