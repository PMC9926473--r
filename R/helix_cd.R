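# Helix-length dependence of the 222 nm CD band.
#
# Because of helix end effects the per-residue 222 nm ellipticity of a
# short helix of n peptide units is attenuated relative to the infinite
# helix: [theta]_222,n = [theta]_222,inf * (n - k)/n, with an empirical
# end-effect constant k that itself grows with n. A one-turn helix (n = 4)
# is therefore nearly CD-silent even when fully formed.

# empirical end-effect constants: short fixed-nucleus helices at the
# tabulated lengths; 4.3 (experimental) / 4.6 (theoretical) for long
# helices.
.K_TABLE <- data.frame(n = c(4, 8, 11), k = c(2.8, 3.5, 4.0))

#' Default helix CD parameters
#'
#' @return list with `theta_infinity` (-41000 deg cm2/dmol), the empirical
#'   end-effect `k_table` (k = 2.8, 3.5, 4.0 at n = 4, 8, 11), and the
#'   long-helix constants `k_experimental` (4.3) and `k_theoretical`
#'   (4.6).
#' @export
helix_cd_params <- function() {
  list(theta_infinity = -41000, k_table = .K_TABLE,
       k_experimental = 4.3, k_theoretical = 4.6)
}

#' Mean residue ellipticity at 222 nm of an n-unit helix
#'
#' `theta_infinity * (n - k)/n`, clamped to 0 when k > n (the end
#' correction cannot exceed the helix itself).
#'
#' @param n helix length in peptide units (carbonyls), integer >= 1.
#' @param k empirical end-effect constant.
#' @param theta_infinity infinite-helix ellipticity, deg cm2/dmol
#'   (negative).
#' @return deg cm2/dmol.
#' @export
theta_222 <- function(n, k = helix_cd_params()$k_experimental,
                      theta_infinity = helix_cd_params()$theta_infinity) {
  if (any(n < 1) || any(n != round(n)))
    abort("helix length n must be a positive integer",
          "hdx_invalid_length")
  theta_infinity * (1 - pmin(k / n, 1))
}

#' End-effect constant for a helix of given length
#'
#' Exact table value at tabulated lengths, piecewise-linear interpolation
#' between them, constant extrapolation beyond the table.
#'
#' @param n helix length(s) in peptide units.
#' @param table data.frame with columns `n`, `k`.
#' @return k value(s).
#' @export
k_for_length <- function(n, table = helix_cd_params()$k_table) {
  if (any(n < 1)) abort("n must be >= 1", "hdx_invalid_length")
  stats::approx(table$n, table$k, xout = n, rule = 2)$y
}

#' Chain-averaged 222 nm ellipticity of a fluctuating-helix ensemble
#'
#' Linear mixture over helical species: each species of length n, formed
#' with population fraction f, covers n of the chain's residues and
#' contributes `f * (n / chain_length) * theta_222(n, k(n))`; non-helical
#' residues contribute nothing at 222 nm.
#'
#' @param lengths helix lengths in peptide units, one per species.
#' @param fractions population fractions in `[0, 1]`, summing to <= 1.
#' @param chain_length number of residues in the chain.
#' @param params list as returned by [helix_cd_params()].
#' @return deg cm2/dmol.
#' @export
ensemble_theta_222 <- function(lengths, fractions, chain_length,
                               params = helix_cd_params()) {
  if (length(lengths) != length(fractions))
    abort("lengths and fractions differ in length",
          "hdx_invalid_ensemble")
  if (length(lengths) == 0) return(0)
  if (any(fractions < 0) || any(fractions > 1) ||
      sum(fractions) > 1 + 1e-9)
    abort("population fractions must lie in [0,1] and sum to <= 1",
          "hdx_invalid_ensemble")
  th <- theta_222(lengths, k_for_length(lengths, params$k_table),
                  params$theta_infinity)
  sum(fractions * (lengths / chain_length) * th)
}
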