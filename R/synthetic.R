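# Deterministic generators for every input the pipeline consumes.
#
# Noise models: multiplicative Gaussian on signals (peak-volume error
# scales with intensity) and lognormal on rates. All generators are
# bit-reproducible under a fixed seed.

#' Generate a long-format exchange decay table
#'
#' `Y(t) = dY*exp(-k t) + Yinf` per residue and replicate, with the
#' plateau set to `plateau_fraction` of the initial signal (residual
#' protonation from H2O carry-over) and multiplicative Gaussian noise.
#'
#' @param true_rates named numeric vector of rates (/min); names become
#'   residue labels.
#' @param times sampling times in minutes.
#' @param plateau_fraction `Yinf / Y(0)` (default 0.10).
#' @param noise_sigma relative Gaussian sigma (0 = noiseless).
#' @param replicates replicate measurements per residue.
#' @param y0 initial signal in arbitrary volume units.
#' @param seed integer seed; fixes the output exactly.
#' @return data.frame `residue`, `replicate`, `time_min`, `volume`.
#' @export
gen_decay_table <- function(true_rates, times = seq(0, 300, by = 25),
                            plateau_fraction = 0.10, noise_sigma = 0.05,
                            replicates = 3, y0 = 1000, seed = 1) {
  stopifnot(all(true_rates > 0))
  if (is.null(names(true_rates)))
    names(true_rates) <- paste0("res", seq_along(true_rates))
  set.seed(seed)
  rows <- list()
  for (res in names(true_rates)) {
    k <- true_rates[[res]]
    yinf <- plateau_fraction * y0
    amp <- y0 - yinf
    for (rep_i in seq_len(replicates)) {
      y <- amp * exp(-k * times) + yinf
      if (noise_sigma > 0)
        y <- y * (1 + stats::rnorm(length(times), 0, noise_sigma))
      rows[[length(rows) + 1]] <- data.frame(
        residue = res, replicate = rep_i, time_min = times, volume = y)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a reference-polymer pD series
#'
#' Reference rates from the acid/base/water rate law on a pD grid, with
#' lognormal noise.
#'
#' @param params a [catalysis_params()] object.
#' @param pD_grid pD sampling points (default 1.5 to 4.5, the range that
#'   spans both limbs of the V at acid conditions).
#' @param pKw ionization exponent of D2O.
#' @param noise_sigma sigma of the lognormal noise (0 = noiseless).
#' @param seed integer seed.
#' @return data.frame `pD`, `k_ref` (/min).
#' @export
gen_pdla_series <- function(params, pD_grid = seq(1.5, 4.5, by = 0.25),
                            pKw = 15.24, noise_sigma = 0.05, seed = 1) {
  if (any(pD_grid < 0) || any(pD_grid > pKw))
    abort("pD grid must lie within 0..pKw", "hdx_invalid_parameters")
  set.seed(seed)
  k <- k_ref(pD_grid, params, pKw)
  if (noise_sigma > 0)
    k <- k * exp(stats::rnorm(length(k), 0, noise_sigma))
  data.frame(pD = pD_grid, k_ref = k)
}

#' Generate a two-state CD unfolding curve
#'
#' Ellipticities from [theta_two_state()] on a concentration grid with
#' multiplicative Gaussian noise. Defaults reproduce a cooperative
#' unfolder with dG0 = 5.30 kcal/mol and m = 1.52 kcal/mol/M (midpoint
#' 3.49 M) between sloping helical and unfolded baselines.
#'
#' @param dG0,m thermodynamic parameters (kcal/mol, kcal/mol/M).
#' @param k0,k1,k2,k3 baseline coefficients (deg cm2/dmol and per M).
#' @param conc_grid denaturant molarities.
#' @param temperature kelvin.
#' @param noise_sigma relative Gaussian sigma.
#' @param seed integer seed.
#' @return data.frame `conc_M`, `theta_mrd`.
#' @export
gen_unfolding_curve <- function(dG0 = 5.30, m = 1.52,
                                k0 = -14000, k1 = 120,
                                k2 = -1200, k3 = 60,
                                conc_grid = seq(0, 6, length.out = 15),
                                temperature = 288.15,
                                noise_sigma = 0.02, seed = 1) {
  stopifnot(m > 0)
  set.seed(seed)
  th <- theta_two_state(conc_grid, dG0, m, k0, k1, k2, k3, temperature)
  if (noise_sigma > 0)
    th <- th * (1 + stats::rnorm(length(th), 0, noise_sigma))
  data.frame(conc_M = conc_grid, theta_mrd = th)
}

#' Generate an ideal alpha-helix with known hydrogen bonds
#'
#' Builds a polyalanine backbone from ideal internal coordinates at
#' uniform (phi, psi) = (-57, -47) degrees (helical rise ~1.5 Angstrom,
#' twist ~100 degrees per residue), places amide protons at ideal
#' geometry, and emits the combinatorial truth list of i -> i-4 hydrogen
#' bonds (donors 5..n).
#'
#' @param n_residues chain length (>= 2; >= 5 for any i -> i-4 bond).
#' @param phi,psi backbone torsions in degrees.
#' @param file optional path; when given the helix is also written as a
#'   PDB file.
#' @return list with `atoms` (a `backbone_atoms` object) and
#'   `true_hbonds` (data.frame `donor`, `acceptor`).
#' @export
gen_ideal_helix <- function(n_residues = 12, phi = -57, psi = -47,
                            file = NULL) {
  if (n_residues < 2)
    abort("need at least 2 residues", "hdx_invalid_parameters")
  ch <- .build_chain(n_residues, phi, psi)
  atoms <- structure(
    c(ch, list(resno = seq_len(n_residues),
               resid = rep("ALA", n_residues))),
    class = "backbone_atoms")
  donors <- if (n_residues >= 5) 5:n_residues else integer(0)
  truth <- data.frame(donor = donors, acceptor = donors - 4L)
  if (!is.null(file)) {
    types <- c("N", "CA", "C", "O", "H")
    xyz <- c(); resno <- c(); elety <- c()
    for (i in seq_len(n_residues)) {
      for (ty in types) {
        co <- atoms[[ty]][i, ]
        if (any(!is.finite(co))) next
        xyz <- c(xyz, co); resno <- c(resno, i); elety <- c(elety, ty)
      }
    }
    bio3d::write.pdb(file = file, xyz = xyz, resno = resno,
                     resid = rep("ALA", length(resno)), elety = elety)
  }
  list(atoms = atoms, true_hbonds = truth)
}

#' Apply a rigid-body rotation/translation to backbone atoms
#'
#' Utility for invariance checks: hydrogen-bond detection must not depend
#' on the molecular frame.
#'
#' @param atoms a `backbone_atoms` object.
#' @param angles Euler-like rotation angles about x, y, z (radians).
#' @param translation length-3 shift vector.
#' @return transformed `backbone_atoms`.
#' @export
transform_backbone <- function(atoms, angles = c(0.3, -1.1, 2.0),
                               translation = c(10, -5, 3)) {
  rx <- matrix(c(1, 0, 0, 0, cos(angles[1]), -sin(angles[1]),
                 0, sin(angles[1]), cos(angles[1])), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(angles[2]), 0, sin(angles[2]), 0, 1, 0,
                 -sin(angles[2]), 0, cos(angles[2])), 3, 3, byrow = TRUE)
  rz <- matrix(c(cos(angles[3]), -sin(angles[3]), 0,
                 sin(angles[3]), cos(angles[3]), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  rot <- rz %*% ry %*% rx
  for (ty in c("N", "CA", "C", "O", "H")) {
    ok <- is.finite(atoms[[ty]][, 1])
    atoms[[ty]][ok, ] <- t(rot %*% t(atoms[[ty]][ok, , drop = FALSE])) +
      matrix(translation, sum(ok), 3, byrow = TRUE)
  }
  atoms
}
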