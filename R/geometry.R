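# Small 3D helpers and an internal-coordinate chain builder used by the
# ideal-helix generator and the hydrogen-bond detector.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) v / sqrt(sum(v^2))

# Place atom D given atoms A-B-C, the C-D bond length, the B-C-D angle and
# the A-B-C-D torsion (degrees). Standard natural-extension construction.
.place_atom <- function(a, b, c, bond, angle, torsion) {
  angle <- angle * pi / 180
  torsion <- torsion * pi / 180
  bc <- .unit(c - b)
  nrm <- .unit(.cross3(b - a, bc))
  m <- .cross3(nrm, bc)
  d <- c(-bond * cos(angle),
         bond * sin(angle) * cos(torsion),
         bond * sin(angle) * sin(torsion))
  c + d[1] * bc + d[2] * m + d[3] * nrm
}

# Ideal backbone geometry (lengths in Angstrom, angles in degrees)
.BB <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            n_h = 1.0,
            ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
            ang_ca_c_o = 120.8)

# Build N/CA/C/O/H backbone coordinates for a polyalanine-like chain with
# uniform (phi, psi) and trans peptide bonds. Returns a matrix list per
# atom type, rows = residues.
.build_chain <- function(n_residues, phi = -57, psi = -47) {
  N <- CA <- C <- O <- H <- matrix(NA_real_, n_residues, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BB$n_ca, 0, 0)
  ang <- .BB$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + .BB$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_residues - 1) + 1) {
    N[i, ] <- .place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                          .BB$c_n, .BB$ang_ca_c_n, psi)
    CA[i, ] <- .place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                           .BB$n_ca, .BB$ang_c_n_ca, 180)   # omega
    C[i, ] <- .place_atom(C[i - 1, ], N[i, ], CA[i, ],
                          .BB$ca_c, .BB$ang_n_ca_c, phi)
  }
  for (i in seq_len(n_residues)) {
    # carbonyl O opposite the next N across the sp2 carbon
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ],
                          .BB$c_o, .BB$ang_ca_c_o, psi + 180)
    if (i > 1) H[i, ] <- amide_h_position(N[i, ], C[i - 1, ], CA[i, ])
  }
  list(N = N, CA = CA, C = C, O = O, H = H)
}

#' Ideal amide-proton position
#'
#' Places H on the donor nitrogen at 1.0 Angstrom along the external
#' bisector of the C(i-1)-N-CA angle, i.e. in the peptide plane and trans
#' to the preceding carbonyl.
#'
#' @param n,c_prev,ca coordinates (length-3) of the amide N, the previous
#'   residue's carbonyl C and the residue's own CA.
#' @return length-3 coordinate vector.
#' @export
amide_h_position <- function(n, c_prev, ca) {
  n + .BB$n_h * .unit(.unit(n - c_prev) + .unit(n - ca))
}
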