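# Nearest-neighbour side-chain corrections to the reference exchange rate.
#
# Literature values are tabulated as log10 factors; they are converted to
# multiplicative factors at table-construction time because the rate
# equation is multiplicative. For the amide NH of residue i the acid factor
# is A_L(residue i) * A_R(residue i-1): the "L" factor of a side chain acts
# on the peptide NH to its left (the residue's own NH), the "R" factor on
# the peptide to its right (the next residue's NH). Base factors likewise.

# log10 factors, poly-DL-alanine reference (Bai-convention, D2O).
# Columns: AL, AR (acid), BL, BR (base).
.SIDECHAIN_LOG10 <- rbind(
  A       = c( 0.00,  0.00,  0.00,  0.00),
  R       = c(-0.59, -0.32,  0.08,  0.22),
  N       = c(-0.58, -0.13,  0.49,  0.32),
  D_prot  = c(-0.90, -0.12,  0.69,  0.60),   # Asp-COOD (protonated)
  D_deprot= c( 0.90,  0.58,  0.10, -0.18),   # Asp-COO-
  C       = c(-0.54, -0.46,  0.62,  0.55),
  E_prot  = c(-0.60, -0.27,  0.24,  0.39),   # Glu-COOD
  E_deprot= c(-0.90,  0.31, -0.11, -0.15),   # Glu-COO-
  G       = c(-0.22,  0.22,  0.27,  0.17),
  Q       = c(-0.47, -0.27,  0.06,  0.20),
  H_prot  = c(-0.80, -0.51,  0.80,  0.83),   # His+
  H_deprot= c( 0.00,  0.00, -0.10,  0.14),   # His0
  I       = c(-0.91, -0.59, -0.73, -0.23),
  L       = c(-0.57, -0.13, -0.58, -0.21),
  K       = c(-0.56, -0.29, -0.04,  0.12),
  M       = c(-0.64, -0.28, -0.01,  0.11),
  F       = c(-0.52, -0.43, -0.24,  0.06),
  P_trans = c( 0.00, -0.19,  0.00, -0.24),
  P_cis   = c( 0.00, -0.85,  0.00,  0.60),
  S       = c(-0.44, -0.39,  0.37,  0.30),
  T       = c(-0.79, -0.47, -0.07,  0.20),
  W       = c(-0.40, -0.44, -0.41, -0.11),
  Y       = c(-0.41, -0.37, -0.27,  0.05),
  V       = c(-0.74, -0.30, -0.70, -0.14),
  # chain termini: the protonated alpha-amine acts as the left neighbour of
  # residue 2's NH (R factors); the carboxy terminus as part of the last
  # residue's own peptide group (L factors).
  NT      = c(   NA, -1.32,    NA,  1.62),
  CT_deprot = c( 0.96,  NA, -1.80,    NA),
  CT_prot   = c( 0.05,  NA,  0.00,    NA)
)
colnames(.SIDECHAIN_LOG10) <- c("AL", "AR", "BL", "BR")

# model pKa values (D2O-shifted) used to pick protonation variants
.MODEL_PKA <- c(D = 4.48, E = 4.93, H = 7.00, CT = 4.00)

#' Side-chain factor table for intrinsic-rate calculation
#'
#' Multiplicative acid (`AL`, `AR`) and base (`BL`, `BR`) side-chain
#' factors for every standard one-letter residue code, with
#' protonation-state variants for Asp, Glu, His and the carboxy terminus
#' resolved against model pKa values at the working pD, and cis/trans
#' variants for proline. Alanine factors are 1 by construction of the
#' poly-DL-alanine reference.
#'
#' @param pD working pD used to select protonation variants.
#' @param pKa named numeric vector of model pKa values for `D`, `E`, `H`
#'   and `CT` (C-terminal carboxylate); defaults are D2O-shifted values.
#' @return a data.frame keyed by residue code with columns `AL`, `AR`,
#'   `BL`, `BR` (multiplicative factors). Special rows: `P_trans`,
#'   `P_cis`, `NT`, `CT`.
#' @export
sidechain_factors <- function(pD = 3.8, pKa = .MODEL_PKA) {
  pick <- function(code) if (pD < pKa[[code]]) "prot" else "deprot"
  rows <- rownames(.SIDECHAIN_LOG10)
  keep <- setdiff(rows, c("D_prot", "D_deprot", "E_prot", "E_deprot",
                          "H_prot", "H_deprot", "CT_prot", "CT_deprot"))
  tab <- .SIDECHAIN_LOG10[keep, , drop = FALSE]
  tab <- rbind(tab,
               D  = .SIDECHAIN_LOG10[paste0("D_", pick("D")), ],
               E  = .SIDECHAIN_LOG10[paste0("E_", pick("E")), ],
               H  = .SIDECHAIN_LOG10[paste0("H_", pick("H")), ],
               CT = .SIDECHAIN_LOG10[paste0("CT_", pick("CT")), ])
  out <- as.data.frame(10^tab)
  # NA log entries mean "does not apply"; neutral factor 1
  out[is.na(out)] <- 1
  out
}

.factor_row <- function(factors, code, side) {
  if (!code %in% rownames(factors))
    abort(sprintf("unknown residue code '%s'", code), "hdx_unknown_residue")
  factors[code, side]
}
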