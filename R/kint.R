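# Sequence-specific intrinsic exchange rates.

.seq_chars <- function(sequence) {
  if (length(sequence) == 1 && nchar(sequence) > 1)
    sequence <- strsplit(sequence, "")[[1]]
  toupper(sequence)
}

#' Intrinsic exchange rate of one backbone NH
#'
#' Evaluates
#' `k_int = AL*AR*A*[D+] + BL*BR*B*[OD-] + BL*BR*C`
#' where `AL`/`BL` are the factors of the residue's own side chain and
#' `AR`/`BR` those of the preceding residue's side chain; the protonated
#' alpha-amine contributes an extra right-factor at position 2 and the
#' carboxy terminus an extra left-factor at the last position.
#'
#' @param sequence one-letter sequence (string or character vector).
#' @param position 1-based index of the residue whose NH is evaluated.
#'   Position 1 (alpha-amine, no peptide NH) and prolines are rejected.
#' @param conditions an [exchange_conditions()] object.
#' @param params a [catalysis_params()] object; default: PDLA constants
#'   adjusted to `conditions$temperature`.
#' @param factors side-chain factor table from [sidechain_factors()].
#' @param proline_isomer `"trans"` or `"cis"`: isomer assumed when the
#'   preceding residue is a proline.
#' @param apply_nterm,apply_cterm apply the terminal-group corrections at
#'   positions 2 and n. Set `apply_nterm = FALSE` when the supplied
#'   sequence window does not start at the chain's true N-terminus (e.g.
#'   a numbering convention that drops leading tag residues), and
#'   likewise for `apply_cterm`.
#' @return rate in /min, with an attribute `terms` holding the acid, base
#'   and water contributions.
#' @export
k_int_for_residue <- function(sequence, position, conditions,
                              params = pdla_catalysis_defaults(conditions$temperature),
                              factors = sidechain_factors(conditions$pD),
                              proline_isomer = c("trans", "cis"),
                              apply_nterm = TRUE, apply_cterm = TRUE) {
  proline_isomer <- match.arg(proline_isomer)
  ch <- .seq_chars(sequence)
  n <- length(ch)
  if (position < 1 || position > n)
    abort("position outside sequence", "hdx_invalid_parameters")
  if (position == 1)
    abort("position 1 carries a free alpha-amine, not a peptide NH",
          "hdx_no_exchangeable_nh")
  res <- ch[position]
  if (res == "P")
    abort("proline has no exchangeable backbone NH",
          "hdx_no_exchangeable_nh")
  prev <- ch[position - 1]
  prev_code <- if (prev == "P") paste0("P_", proline_isomer) else prev

  AL <- .factor_row(factors, res, "AL")
  BL <- .factor_row(factors, res, "BL")
  AR <- .factor_row(factors, prev_code, "AR")
  BR <- .factor_row(factors, prev_code, "BR")
  if (position == 2 && apply_nterm) {  # alpha-amine: second left neighbour
    AR <- AR * factors["NT", "AR"]
    BR <- BR * factors["NT", "BR"]
  }
  if (position == n && apply_cterm) {  # carboxy terminus: own peptide group
    AL <- AL * factors["CT", "AL"]
    BL <- BL * factors["CT", "BL"]
  }

  ions <- ion_concentrations(conditions)
  terms <- c(acid  = AL * AR * params$A * ions$d_plus,
             base  = BL * BR * params$B * ions$od_minus,
             water = BL * BR * params$C)
  structure(sum(terms), terms = terms)
}

#' Blend intrinsic rates over proline cis/trans isomers
#'
#' For an NH following a proline the intrinsic rate depends on the proline
#' isomer state; the population-weighted rate is
#' `(1 - trans_fraction) * k_cis + trans_fraction * k_trans`, with 80%
#' trans assumed by default.
#'
#' @param k_int_cis,k_int_trans rates for the pure isomers, /min.
#' @param trans_fraction fraction of trans isomer in `[0, 1]`.
#' @export
k_int_after_proline <- function(k_int_cis, k_int_trans,
                                trans_fraction = 0.8) {
  if (any(trans_fraction < 0) || any(trans_fraction > 1))
    abort("trans_fraction must lie in [0, 1]", "hdx_invalid_parameters")
  (1 - trans_fraction) * k_int_cis + trans_fraction * k_int_trans
}

#' Per-residue intrinsic rates for a whole sequence
#'
#' Applies [k_int_for_residue()] along the chain. Residues following a
#' proline are blended over the cis/trans isomers with
#' [k_int_after_proline()]. Position 1 and prolines get `NA`.
#'
#' @inheritParams k_int_for_residue
#' @param trans_fraction proline trans population used for post-proline
#'   NHs.
#' @param offset added to the 1-based index to produce reported residue
#'   numbers (for constructs whose numbering does not start at the true
#'   N-terminus).
#' @return data.frame with columns `position`, `residue`, `kint` (/min)
#'   and the `acid`/`base`/`water` term decomposition.
#' @export
k_int_profile <- function(sequence, conditions,
                          params = pdla_catalysis_defaults(conditions$temperature),
                          factors = sidechain_factors(conditions$pD),
                          trans_fraction = 0.8, offset = 0,
                          apply_nterm = TRUE, apply_cterm = TRUE) {
  ch <- .seq_chars(sequence)
  n <- length(ch)
  out <- data.frame(position = seq_len(n) + offset, residue = ch,
                    kint = NA_real_, acid = NA_real_, base = NA_real_,
                    water = NA_real_)
  for (i in seq_len(n)) {
    if (i == 1 || ch[i] == "P") next
    if (ch[i - 1] == "P") {
      kt <- k_int_for_residue(ch, i, conditions, params, factors, "trans",
                              apply_nterm, apply_cterm)
      kc <- k_int_for_residue(ch, i, conditions, params, factors, "cis",
                              apply_nterm, apply_cterm)
      terms <- k_int_after_proline(attr(kc, "terms"), attr(kt, "terms"),
                                   trans_fraction)
    } else {
      k <- k_int_for_residue(ch, i, conditions, params, factors,
                             apply_nterm = apply_nterm,
                             apply_cterm = apply_cterm)
      terms <- attr(k, "terms")
    }
    out$acid[i] <- terms[["acid"]]
    out$base[i] <- terms[["base"]]
    out$water[i] <- terms[["water"]]
    out$kint[i] <- sum(terms)
  }
  out
}

#' Rescale the base/water reference contributions of an intrinsic rate
#'
#' Multiplies the base-catalysis and water-catalysis contributions by a
#' constant (e.g. 1.35, the empirical upward correction of the reference
#' base constant) while leaving the acid channel untouched. At
#' base-dominated pD this scales the whole rate, and hence the protection
#' factor, by the same constant.
#'
#' @param k_int a rate returned by [k_int_for_residue()] (carrying its
#'   `terms` attribute) or a profile data.frame from [k_int_profile()].
#' @param factor multiplicative correction, > 0; 1 is the identity.
#' @return same shape as the input with corrected rates.
#' @export
apply_reference_correction <- function(k_int, factor = 1.35) {
  if (!is.finite(factor) || factor <= 0)
    abort("correction factor must be positive", "hdx_invalid_parameters")
  if (is.data.frame(k_int)) {
    k_int$base <- k_int$base * factor
    k_int$water <- k_int$water * factor
    k_int$kint <- k_int$acid + k_int$base + k_int$water
    return(k_int)
  }
  terms <- attr(k_int, "terms")
  if (is.null(terms))
    abort("k_int lacks a term decomposition; recompute with k_int_for_residue",
          "hdx_invalid_parameters")
  terms[["base"]] <- terms[["base"]] * factor
  terms[["water"]] <- terms[["water"]] * factor
  structure(sum(terms), terms = terms)
}
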