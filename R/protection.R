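# EX2 protection analysis: protection factors, H-bond fractions,
# bond-breakage free energies, protection classes and per-helix summaries.
#
# Under EX2 (opening/closing fast relative to the chemical step) only the
# open, non-H-bonded form exchanges, so k_obs/k_int = 1 - f_hbond and the
# protection factor P = k_int/k_obs measures the closed-state population.

#' Protection factor
#'
#' `P = k_int / k_obs`. The relative error of k_obs propagates directly
#' into P when a standard error is supplied.
#'
#' @param k_int intrinsic rate, /min.
#' @param k_obs observed rate, /min.
#' @param k_obs_se optional standard error of `k_obs`.
#' @return P (with attribute `se` when `k_obs_se` is given).
#' @export
protection_factor <- function(k_int, k_obs, k_obs_se = NULL) {
  if (any(!is.finite(k_int)) || any(!is.finite(k_obs)) ||
      any(k_int <= 0) || any(k_obs <= 0))
    abort("rates must be finite and positive", "hdx_invalid_rate")
  P <- k_int / k_obs
  if (!is.null(k_obs_se)) attr(P, "se") <- P * k_obs_se / k_obs
  P
}

#' EX2 hydrogen-bond fraction
#'
#' `f_hbond = 1 - 1/P`, valid for P >= 1; values of P below 1 (exchange
#' faster than the unstructured reference) have no EX2 interpretation and
#' return `NA`.
#'
#' @param P protection factor(s).
#' @return fraction(s) in `[0, 1)`; `NA` where P < 1.
#' @export
f_hbond <- function(P) {
  out <- 1 - 1 / P
  out[P < 1] <- NA_real_
  as.numeric(out)
}

#' Free energy of hydrogen-bond breakage
#'
#' `dG = R*T*ln(f/(1-f)) = R*T*ln(P - 1)` in kcal/mol, with
#' R = 1.987e-3 kcal/mol/K. Defined for P > 1; exactly 0 at P = 2.
#'
#' @param P protection factor(s).
#' @param temperature kelvin (default 288.15, i.e. 15.0 C).
#' @return kcal/mol; `NA` where P <= 1.
#' @export
dG_breakage <- function(P, temperature = 288.15) {
  out <- rep(NA_real_, length(P))
  ok <- is.finite(P) & P > 1
  out[ok] <- R_KCAL * temperature * log(P[ok] - 1)
  out
}

#' Classify a protection factor
#'
#' Classes on P rounded to one decimal (matching the precision protection
#' factors are reported at, so borderline values classify consistently):
#' unprotected P < 2.0; significant 2.0 <= P < 4.0; high P >= 4.0.
#'
#' @param P protection factor(s).
#' @return factor with levels `unprotected`, `significant`, `high`.
#' @export
classify_protection <- function(P) {
  Pr <- round(P + 1e-9, 1)          # nudge so x.x5 rounds up, not to even
  cls <- ifelse(Pr >= 4.0, "high",
                ifelse(Pr >= 2.0, "significant", "unprotected"))
  factor(cls, levels = c("unprotected", "significant", "high"))
}

#' Tally protection classes
#'
#' @param P numeric vector of protection factors (`NA` = not followed).
#' @return list with `followed`, `unprotected`, `significant`, `high`,
#'   `protected` (significant + high).
#' @export
tally_classes <- function(P) {
  P <- P[is.finite(P)]
  cls <- classify_protection(P)
  counts <- table(cls)
  list(followed = length(P),
       unprotected = unname(counts[["unprotected"]]),
       significant = unname(counts[["significant"]]),
       high = unname(counts[["high"]]),
       protected = unname(counts[["significant"]] + counts[["high"]]))
}

#' Helix region definitions
#'
#' @param variant `"structure"` for the native-helix boundaries
#'   (H1 10-18, H2 25-37, H3 41-56) or `"extended"` for the variant that
#'   includes the helix-capping NH one residue past each C-terminus
#'   (10-19, 25-38, 41-57).
#' @return data.frame with columns `name`, `first`, `last`.
#' @export
helix_regions <- function(variant = c("structure", "extended")) {
  variant <- match.arg(variant)
  if (variant == "structure")
    data.frame(name = c("H1", "H2", "H3"), first = c(10, 25, 41),
               last = c(18, 37, 56))
  else
    data.frame(name = c("H1", "H2", "H3"), first = c(10, 25, 41),
               last = c(19, 38, 57))
}

#' Per-region protection summary
#'
#' Mean and median P over measured residues in each region, ranked by
#' mean (rank 1 = most protected). Regions without measured residues are
#' dropped from the ranking; exact ties are flagged.
#'
#' @param positions residue numbers.
#' @param P protection factors aligned with `positions` (`NA` allowed).
#' @param regions data.frame as returned by [helix_regions()].
#' @return data.frame `name`, `n`, `mean_P`, `median_P`, `rank`, `tied`.
#' @export
region_summary <- function(positions, P, regions = helix_regions()) {
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    sel <- positions >= regions$first[i] & positions <= regions$last[i] &
      is.finite(P)
    if (!any(sel)) return(NULL)
    data.frame(name = regions$name[i], n = sum(sel),
               mean_P = mean(P[sel]), median_P = stats::median(P[sel]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$rank <- rank(-out$mean_P, ties.method = "min")
  out$tied <- duplicated(out$mean_P) | duplicated(out$mean_P, fromLast = TRUE)
  out[order(out$rank), ]
}

#' Assemble a per-residue protection table
#'
#' Joins observed and intrinsic rates by residue position and derives P,
#' f_hbond, the breakage free energy, protection class and region label.
#'
#' @param kobs data.frame with columns `position`, `k_obs` and optionally
#'   `se` (/min).
#' @param kint data.frame with columns `position`, `kint` (/min) and
#'   optionally `residue`.
#' @param temperature kelvin, for the free-energy column.
#' @param regions region definitions from [helix_regions()].
#' @return data.frame with one row per position present in `kint`:
#'   `position`, `residue`, `k_obs`, `k_obs_se`, `k_int`, `P`, `f_hbond`,
#'   `dG_breakage`, `class`, `region`.
#' @export
protection_table <- function(kobs, kint, temperature = 288.15,
                             regions = helix_regions()) {
  m <- match(kint$position, kobs$position)
  k_obs <- kobs$k_obs[m]
  se <- if ("se" %in% names(kobs)) kobs$se[m] else NA_real_
  P <- ifelse(is.finite(k_obs) & is.finite(kint$kint),
              kint$kint / k_obs, NA_real_)
  region <- rep("other", nrow(kint))
  for (i in seq_len(nrow(regions))) {
    inr <- kint$position >= regions$first[i] & kint$position <= regions$last[i]
    region[inr] <- regions$name[i]
  }
  data.frame(
    position = kint$position,
    residue = if ("residue" %in% names(kint)) kint$residue else NA_character_,
    k_obs = k_obs, k_obs_se = se, k_int = kint$kint, P = P,
    f_hbond = f_hbond(P), dG_breakage = dG_breakage(P, temperature),
    class = classify_protection(P), region = region)
}
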