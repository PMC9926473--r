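# Backbone hydrogen-bond detection and structure annotation.
#
# The criterion is distance-only: an amide H and a carbonyl O at
# H...O <= 2.6 Angstrom are counted as hydrogen bonded. A donor-acceptor
# sequence separation of 4 marks an alpha-helical bond, 3 a 3_10-type
# bond.

#' Load backbone atoms from a PDB file
#'
#' Extracts per-residue N, CA, C, O (and H where present) coordinates from
#' the first model of a PDB file; missing amide protons are rebuilt at
#' ideal geometry ([amide_h_position()]). Prolines and the first residue
#' carry no amide H.
#'
#' @param file path to a PDB-format file.
#' @param offset added to the file's residue numbers to reach the working
#'   numbering convention.
#' @return object of class `backbone_atoms`: a list of per-atom coordinate
#'   matrices (`N`, `CA`, `C`, `O`, `H`; rows = residues) plus `resno` and
#'   `resid` vectors.
#' @export
load_backbone <- function(file, offset = 0) {
  pdb <- bio3d::read.pdb(file, multi = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  resnos <- unique(at$resno)
  n <- length(resnos)
  get <- function(elety) {
    m <- matrix(NA_real_, n, 3)
    sel <- at[at$elety %in% elety, ]
    idx <- match(sel$resno, resnos)
    m[idx, ] <- as.matrix(sel[, c("x", "y", "z")])
    m
  }
  N <- get("N"); CA <- get("CA"); C <- get("C"); O <- get("O")
  H <- get(c("H", "HN"))
  resid <- at$resid[match(resnos, at$resno)]
  if (any(!is.finite(N)) || any(!is.finite(C)) || any(!is.finite(O)) ||
      any(!is.finite(CA)))
    abort("missing backbone heavy atoms (N/CA/C/O)",
          "hdx_malformed_structure")
  for (i in seq_len(n)[-1]) {
    if (resid[i] == "PRO") next
    if (any(!is.finite(H[i, ])))
      H[i, ] <- amide_h_position(N[i, ], C[i - 1, ], CA[i, ])
  }
  structure(list(N = N, CA = CA, C = C, O = O, H = H,
                 resno = resnos + offset, resid = resid),
            class = "backbone_atoms")
}

#' Detect backbone hydrogen bonds by the H...O distance rule
#'
#' For each amide H, every carbonyl O within the cutoff (excluding the
#' residue's own and the preceding peptide group) is reported; the nearest
#' acceptor is flagged primary.
#'
#' @param atoms a `backbone_atoms` object.
#' @param cutoff maximum H...O distance in Angstrom (default 2.6).
#' @return data.frame `donor`, `acceptor` (residue numbers),
#'   `donor_resid`, `acceptor_resid`, `distance`, `helical_offset`
#'   (donor - acceptor), `primary`.
#' @export
detect_hbonds <- function(atoms, cutoff = 2.6) {
  stopifnot(inherits(atoms, "backbone_atoms"))
  n <- length(atoms$resno)
  rows <- list()
  for (i in seq_len(n)) {
    if (any(!is.finite(atoms$H[i, ]))) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2 && j <= i) next    # own / preceding peptide group
      d <- sqrt(sum((atoms$H[i, ] - atoms$O[j, ])^2))
      if (d <= cutoff) {
        rows[[length(rows) + 1]] <- data.frame(
          donor = atoms$resno[i], acceptor = atoms$resno[j],
          donor_resid = atoms$resid[i], acceptor_resid = atoms$resid[j],
          distance = d, helical_offset = i - j)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(donor = integer(), acceptor = integer(),
                      donor_resid = character(),
                      acceptor_resid = character(),
                      distance = numeric(), helical_offset = integer(),
                      primary = logical()))
  out <- do.call(rbind, rows)
  out$primary <- stats::ave(out$distance, out$donor,
                            FUN = function(d) d == min(d)) == 1
  out
}

#' Merge protection records with detected hydrogen bonds
#'
#' Adds the primary acceptor, its distance and the helical offset to each
#' protection record, and flags residues that are protected (class above
#' unprotected) yet lack a native backbone acceptor: their protection must
#' come from non-native interactions.
#'
#' @param records a [protection_table()]-shaped data.frame (columns
#'   `position`, `P`, `class`).
#' @param hbonds output of [detect_hbonds()].
#' @return `records` with added `acceptor`, `hbond_distance`,
#'   `helical_offset`, `non_native_protection`.
#' @export
annotate_with_structure <- function(records, hbonds) {
  if (!"position" %in% names(records))
    abort("records need a 'position' column", "hdx_join_failure")
  prim <- hbonds[hbonds$primary, , drop = FALSE]
  m <- match(records$position, prim$donor)
  records$acceptor <- prim$acceptor[m]
  records$hbond_distance <- prim$distance[m]
  records$helical_offset <- prim$helical_offset[m]
  records$non_native_protection <-
    !is.na(records$class) & records$class != "unprotected" &
    is.na(records$acceptor)
  records
}

#' Write a structure colored by protection factor
#'
#' Emits a PDB file whose B-factor column carries each residue's P value
#' (0 where unmeasured) so molecular viewers can color by protection, plus
#' a sidecar TSV assigning each measured residue to the highest threshold
#' tier its P value exceeds (strict inequality).
#'
#' @param atoms a `backbone_atoms` object.
#' @param records data.frame with `position` and `P`.
#' @param file output PDB path; the sidecar table goes to
#'   `<file>.tiers.tsv`.
#' @param thresholds ascending P thresholds (default 2, 3, 4, 5).
#' @return invisibly, the sidecar data.frame.
#' @export
write_structure_colormap <- function(atoms, records, file,
                                     thresholds = c(2, 3, 4, 5)) {
  stopifnot(all(diff(thresholds) > 0))
  n <- length(atoms$resno)
  P <- records$P[match(atoms$resno, records$position)]
  P[!is.finite(P)] <- 0
  types <- c("N", "CA", "C", "O", "H")
  xyz <- c(); resno <- c(); elety <- c(); bvals <- c(); resid <- c()
  for (i in seq_len(n)) {
    for (ty in types) {
      co <- atoms[[ty]][i, ]
      if (any(!is.finite(co))) next
      xyz <- c(xyz, co)
      resno <- c(resno, atoms$resno[i])
      resid <- c(resid, atoms$resid[i])
      elety <- c(elety, ty)
      bvals <- c(bvals, P[i])
    }
  }
  bio3d::write.pdb(file = file, xyz = xyz, resno = resno, resid = resid,
                   elety = elety, b = round(bvals, 2))
  tier <- vapply(P, function(p) {
    above <- thresholds[p > thresholds]
    if (length(above) == 0) "none" else paste0(">", max(above))
  }, character(1))
  sidecar <- data.frame(position = atoms$resno, P = round(P, 2),
                        tier = tier)
  utils::write.table(sidecar, paste0(file, ".tiers.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(sidecar)
}
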