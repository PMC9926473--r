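Package: hdxprotect
Title: Protection-Factor Analysis of DMSO-Quenched Hydrogen/Deuterium
    Exchange NMR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for amide hydrogen/deuterium (H/D) exchange
    of unfolded proteins measured by DMSO-quenched 2D NMR. Computes
    sequence-specific intrinsic exchange rates from the poly-DL-alanine
    reference rate law with nearest-neighbour side-chain corrections, fits
    single-exponential exchange decays to HSQC cross-peak volumes, converts
    observed and intrinsic rates into EX2 protection factors, hydrogen-bond
    fractions and bond-breakage free energies, fits two-state
    denaturant-unfolding transitions (Santoro-Bolen linear extrapolation)
    to circular dichroism data, models the helix-length dependence of the
    222 nm mean residue ellipticity, and maps backbone hydrogen bonds and
    protection values onto structure coordinates. Includes deterministic
    synthetic-data generators for every input so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
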