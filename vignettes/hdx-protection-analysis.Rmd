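---
title: "Methods: protection-factor analysis of DMSO-quenched H/D exchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protection-factor analysis of DMSO-quenched H/D exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxprotect)
```

## The measurement and its model

In a DMSO-quenched H/D-exchange experiment a protein is exposed to D2O
(here while unfolded in 6 M GdmCl at pD 3.8 and 15 °C), aliquots are
quenched at predetermined times into an acidified DMSO solution that
freezes the exchange, and the surviving NH protonation of each residue is
read out as an HSQC cross-peak volume. Each residue's signal decays as

$$Y(t) = \Delta Y\,e^{-k_\mathrm{obs} t} + Y(\infty),$$

single-exponential under these conditions, with a non-zero plateau
because the exchange buffer retains ~10% H2O
(`fit_single_exponential()`, `check_plateau()`).

The chemistry of exchange in an unstructured chain is acid-, base- and
water-catalyzed:

$$k_\mathrm{ref} = A\,[\mathrm{D^+}] + B\,[\mathrm{OD^-}] + C
                 = A\,10^{-\mathrm{pD}} + B\,10^{\mathrm{pD}-\mathrm{p}K_w} + C,$$

calibrated on poly-DL-alanine (PDLA). On a log scale this is V-shaped in
pD with a minimum at $(\mathrm{p}K_w + \log_{10} A/B)/2$;
`fit_catalysis_params()` estimates $(A, B, C)$ from a measured pD series
by least squares on $\log_{10} k_\mathrm{ref}$. The sequence-specific
intrinsic rate multiplies each channel by the side-chain factors of the
two residues flanking the peptide group (Bai convention: the right-factor
of the preceding residue and the left-factor of the residue's own side
chain), with extra factors for the protonated α-amine (acting on position
2) and the carboxy terminus (acting on the last peptide group):

$$k_\mathrm{int} = A_L A_R\,A\,[\mathrm{D^+}] + B_L B_R\,B\,[\mathrm{OD^-}]
                 + B_L B_R\,C.$$

Under the EX2 limit — structural opening and closing much faster than the
chemical step — only the open (non-H-bonded) fraction of each NH
exchanges, so

$$P = \frac{k_\mathrm{int}}{k_\mathrm{obs}}, \qquad
  f_\mathrm{Hbond} = 1 - \frac{1}{P}, \qquad
  \Delta G_\mathrm{breakage} = RT\,\ln\frac{f}{1-f} = RT\,\ln(P-1).$$

$P < 1$ (exchange faster than the reference) has no EX2 interpretation;
such values are reported but excluded from $f$ and $\Delta G$
(`NA`). The EX2 assumption itself is untested by this package: in the
EX1 limit $k_\mathrm{obs}$ would instead report the opening rate, and
the $f$/$\Delta G$ columns would be meaningless.

Two side analyses complete the picture. Equilibrium stability comes from
a two-state linear-extrapolation fit of a CD denaturation curve
(`fit_two_state()`): the observed ellipticity is the population-weighted
mean of two linearly sloping baselines with
$K = \exp(-(\Delta G^\circ - m c)/RT)$. And the helix-length CD model
(`theta_222()`),

$$[\theta]_{222,n} = [\theta]_{222,\infty}\,\frac{n-k}{n}
  \quad (k/n = 1 \text{ when } k > n),$$

explains why strong exchange protection can coexist with a flat 222 nm
CD signal: with the short-helix end-effect constant $k = 2.8$ a fully
formed one-turn helix ($n = 4$ peptide units) reads
$0.3\,[\theta]_{222,\infty} = -12{,}300$ deg cm²/dmol per helical
residue, but diluted over a 60-residue chain at realistic population the
chain-averaged signal is a few hundred (`ensemble_theta_222()`), below
CD detectability.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| pD | pH\* + 0.4 | — | fixed glass-electrode correction in D2O |
| pKw (D2O) | 15.24 | — | ionization of D2O at 15.0 °C |
| temperature | 288.15 | K | the exchange experiment's temperature |
| A, B, C | 10^1.62, 10^10.18, 10^−1.5 at 293.15 K | /M/min, /M/min, /min | published PDLA constants in D2O; Arrhenius-adjusted with Ea = 14/17/19 kcal/mol (acid/base/water). User-measured values (e.g. from a PDLA pD series at the working denaturant concentration) override them via `catalysis_params()` |
| base-reference correction | 1.35 | — | empirical upward revision of the base/water reference channel; `apply_reference_correction()` applies it to the base and water terms so P scales by the same factor at base-dominated pD |
| proline trans fraction | 0.8 | — | assumed cis/trans population for NHs following proline |
| model pKa (Asp, Glu, His, C-term) | 4.48, 4.93, 7.0, 4.0 | — | D2O-shifted model values; select the protonation-state factor variants. At the working pD 3.8 Asp/Glu are protonated |
| P class boundaries | 2.0 / 4.0 | — | unprotected / significant / high |
| H-bond cutoff | 2.6 | Å | maximum H···O distance; distance-only rule |
| colormap thresholds | 2, 3, 4, 5 | — | strict (">") tiers for structure coloring |

## Numerical choices

- **Nonlinear fits** use Levenberg–Marquardt (`minpack.lm::nlsLM`) with
  tight convergence tolerances (`ftol = ptol ≈ 1e-15`), so noiseless
  synthetic data are recovered to better than 6 significant digits — a
  fixed-point property the tests assert for every fitter.
- **Initial guesses** are data-derived: exponential fits take the
  plateau from the last point, the amplitude from first-minus-last and
  the rate from a log-linear regression of the plateau-subtracted
  signal; two-state fits take baselines from the three extreme points on
  each side, the midpoint from the steepest local gradient and m from
  the apparent transition width.
- **Degenerate inputs** raise classed conditions rather than returning
  garbage: constant decays (`hdx_fit_failure`), unbracketed transitions
  (the steepest gradient must exceed twice the median gradient;
  `hdx_ill_conditioned_fit`), proline/terminal positions
  (`hdx_no_exchangeable_nh`). The catalysis fit falls back to a
  linear-basis non-negative fit when the log-scale fit is singular
  (one-limb pD data) and flags the result ill-conditioned.
- **Rounding rule for classes**: P is rounded to one decimal before
  thresholding, with a tiny upward nudge so x.x5 rounds up rather than
  to even. This makes borderline residues (a recomputed ratio of 1.95
  that is reported as 2.0) classify consistently with values quoted at
  printed precision, and it is why the class tallies of the bundled
  table reproduce exactly.
- **Recomputed vs printed P**: printed ratios were formed before the
  rate columns were rounded, so recomputation from printed rates is held
  to ±0.1.
- **Region boundaries**: two published conventions exist
  (helix cores 10–18 / 25–37 / 41–56, or extended by one capping residue
  each). `helix_regions("structure")` is the default; the per-helix
  ranking (H3 most protected) is identical under both, which is why the
  choice is safe to default.
- **Ensemble CD model** is a deliberately simple linear mixture: species
  fractions must sum to ≤ 1, and non-helical residues contribute zero at
  222 nm (the coil band there is negligible for this purpose).

## What the synthetic generators emulate — and what they do not

`gen_decay_table()` produces exponential decays with a plateau at 10% of
the initial signal (residual H2O) and multiplicative Gaussian noise (5%
default — peak-volume error scales with intensity). `gen_pdla_series()`
produces the V-shaped reference-rate series over pD 1.5–4.5 with
lognormal rate noise. `gen_unfolding_curve()` produces a cooperative
two-state transition (ΔG° = 5.30 kcal/mol, m = 1.52 kcal/mol/M, midpoint
3.49 M) between sloping baselines over 0–6 M at 2% noise.
`gen_ideal_helix()` builds a polyalanine α-helix from ideal internal
coordinates — uniform (φ, ψ) = (−57°, −47°), trans peptides, amide
protons on the external bisector of C(i−1)–N–CA — which yields the
canonical ~1.5 Å rise and ~100° twist per residue and H···O(i−4)
distances of ~2.1 Å; the torsion parametrization is used instead of
literal rise/twist inputs because it is the only way to place chemically
correct carbonyl and amide-proton geometry, and the resulting rise/twist
are asserted in tests. All generators are bit-reproducible under a fixed
seed.

What passing these tests shows is that the estimators are unbiased and
self-consistent *under the assumed error model*. Real HSQC volume errors
are not exactly multiplicative-Gaussian (overlap, baseline distortion,
t1 noise), real unfolded ensembles are not a single helical species, and
real structures deviate from ideal helix geometry — so parameter
recovery on synthetic data bounds, but does not prove, accuracy on real
spectra.

## Known limitations

- The absolute intrinsic-rate scale depends on the PDLA calibration at
  the working denaturant concentration and temperature; the shipped
  defaults reproduce a reference-calibrated rate column only to within
  calibration uncertainty (~tens of percent), which is why rate-column
  agreement is a tolerant consistency check while the *ratios* (P) are
  exact. Measured $(A, B, C)$ should be supplied when available. The
  denaturant dependence of $k_\mathrm{ref}$ is not modeled — at pD ≈ 3.7
  the 0 M and 6 M values happen to coincide, which is what justifies
  using one calibration across conditions here.
- Only the H→D direction in D2O is implemented, and only backbone NHs
  (no Asn/Gln/Arg side-chain amides).
- H-bond detection is the stated distance-only rule, not DSSP/STRIDE;
  secondary-structure strings are accepted as annotation, never
  computed. For NMR ensembles only the first model is read.
- No EX1 or mixed-regime modeling, no three-state unfolding, no full CD
  spectrum calculation, no helix-propensity prediction.

## Problem sizes

The stochastic checks use 50 synthetic unfolding curves (15
concentrations each) and 100 synthetic decays (12 time points each),
with 20–40-replicate variants in the unit tests; these sizes put the
Monte-Carlo error of the recovered means well inside the 2% assertion
bands while keeping the whole suite to a few seconds.
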