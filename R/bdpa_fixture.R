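# Bundled study system: the B domain of staphylococcal protein A (BDPA),
# a 3-helix bundle, with its published per-residue exchange measurements
# in 6 M GdmCl (pD 3.8, 15 C). Rates are stored exactly as printed, in
# units of 1e-2 /min, to avoid transcription drift; positions follow the
# convention that the fourth residue of the construct (Met) is position 1.

.BDPA_SEQ <- "MADNKFNKEQQNAFYEILHLPNLNEEQRNGFIQSLKDDPSQSANLLAEAKKLNDAQAPK"

.BDPA_TABLE <- local({
  # residue, kobs_e2, kobs_se_e2, kint_e2, P_printed, hbond A, acceptor, ss
  txt <- "
residue pos kobs se kint P hb acc ss
A2   2   NA    NA   8.52  NA  NA  NA   Coil
D3   3   NA    NA  27.88  NA  NA  NA   Coil
N4   4   NA    NA  67.93  NA  NA  NA   Coil
K5   5   5.15  0.08 12.49 2.4 NA  NA   Coil
F6   6   NA    NA   4.99  NA  NA  NA   Turn
N7   7   NA    NA  23.20  NA  NA  NA   Turn
K8   8   NA    NA  12.49  NA  NA  NA   Turn
E9   9   4.02  0.17 14.36 3.6 2.4 7    Turn
Q10  10  NA    NA  17.46  NA  NA  NA   Helix
Q11  11  NA    NA  11.92  NA  NA  NA   Helix
N12  12  NA    NA  32.02  NA  NA  NA   Helix
A13  13  4.72  0.25 13.80 2.9 1.7 9    Helix
F14  14  2.61  0.13  3.82 1.5 1.9 10   Helix
Y15  15  2.01  0.05  4.06 2.0 2.4 11   Helix
E16  16  3.26  0.08 12.22 3.7 1.8 13   Helix
I17  17  1.22  0.05  2.84 2.3 2.0 13   Helix
L18  18  1.03  0.07  1.03 1.0 2.4 14   Helix
H19  19  NA    NA  25.43  NA  2.3 16   Coil
L20  20  NA    NA  11.63  NA  NA  NA   Turn
P21  21  NA    NA     NA  NA  NA  NA   Turn
N22  22  8.32  0.43 25.40 3.1 2.6 20   Turn
L23  23  NA    NA   3.63  NA  2.5 20   Turn
N24  24  5.18  0.54 12.49 2.4 NA  NA   Coil
E25  25  NA    NA  22.76  NA  NA  NA   Helix
E26  26  NA    NA  25.29  NA  NA  NA   Helix
Q27  27  NA    NA  17.46  NA  NA  NA   Helix
R28  28  NA    NA  12.48  NA  2.4 24   Helix
N29  29  13.36 1.09 33.53 2.5 1.7 25   Helix
G30  30  8.11  0.42 12.83 1.6 2.4 26   Helix
F31  31  NA    NA   5.65  NA  2.4 28   Helix
I32  32  NA    NA   1.41  NA  2.6 28   Helix
Q33  33  NA    NA   4.43  NA  1.8 29   Helix
S34  34  7.42  0.18 24.31 3.3 1.9 31   Helix
L35  35  2.58  0.11  3.45 1.3 2.5 31   Helix
K36  36  NA    NA   3.72  NA  2.1 32   Helix
D37  37  NA    NA  36.50  NA  2.3 33   Helix
D38  38  NA    NA  93.07  NA  1.7 34   Turn
P39  39  NA    NA     NA  NA  NA  NA   Turn
S40  40  8.36  1.00 19.28 2.3 NA  NA   Turn
Q41  41  NA    NA  14.99  NA  NA  NA   Helix
S42  42  9.53  0.45 24.31 2.6 NA  NA   Helix
A43  43  6.15  0.12 13.12 2.1 NA  NA   Helix
N44  44  9.99  0.82 20.24 2.0 2.4 41   Helix
L45  45  1.86  0.11  3.63 2.0 2.4 41   Helix
L46  46  NA    NA   1.10  NA  2.3 42   Helix
A47  47  1.94  0.12  4.18 2.1 2.4 43   Helix
E48  48  3.84  0.27 10.93 2.8 2.1 45   Helix
A49  49  2.93  0.16 15.30 5.2 2.3 45   Helix
K50  50  NA    NA   6.01  NA  2.3 46   Helix
K51  51  1.50  0.15  7.88 5.2 2.4 47   Helix
L52  52  1.54  0.08  2.29 1.5 2.1 48   Helix
N53  53  7.53  0.31 12.49 1.7 1.9 49   Helix
D54  54  NA    NA  57.82  NA  1.9 50   Helix
A55  55  5.50  0.60 22.23 4.0 2.3 51   Helix
Q56  56  4.00  0.12  7.57 1.9 2.5 52   Helix
A57  57  2.51  0.13 10.46 4.2 1.9 53   Coil
P58  58  NA    NA     NA  NA  NA  NA   Coil
K59  59  2.74  0.18  3.63 1.3 NA  NA   Coil
"
  df <- utils::read.table(text = txt, header = TRUE,
                          stringsAsFactors = FALSE)
  data.frame(residue = df$residue, position = df$pos,
             kobs_e2 = df$kobs, kobs_se_e2 = df$se, kint_e2 = df$kint,
             P = df$P, hbond_length = df$hb, acceptor = df$acc,
             sec_struct = df$ss)
})

#' Bundled BDPA exchange fixture
#'
#' The study system packaged as data: the conventionally numbered
#' sequence of the B domain of protein A (position 1 = Met, the fourth
#' residue of the expressed construct; numbering runs 1-59), the helix
#' region definitions, and the published per-residue exchange table
#' (observed and intrinsic rates in 1e-2 /min as printed, protection
#' factors, native H-bond lengths/acceptors and secondary structure).
#'
#' @return list with `sequence` (string), `numbering_offset` (3: residues
#'   preceding position 1 in the expressed construct), `regions`
#'   (see [helix_regions()]) and `table` (data.frame; one row per
#'   position, `NA` where a quantity was not measured, prolines `NA`
#'   throughout).
#' @export
bdpa_fixture <- function() {
  list(sequence = .BDPA_SEQ,
       numbering_offset = 3L,
       regions = helix_regions("structure"),
       table = .BDPA_TABLE)
}
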