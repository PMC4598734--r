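# Physical constants and composition tables used throughout the package.
# All masses in Da, m/z in Th, drift times in ms, CCS in A^2.

#' Mass-spectrometry constants
#'
#' Central table of the physical constants the package relies on: the proton
#' mass used for charging, the 13C-12C mass difference that sets isotopologue
#' spacing, and monoisotopic/average hydrogen-atom masses used by the
#' cross-link mass rule (two hydrogens lost per covalent bond).
#'
#' @return Named list with elements `proton`, `c13_c12`, `h_mono`, `h_avg`
#'   (all Da).
#' @export
#' @examples
#' ms_constants()$c13_c12
ms_constants <- function() {
  list(
    proton  = 1.007276,   # mass of H+
    c13_c12 = 1.003355,   # 13C - 12C
    h_mono  = 1.007825,   # monoisotopic H atom
    h_avg   = 1.00794     # average H atom
  )
}

# Monoisotopic and average atomic masses for the elements of unmodified
# peptides. Average masses are IUPAC standard atomic weights.
.element_masses <- data.frame(
  element = c("C", "H", "N", "O", "S"),
  mono    = c(12.000000, 1.0078250319, 14.0030740052, 15.9949146221, 31.97207069),
  avg     = c(12.011,    1.00794,      14.0067,       15.9994,       32.065),
  stringsAsFactors = FALSE
)

# Isotope distributions per element on the "extra neutrons" grid, index 1 = +0.
# Abundances from IUPAC 2013; trace isotopes below 1e-5 kept where they shift
# envelopes of kDa species (18O, 34S).
.element_isotopes <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0.0000, 0.0001)
)

# Elemental composition of amino-acid residues (peptide-bonded, i.e. free
# amino acid minus one water), canonical one-letter codes.
.residue_formulas <- list(
  G = c(C = 2,  H = 3,  N = 1, O = 1, S = 0),
  A = c(C = 3,  H = 5,  N = 1, O = 1, S = 0),
  S = c(C = 3,  H = 5,  N = 1, O = 2, S = 0),
  P = c(C = 5,  H = 7,  N = 1, O = 1, S = 0),
  V = c(C = 5,  H = 9,  N = 1, O = 1, S = 0),
  T = c(C = 4,  H = 7,  N = 1, O = 2, S = 0),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4,  H = 6,  N = 2, O = 2, S = 0),
  D = c(C = 4,  H = 5,  N = 1, O = 3, S = 0),
  Q = c(C = 5,  H = 8,  N = 2, O = 2, S = 0),
  K = c(C = 6,  H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5,  H = 7,  N = 1, O = 3, S = 0),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6,  H = 7,  N = 3, O = 1, S = 0),
  F = c(C = 9,  H = 9,  N = 1, O = 1, S = 0),
  R = c(C = 6,  H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9,  H = 9,  N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

#' Canonical amyloid-beta sequences
#'
#' One-letter sequences of the 40- and 42-residue amyloid-beta peptides.
#'
#' @return Named character vector with elements `Abeta40` and `Abeta42`.
#' @export
abeta_sequences <- function() {
  c(
    Abeta40 = "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVV",
    Abeta42 = "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"
  )
}
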