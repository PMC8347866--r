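#' @name mass-constants
#' @title Residue and modification mass constants
#'
#' @description
#' Monoisotopic and average masses (Da) of the 20 canonical amino acid
#' residues, of water, and of the modification deltas used throughout the
#' package: phosphorylation (HPO3), methionine oxidation (O), and the four
#' monosaccharide residue classes of compositional O-glycan analysis —
#' N-acetylhexosamine (N), hexose (H), deoxyhexose/fucose (F) and
#' N-acetylneuraminic/sialic acid (S).
#'
#' Values are elemental sums over IUPAC monoisotopic atomic masses
#' (monoisotopic scale) and IUPAC standard atomic weights (average scale),
#' frozen here to six decimals. Glycans are treated compositionally:
#' isomeric monosaccharides (e.g. GalNAc vs GlcNAc) are not distinguished.
NULL

# residue masses, Da (peptide-bond residues, i.e. amino acid minus water)
.MONO_RESIDUE <- c(
  A = 71.037114, R = 156.101111, N = 114.042927, D = 115.026943,
  C = 103.009185, E = 129.042593, Q = 128.058578, G = 57.021464,
  H = 137.058912, I = 113.084064, L = 113.084064, K = 128.094963,
  M = 131.040485, F = 147.068414, P = 97.052764, S = 87.032028,
  T = 101.047678, W = 186.079313, Y = 163.063329, V = 99.068414
)

.AVG_RESIDUE <- c(
  A = 71.077900, R = 156.185680, N = 114.102640, D = 115.087400,
  C = 103.142900, E = 129.113980, Q = 128.129220, G = 57.051320,
  H = 137.139280, I = 113.157640, L = 113.157640, K = 128.172280,
  M = 131.196060, F = 147.173860, P = 97.115180, S = 87.077300,
  T = 101.103880, W = 186.209900, Y = 163.173260, V = 99.131060
)

.MASS_WATER <- c(mono = 18.010565, avg = 18.015280)

# modification deltas, Da
.MASS_PHOSPHO <- c(mono = 79.966331, avg = 79.979900)
.MASS_OXIDATION <- c(mono = 15.994915, avg = 15.999400)

# monosaccharide residue masses in fixed letter order N, H, F, S
.MONO_GLYCAN <- c(N = 203.079373, H = 162.052824, F = 146.057909, S = 291.095417)
.AVG_GLYCAN  <- c(N = 203.192520, H = 162.140600, F = 146.141200, S = 291.254580)

.GLYCAN_LETTERS <- c("N", "H", "F", "S")

.check_scale <- function(scale) {
  match.arg(scale, c("mono", "avg"))
}
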