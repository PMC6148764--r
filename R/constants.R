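#' @keywords internal
"_PACKAGE"

## The 20 standard amino acids, one-letter, alphabetical.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)
AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

## Kyte-Doolittle hydropathy. Threshold 0 separates hydrophobic (>= 0)
## from hydrophilic (< 0) in the design filters.
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I =  4.5, L =  3.8, K = -3.9, M =  1.9, F =  2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

## Theoretical maximum SASA (A^2) of residue X in an extended Gly-X-Gly
## tripeptide (Tien et al. 2013, theoretical column); used to normalize
## residue SASA into relative SASA for surface/core classification.
MAX_SASA_GXG <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
  G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
  P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174
)

## Bondi-style van der Waals radii (Angstrom) by element; metals get
## ionic-scale radii so HETATM cofactors participate in distance work.
VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  FE = 1.94, ZN = 1.39, MN = 1.94, MG = 1.73, CA = 1.97, `NA` = 2.27,
  K = 2.75, CU = 1.40, NI = 1.63, CO = 1.53
)

## Side-chain interaction capabilities, used by the interaction-loss
## filter rule: can a residue type's side chain donate/accept hydrogen
## bonds, or carry a charge for salt bridges?
SIDECHAIN_HBOND_DONOR    <- c("R", "N", "Q", "H", "K", "S", "T", "W", "Y", "C")
SIDECHAIN_HBOND_ACCEPTOR <- c("D", "E", "N", "Q", "H", "S", "T", "Y", "M")
SIDECHAIN_POSITIVE <- c("K", "R", "H")
SIDECHAIN_NEGATIVE <- c("D", "E")

## Side-chain nitrogen/oxygen atom names relevant to polar interactions.
SALT_BRIDGE_N <- c("NZ", "NH1", "NH2", "NE", "ND1", "NE2")
SALT_BRIDGE_O <- c("OD1", "OD2", "OE1", "OE2")
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

## IUPAC nucleotide ambiguity codes.
IUPAC_NT <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
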