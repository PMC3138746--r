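# Canonical amino-acid tables used throughout the package.

#' The 20 canonical amino acids, one-letter codes, alphabetical
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

# chi1 rotamer grid (degrees) shared by all rotameric residues:
# gauche-minus, trans, gauche-plus. ALA and GLY are non-rotameric.
CHI1_ROTAMERS <- c(-60, 180, 60)

# chi1 rotamer prior probabilities, loosely following the populations
# observed in protein structures (g- favoured, g+ disfavoured). One generic
# triple is used for all rotameric types; beta-branched residues (V, I, T)
# prefer trans more strongly.
.rotamerPrior <- function(aa) {
  if (aa %in% c("A", "G")) return(1)
  if (aa %in% c("V", "I", "T")) return(c(0.25, 0.60, 0.15))
  c(0.52, 0.33, 0.15)
}

#' chi1 rotamer states for an amino-acid type
#'
#' @param aa one-letter amino-acid code.
#' @return data.frame with columns `chi1` (degrees, NA for ALA/GLY) and
#'   `prob` (prior probability, sums to 1).
#' @export
rotamerStates <- function(aa) {
  stopifnot(aa %in% AA_ALPHABET)
  if (aa %in% c("A", "G")) {
    return(data.frame(chi1 = NA_real_, prob = 1))
  }
  data.frame(chi1 = CHI1_ROTAMERS, prob = .rotamerPrior(aa))
}

# Distance (Angstrom) from CB to the side-chain pseudo-atom, one per type:
# roughly the centroid distance of the side chain beyond CB. ALA/GLY have
# no pseudo-atom beyond CB (distance 0 -> pseudo-atom sits on CB).
SC_DISTANCE <- c(A = 0.0, C = 1.8, D = 2.2, E = 2.9, F = 3.4, G = 0.0,
                 H = 3.1, I = 2.1, K = 3.6, L = 2.4, M = 2.9, N = 2.2,
                 P = 1.5, Q = 2.9, R = 4.1, S = 1.4, T = 1.4, V = 1.5,
                 W = 3.9, Y = 3.8)

# Effective LJ diameter (sigma, Angstrom) of the side-chain pseudo-atom,
# scaled with side-chain bulk.
SC_SIGMA <- c(A = 3.4, C = 3.8, D = 4.0, E = 4.3, F = 4.8, G = 3.0,
              H = 4.5, I = 4.4, K = 4.4, L = 4.5, M = 4.4, N = 4.0,
              P = 3.9, Q = 4.3, R = 4.6, S = 3.6, T = 3.9, V = 4.1,
              W = 5.0, Y = 4.9)

# LJ well depth (score units) per type; mildly deeper for large
# hydrophobics so packing has something to optimize.
SC_EPSILON <- c(A = 0.15, C = 0.20, D = 0.18, E = 0.18, F = 0.30, G = 0.10,
                H = 0.22, I = 0.28, K = 0.18, L = 0.28, M = 0.26, N = 0.18,
                P = 0.18, Q = 0.18, R = 0.18, S = 0.15, T = 0.18, V = 0.24,
                W = 0.32, Y = 0.30)

# sigma for backbone heavy atoms (N, CA, C, O, CB) in the clash term.
BACKBONE_SIGMA <- 3.2

# Gamma-position atoms used to measure native chi1 when a full side chain
# is present in the input coordinates.
GAMMA_ATOMS <- c("CG", "CG1", "OG", "OG1", "SG")

# Chemical similarity groups for the naive baseline profile.
SIMILARITY_GROUPS <- list(
  c("D", "E", "N", "Q"),
  c("R", "K", "H"),
  c("L", "I", "V", "M"),
  c("F", "Y", "W"),
  c("P", "A", "G"),
  c("S", "T"),
  "C"
)
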