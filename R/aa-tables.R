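#' Amino-acid reference tables
#'
#' Constant tables used across the sequence and structure profilers: the
#' Kyte-Doolittle hydropathy scale, a Bjellqvist-compatible side-chain and
#' terminus pKa set, Pace extinction-coefficient increments, van der Waals
#' radii for the elements that occur in protein crystal structures, and
#' theoretical maximum solvent accessibilities (Gly-X-Gly style) used to
#' normalise residue SASA into relative accessibility.
#'
#' All tables are plain named vectors so a caller can swap in an alternative
#' parameterisation without touching package internals.
#'
#' @name aa_tables
#' @keywords internal
NULL

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

AA3_TO_1 <- structure(names(AA3), names = unname(AA3))

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values; the mean over a sequence is the grand
#' average of hydropathy (GRAVY). More negative means more hydrophilic.
#'
#' @return Named numeric vector over the 20 canonical one-letter codes.
#' @export
#' @examples
#' kyte_doolittle_scale()[["A"]]  # 1.8
kyte_doolittle_scale <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)
}

#' Default pKa set for isoelectric-point calculation
#'
#' Bjellqvist-compatible values: side-chain pKa for D, E, C, Y, H, K, R and
#' generic terminal pKa values. Any named numeric vector with these nine
#' entries can be substituted.
#'
#' @return Named numeric vector with entries `Nterm`, `Cterm`, `D`, `E`,
#'   `C`, `Y`, `H`, `K`, `R`.
#' @export
pka_bjellqvist <- function() {
  c(Nterm = 7.5, Cterm = 3.55,
    D = 4.05, E = 4.45, C = 9.0, Y = 10.0,
    H = 5.98, K = 10.0, R = 12.0)
}

# Pace molar extinction increments at 280 nm (M^-1 cm^-1)
EPS_TRP <- 5500
EPS_TYR <- 1490
EPS_CYSTINE <- 125

#' Van der Waals radii used for SASA
#'
#' United-atom style radii (Angstrom) keyed by element symbol. Hydrogens are
#' listed but are excluded from SASA by default because crystal structures
#' rarely carry them.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
    P = 1.80, SE = 1.90)
}

#' Theoretical maximum accessible surface areas
#'
#' Tien et al.-style theoretical Gly-X-Gly maxima (Angstrom^2) used to turn a
#' residue's SASA into relative accessibility. Relative accessibility may
#' exceed 1 for distorted conformations; that is expected and harmless.
#'
#' @return Named numeric vector over the 20 one-letter codes.
#' @export
max_asa_theoretical <- function() {
  c(A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
    Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
    L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
    S = 155.0, T = 172.0, V = 174.0, W = 285.0, Y = 263.0)
}

# Common nonstandard residue names mapped onto a canonical parent (used when
# extracting sequences from coordinates; they still map to X in reports).
NONSTANDARD_PARENT <- c(MSE = "MET", SEC = "CYS", PYL = "LYS",
                        HYP = "PRO", SEP = "SER", TPO = "THR", PTR = "TYR")

aa3_to_1 <- function(resname) {
  out <- AA3_TO_1[resname]
  out[is.na(out)] <- "X"
  unname(out)
}

is_canonical_aa3 <- function(resname) resname %in% unname(AA3)
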