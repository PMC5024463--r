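# Shared amino-acid tables and small helpers used across modules.

# Three-letter names indexed by one-letter code (HGVS protein names).
AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", X = "Xaa", `*` = "Ter"
)

AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

# Three-letter residue names as they appear in PDB files.
AA_PDB_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)

NUCLEIC_RESIDUES <- c("DA", "DC", "DG", "DT", "DU", "DI",
                      "A", "C", "G", "U", "I")

# Theoretical maximum accessible surface area per residue (A^2),
# Tien et al. 2013 theoretical values; denominators for relative
# solvent accessibility.
MAX_ASA <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0
)

# Van der Waals radii (A) by element for surface-area integration.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
VDW_DEFAULT <- 1.70

# Charged side-chain atoms taking part in salt bridges.  DNA backbone
# phosphate oxygens count as negative partners.
POSITIVE_ATOMS <- list(
  ARG = c("NH1", "NH2", "NE"),
  LYS = c("NZ"),
  HIS = c("ND1", "NE2")
)
NEGATIVE_ATOMS <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2")
)
DNA_PHOSPHATE_ATOMS <- c("OP1", "OP2")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round a proportion for reporting
#'
#' Centralised rounding conventions used in all reported statistics:
#' confusion-matrix metrics to 2 decimals, percentages to 1 decimal.
#'
#' @param x Numeric vector.
#' @return Rounded numeric vector.
#' @export
round_metric <- function(x) round(x, 2)

#' @rdname round_metric
#' @export
round_percent <- function(x) round(x, 1)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     if.fuzzy.codon = "X"))
}
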