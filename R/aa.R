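#' Canonical amino-acid alphabet and weight groups
#'
#' The 20 canonical amino acids (one-letter codes, alphabetical) and the
#' 12-group partition used for the mutation-weighting scheme: chemically
#' similar residues share a weight (negative DE; small hydrophobic VIL;
#' large hydrophobic FY; polar uncharged STNQ; positive KH) while G, A, C,
#' M, P, W and R keep individual weights.
#'
#' @format `AA_CODES` is a character vector of length 20. `AA_GROUPS` is a
#'   named integer vector mapping each one-letter code to its group index
#'   in 1..12. `AA_GROUP_NAMES` labels the 12 groups.
#' @name aa-alphabet
NULL

#' @rdname aa-alphabet
#' @export
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' @rdname aa-alphabet
#' @export
AA_GROUP_NAMES <- c("DE", "VIL", "FY", "STNQ", "KH",
                    "G", "A", "C", "M", "P", "W", "R")

#' @rdname aa-alphabet
#' @export
AA_GROUPS <- c(D = 1L, E = 1L,
               V = 2L, I = 2L, L = 2L,
               F = 3L, Y = 3L,
               S = 4L, T = 4L, N = 4L, Q = 4L,
               K = 5L, H = 5L,
               G = 6L, A = 7L, C = 8L, M = 9L,
               P = 10L, W = 11L, R = 12L)

aa_index <- function(aa) {
  i <- match(aa, AA_CODES)
  if (anyNA(i)) {
    stop("unknown amino-acid code(s): ",
         paste(unique(aa[is.na(i)]), collapse = ", "))
  }
  i
}

is_canonical_aa <- function(aa) aa %in% AA_CODES
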