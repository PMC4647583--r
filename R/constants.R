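# Packaged physical constants and domain vocabularies.

# Standard monoisotopic atomic masses (u), most abundant isotope.
.ATOMIC_MASSES <- c(
  H  = 1.0078250319,
  C  = 12,
  N  = 14.0030740052,
  O  = 15.9949146221,
  Na = 22.98976928,
  P  = 30.97376163,
  S  = 31.97207100,
  K  = 38.96370668,
  Cl = 34.96885268,
  F  = 18.99840322,
  Br = 78.9183371,
  I  = 126.904473,
  Si = 27.9769265325,
  Se = 79.9165213,
  Mg = 23.9850417,
  Ca = 39.96259098,
  Fe = 55.9349375,
  Zn = 63.9291422,
  Cu = 62.9295975
)

# Electron rest mass (u); subtracted once per positive charge so that adduct
# m/z refers to the cation, not the neutral composition.
.ELECTRON_MASS <- 0.00054857990

# Closed enumeration of recognised assembly-line domain codes.
.DOMAIN_CODES <- c("KS", "AT", "PP", "KR", "DH", "ER", "AM", "C", "A",
                   "MT", "TE", "HXXPF")

.PROTEIN_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# IUPAC nucleotide degeneracy codes.
.IUPAC_NT <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Dinoflagellate spliced-leader consensus
#'
#' The 22-nt conserved spliced-leader (SL) sequence added to dinoflagellate
#' mRNA 5' ends by trans-splicing, with an IUPAC-degenerate first base
#' (`D` = A, G or T).
#'
#' @return A single character string, `"DCCGTAGCCATTTTGGCTCAAG"`.
#' @export
#' @examples
#' nchar(slConsensus())  # 22
slConsensus <- function() "DCCGTAGCCATTTTGGCTCAAG"

#' Default adduct specifications for positive-ion mode
#'
#' The three singly charged cation adducts observed for polyketide polyols in
#' positive-mode electrospray: protonated, ammoniated and sodiated.
#'
#' @return A named list of adduct specifications, each a list with elements
#'   `name`, `atoms` (named integer vector of atoms added to the neutral
#'   molecule) and `charge`.
#' @export
#' @examples
#' names(defaultAdducts())
defaultAdducts <- function() {
  list(
    "[M+H]+"   = list(name = "[M+H]+",   atoms = c(H = 1L),          charge = 1L),
    "[M+NH4]+" = list(name = "[M+NH4]+", atoms = c(N = 1L, H = 4L),  charge = 1L),
    "[M+Na]+"  = list(name = "[M+Na]+",  atoms = c(Na = 1L),         charge = 1L)
  )
}

#' Packaged atomic-mass table
#'
#' @return Named numeric vector of monoisotopic atomic masses (u), plus the
#'   electron mass as attribute `electron`.
#' @export
atomicMasses <- function() {
  out <- .ATOMIC_MASSES
  attr(out, "electron") <- .ELECTRON_MASS
  out
}
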