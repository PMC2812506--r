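# Monoisotopic residue masses (Da) of the 20 standard amino acids, and the
# physical constants used for fragment-ion arithmetic.

AA_MONO <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

PROTON_MASS <- 1.00727646688
WATER_MASS  <- 18.0105646863

#' Fixed-modification configurations
#'
#' The sample-preparation chemistry assumed by the pipeline blocks cysteines
#' with methylmethanethiosulphate (MMTS, +45.98772 Da) and attaches an
#' isobaric 4-plex label (+144.10207 Da) to every lysine side chain and to the
#' peptide N-terminus. `itraq_mmts()` encodes exactly that; `no_mods()` turns
#' all fixed shifts off.
#'
#' @return a list with components `residue` (named numeric vector of per-residue
#'   mass shifts) and `nterm` (mass shift applied once at the N-terminus).
#' @export
itraq_mmts <- function() {
  list(residue = c(C = 45.98772, K = 144.10207), nterm = 144.10207)
}

#' @rdname itraq_mmts
#' @export
no_mods <- function() {
  list(residue = numeric(0), nterm = 0)
}

# Per-residue masses of a peptide including fixed residue modifications.
residue_masses <- function(peptide, mods = itraq_mmts()) {
  check_aa(peptide)
  aa <- chars(peptide)
  m <- unname(AA_MONO[aa])
  if (length(mods$residue)) {
    shift <- mods$residue[aa]
    shift[is.na(shift)] <- 0
    m <- m + unname(shift)
  }
  m
}

#' Monoisotopic neutral peptide mass
#'
#' @param peptide amino-acid string (standard 20 letters).
#' @param mods fixed-modification configuration, see [itraq_mmts()].
#' @return neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(peptide, mods = itraq_mmts()) {
  sum(residue_masses(peptide, mods)) + WATER_MASS + mods$nterm
}

#' Theoretical singly charged b/y fragment ions
#'
#' Generates the singly protonated b- and y-ion ladders (b1..b(n-1),
#' y1..y(n-1)) for a peptide under a fixed-modification configuration. The
#' N-terminal shift is carried by b ions and by the full-length y ion only
#' (which is not emitted), matching where the label sits chemically.
#'
#' @inheritParams peptide_mass
#' @return numeric vector of m/z values named `b1..`/`y1..`, unsorted.
#' @export
theoretical_ions <- function(peptide, mods = itraq_mmts()) {
  m <- residue_masses(peptide, mods)
  n <- length(m)
  if (n < 2L) {
    stop("peptide must have at least 2 residues to produce fragment ions")
  }
  b <- cumsum(m)[seq_len(n - 1L)] + mods$nterm + PROTON_MASS
  y <- cumsum(rev(m))[seq_len(n - 1L)] + WATER_MASS + PROTON_MASS
  stats::setNames(c(b, y),
                  c(paste0("b", seq_len(n - 1L)), paste0("y", seq_len(n - 1L))))
}

#' Precursor m/z of a peptide at a given charge
#'
#' @inheritParams peptide_mass
#' @param charge positive integer charge state.
#' @return m/z in Thomson.
#' @export
precursor_mz <- function(peptide, charge = 2L, mods = itraq_mmts()) {
  stopifnot(charge >= 1L)
  (peptide_mass(peptide, mods) + charge * PROTON_MASS) / charge
}
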