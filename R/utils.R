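#' @keywords internal
"_PACKAGE"

#' @importFrom methods is
#' @importFrom stats plogis runif wilcox.test
#' @importFrom utils head tail
NULL

# Valid nucleotide alphabet: the four bases plus the IUPAC ambiguity letters.
DNA_ALPHABET <- c("A", "C", "G", "T",
                  "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Reverse-complement a nucleotide string
#'
#' @param x single character string over the IUPAC DNA alphabet.
#' @return the reverse complement as a character string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Validate a nucleotide sequence
#'
#' Errors (reporting the first offending position) when `x` contains a
#' character outside the IUPAC DNA alphabet.
#' @noRd
check_dna <- function(x, what = "sequence") {
  bad <- regexpr(sprintf("[^%s]", paste(DNA_ALPHABET, collapse = "")), x)
  if (bad != -1L) {
    stop(sprintf("invalid character '%s' at position %d of %s",
                 substr(x, bad, bad), bad, what), call. = FALSE)
  }
  invisible(x)
}

check_aa <- function(x, what = "peptide") {
  bad <- regexpr(sprintf("[^%s]", paste(AA_LETTERS, collapse = "")), x)
  if (bad != -1L) {
    stop(sprintf("unknown residue '%s' at position %d of %s",
                 substr(x, bad, bad), bad, what), call. = FALSE)
  }
  invisible(x)
}

# Split one string into a character vector of single letters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# Deterministic derivation of independent sub-seeds from one master seed,
# so each randomised stage of a fixture draws from its own stream.
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Truncate (not round) to two decimals; used for reported percentages where
# the convention is truncation.
trunc2 <- function(x) floor(x * 100 + 1e-9) / 100
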