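# In-silico tryptic digestion.

#' Tryptic digestion of a protein sequence
#'
#' Cleaves C-terminal to lysine or arginine except when the next residue is
#' proline, and emits all products with at most `missed` internal cleavage
#' sites. In `semi` mode, every sub-peptide of a full-tryptic product that
#' keeps one tryptic (or protein-terminal) end is additionally emitted, with
#' `tryptic_status = "semi"`.
#'
#' @param aa_seq protein sequence (amino-acid string).
#' @param missed maximum number of missed cleavage sites (default 1).
#' @param mode `"full"` or `"semi"`.
#' @param min_len minimum product length in residues (default 1, i.e. all).
#' @return `data.frame` with columns `pep`, `offset` (0-based start within
#'   the parent), `missed` and `tryptic_status`.
#' @export
digest <- function(aa_seq, missed = 1L, mode = c("full", "semi"),
                   min_len = 1L) {
  mode <- match.arg(mode)
  stopifnot(nzchar(aa_seq))
  n <- nchar(aa_seq)
  aa <- chars(aa_seq)
  # cleavage boundaries: after position i when aa[i] in {K,R} and aa[i+1] != P
  sites <- which(aa[-n] %in% c("K", "R") & aa[-1L] != "P")
  bounds <- c(0L, sites, n)             # product spans (bounds[j], bounds[k]]
  nb <- length(bounds)

  rows <- list()
  for (j in seq_len(nb - 1L)) {
    for (k in (j + 1L):min(nb, j + 1L + missed)) {
      s <- bounds[j] + 1L
      e <- bounds[k]
      rows[[length(rows) + 1L]] <- data.frame(
        pep = substr(aa_seq, s, e), offset = s - 1L,
        missed = k - j - 1L, tryptic_status = "full",
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)

  if (mode == "semi") {
    semi <- list()
    for (i in seq_len(nrow(out))) {
      s <- out$offset[i] + 1L
      len <- nchar(out$pep[i])
      if (len < 2L) next
      # ragged C-terminus (keep tryptic N-terminus)
      for (e in seq_len(len - 1L)) {
        semi[[length(semi) + 1L]] <- data.frame(
          pep = substr(out$pep[i], 1L, e), offset = s - 1L,
          missed = out$missed[i], tryptic_status = "semi",
          stringsAsFactors = FALSE)
      }
      # ragged N-terminus (keep tryptic C-terminus)
      for (b in 2:len) {
        semi[[length(semi) + 1L]] <- data.frame(
          pep = substr(out$pep[i], b, len), offset = s - 1L + b - 1L,
          missed = out$missed[i], tryptic_status = "semi",
          stringsAsFactors = FALSE)
      }
    }
    if (length(semi)) {
      semi <- do.call(rbind, semi)
      # a "semi" product identical in span to a full-tryptic one is full
      key <- paste(semi$pep, semi$offset)
      semi <- semi[!key %in% paste(out$pep, out$offset), , drop = FALSE]
      semi <- semi[!duplicated(paste(semi$pep, semi$offset)), , drop = FALSE]
      out <- rbind(out, semi)
    }
  }
  out <- out[nchar(out$pep) >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}
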