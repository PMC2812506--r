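# Construction of the coordinate-tracked six-frame translation database and
# its reversed decoy.
#
# An entry is a stop-to-stop segment from one reading frame of one strand,
# kept when it is at least `min_len` residues long and (optionally) contains
# a tryptic residue (K or R). Coordinates are 1-based inclusive positions of
# the translated nucleotides on the forward chromosome; minus-strand entries
# translate the reverse complement.

#' Six-frame translation of a chromosome with coordinate tracking
#'
#' Translates a nucleotide sequence in all three frames on both strands using
#' the standard genetic code, splitting at stop codons, and returns every
#' surviving segment as a putative protein with its genomic coordinates.
#'
#' Codons containing an IUPAC ambiguity letter are not translated. With
#' `ambiguity = "terminate"` (default) such a codon ends the current segment,
#' exactly like a stop codon, so every emitted entry is genomically
#' contiguous and satisfies `end - start + 1 == 3 * nchar(aa)`. With
#' `ambiguity = "skip"` the codon is dropped and the segment continues; the
#' coordinate span of such entries then covers the skipped codons and the
#' length identity no longer holds (the entry is flagged in `contiguous`).
#'
#' @param sequence chromosome sequence, a single string over the IUPAC DNA
#'   alphabet (or a `DNAString`).
#' @param chrom chromosome identifier recorded in each entry.
#' @param min_len minimum segment length in amino acids (default 6).
#' @param require_kr drop segments containing neither lysine nor arginine,
#'   which could never yield a tryptic peptide (default `TRUE`).
#' @param ambiguity how to handle codons containing ambiguity letters.
#' @return `data.frame` with columns `accession`, `chrom`, `strand` (+1/-1),
#'   `frame` (1-3, offset of the first translated nucleotide on the reading
#'   strand), `start`, `end` (1-based inclusive, forward strand), `aa`,
#'   `is_decoy` (all `FALSE`) and `contiguous`.
#' @export
translate_six_frame <- function(sequence, chrom = "chr1", min_len = 6L,
                                require_kr = TRUE,
                                ambiguity = c("terminate", "skip")) {
  ambiguity <- match.arg(ambiguity)
  if (is(sequence, "DNAString")) sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sequence")
  check_dna(sequence, what = sprintf("chromosome '%s'", chrom))
  n <- nchar(sequence)

  out <- vector("list", 6L)
  k <- 0L
  for (strand in c(1L, -1L)) {
    reading <- if (strand == 1L) sequence else revcomp(sequence)
    for (frame in 1:3) {
      k <- k + 1L
      ncod <- (n - frame + 1L) %/% 3L
      if (ncod < 1L) next
      dna <- Biostrings::DNAString(substr(reading, frame, frame + 3L * ncod - 1L))
      aa <- chars(as.character(Biostrings::translate(dna, no.init.codon = TRUE, if.fuzzy.codon = "X")))
      segs <- split_segments(aa, frame, ambiguity)
      if (!nrow(segs)) next
      keep <- nchar(segs$aa) >= min_len
      if (require_kr) keep <- keep & grepl("[KR]", segs$aa)
      segs <- segs[keep, , drop = FALSE]
      if (!nrow(segs)) next
      # reading-strand nt coordinates of the segment
      p1 <- frame + 3L * (segs$i1 - 1L)
      p2 <- frame + 3L * segs$i2 - 1L
      if (strand == 1L) {
        start <- p1; end <- p2
      } else {
        start <- n - p2 + 1L; end <- n - p1 + 1L
      }
      out[[k]] <- data.frame(
        chrom = chrom, strand = strand, frame = frame,
        start = start, end = end, aa = segs$aa,
        contiguous = segs$contiguous, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(chrom = character(), strand = integer(),
                      frame = integer(), start = integer(), end = integer(),
                      aa = character(), contiguous = logical(),
                      stringsAsFactors = FALSE)
  }
  res$accession <- sprintf("SF.%s.%s%d.%d", res$chrom,
                           ifelse(res$strand == 1L, "P", "M"),
                           res$frame, res$start)
  res$is_decoy <- rep(FALSE, nrow(res))
  rownames(res) <- NULL
  res[, c("accession", "chrom", "strand", "frame", "start", "end",
          "aa", "is_decoy", "contiguous")]
}

# Split a translated frame (character vector of residues, '*' for stop, 'X'
# for untranslatable codon) into retained segments. Returns codon-index
# bounds i1/i2 within the frame and the concatenated amino-acid string.
split_segments <- function(aa, frame, ambiguity) {
  is_stop <- aa == "*"
  is_amb <- aa == "X"
  brk <- if (ambiguity == "terminate") is_stop | is_amb else is_stop
  grp <- cumsum(brk)
  keep <- !brk
  if (!any(keep)) {
    return(data.frame(i1 = integer(), i2 = integer(), aa = character(),
                      contiguous = logical(), stringsAsFactors = FALSE))
  }
  idx <- which(keep)
  g <- grp[keep]
  i1 <- tapply(idx, g, min)
  i2 <- tapply(idx, g, max)
  seqs <- vapply(split(aa[keep], g), paste, character(1), collapse = "")
  contiguous <- !grepl("X", seqs, fixed = TRUE)
  seqs <- gsub("X", "", seqs, fixed = TRUE)   # only present in "skip" mode
  nonempty <- nzchar(seqs)
  data.frame(i1 = as.integer(i1)[nonempty], i2 = as.integer(i2)[nonempty],
             aa = unname(seqs[nonempty]), contiguous = contiguous[nonempty],
             stringsAsFactors = FALSE)
}

#' Reversed decoy database
#'
#' One decoy per target entry: the amino-acid sequence is reversed and the
#' accession prefixed with `DECOY_`. Entry counts, per-entry lengths and
#' total residue composition are preserved.
#'
#' @param entries target entry `data.frame` from [translate_six_frame()] (or
#'   any data frame with `accession` and `aa` columns).
#' @return a data frame of the same shape with `is_decoy = TRUE`.
#' @export
make_decoy <- function(entries) {
  stopifnot(all(c("accession", "aa") %in% names(entries)))
  d <- entries
  d$aa <- vapply(entries$aa,
                 function(s) paste(rev(chars(s)), collapse = ""),
                 character(1), USE.NAMES = FALSE)
  d$accession <- ifelse(grepl("^DECOY_", entries$accession),
                        sub("^DECOY_", "", entries$accession),
                        paste0("DECOY_", entries$accession))
  d$is_decoy <- !isTRUE_vec(entries$is_decoy, nrow(entries))
  d
}

isTRUE_vec <- function(x, n) {
  if (is.null(x)) rep(FALSE, n) else as.logical(x)
}

#' Encode / parse coordinate-carrying FASTA headers
#'
#' Headers have the fixed layout
#' `ACC|chrom|strand|frame|start|end|decoy_flag`, carrying everything needed
#' to reconstruct an entry's provenance from its FASTA record alone.
#'
#' @param entry one-row data frame (or list) with fields `accession`,
#'   `chrom`, `strand`, `frame`, `start`, `end`, `is_decoy`.
#' @return `encode_header()`: the header string (without the leading `>`).
#' @export
encode_header <- function(entry) {
  sprintf("%s|%s|%+d|%d|%d|%d|%d",
          entry$accession, entry$chrom, as.integer(entry$strand),
          as.integer(entry$frame), as.integer(entry$start),
          as.integer(entry$end), as.integer(isTRUE(as.logical(entry$is_decoy))))
}

#' @rdname encode_header
#' @param header a header string produced by [encode_header()].
#' @return `parse_header()`: a one-row data frame with the entry fields.
#' @export
parse_header <- function(header) {
  tok <- strsplit(header, "|", fixed = TRUE)[[1L]]
  if (length(tok) != 7L) {
    stop(sprintf("malformed header '%s': expected 7 '|'-separated tokens, got %d",
                 header, length(tok)))
  }
  num <- function(i, what) {
    v <- suppressWarnings(as.integer(tok[i]))
    if (is.na(v)) stop(sprintf("malformed header token '%s' (%s)", tok[i], what))
    v
  }
  strand <- num(3L, "strand")
  if (!strand %in% c(1L, -1L)) {
    stop(sprintf("malformed header token '%s' (strand must be +1 or -1)", tok[3L]))
  }
  data.frame(accession = tok[1L], chrom = tok[2L], strand = strand,
             frame = num(4L, "frame"), start = num(5L, "start"),
             end = num(6L, "end"),
             is_decoy = num(7L, "decoy_flag") == 1L,
             stringsAsFactors = FALSE)
}

#' Write / read an entry database as FASTA
#'
#' Sequences are wrapped at 60 columns; headers carry the genomic provenance
#' (see [encode_header()]).
#'
#' @param entries entry data frame.
#' @param path file path.
#' @export
write_orf_fasta <- function(entries, path) {
  headers <- vapply(seq_len(nrow(entries)),
                    function(i) encode_header(entries[i, ]), character(1))
  x <- Biostrings::AAStringSet(stats::setNames(entries$aa, headers))
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' @rdname write_orf_fasta
#' @return `read_orf_fasta()`: the entry data frame.
#' @export
read_orf_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  fields <- do.call(rbind, lapply(names(x), parse_header))
  fields$aa <- as.character(x, use.names = FALSE)
  fields$contiguous <- (fields$end - fields$start + 1L) == 3L * nchar(fields$aa)
  fields[, c("accession", "chrom", "strand", "frame", "start", "end",
             "aa", "is_decoy", "contiguous")]
}

#' Extract an oriented genomic subsequence
#'
#' @param genome named character vector or `DNAStringSet`, one element per
#'   chromosome.
#' @param chrom,start,end 1-based inclusive interval.
#' @param strand +1 or -1; minus returns the reverse complement.
#' @return nucleotide string in reading orientation.
#' @export
extract_genomic <- function(genome, chrom, start, end, strand = 1L) {
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  if (!chrom %in% names(genome)) stop(sprintf("chromosome '%s' not in genome", chrom))
  n <- nchar(genome[[chrom]])
  if (start < 1L || end > n || start > end) {
    stop(sprintf("interval %d-%d out of range for %s (length %d)",
                 start, end, chrom, n))
  }
  s <- substr(genome[[chrom]], start, end)
  if (strand == -1L) s <- revcomp(s)
  s
}

#' Translate a nucleotide string in one frame
#'
#' Helper used by round-trip checks and the junction database: standard-code
#' translation of `nt` starting at `frame`, keeping `*` for stops and `X`
#' for ambiguous codons.
#' @param nt nucleotide string.
#' @param frame 1, 2 or 3.
#' @return amino-acid string (possibly containing `*`/`X`).
#' @export
translate_frame <- function(nt, frame = 1L) {
  ncod <- (nchar(nt) - frame + 1L) %/% 3L
  if (ncod < 1L) return("")
  dna <- Biostrings::DNAString(substr(nt, frame, frame + 3L * ncod - 1L))
  as.character(Biostrings::translate(dna, no.init.codon = TRUE, if.fuzzy.codon = "X"))
}
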