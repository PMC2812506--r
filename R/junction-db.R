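# Exon-junction peptide database.
#
# Peptides spanning splice junctions are invisible to a linear six-frame
# translation of the genome. To account for them, the 3' end of each
# donor-eligible exon (up to `end_len` nt) is concatenated with the 5' end
# of each acceptor-eligible exon of the same gene and translated in three
# frames. Pairing every donor with every acceptor (including self-pairs)
# covers annotated junctions, exon skipping and alternative junctions; a
# within-transcript mode restricts pairs to exons of one transcript.

#' Build the exon-junction peptide database
#'
#' @param gene_models gene-model table: a `data.frame` with columns `chrom`,
#'   `start`, `end` (1-based inclusive exon coordinates), `strand` (`"+"` or
#'   `"-"`), `gene_id`, `transcript_id`, `exon_id`, `exon_rank` (1 =
#'   5'-most exon of the transcript).
#' @param genome named character vector or `DNAStringSet` of chromosomes.
#' @param end_len nucleotides taken from each exon end (default 54); exons
#'   shorter than `end_len` contribute their whole sequence.
#' @param pairing `"gene"` (default): all donor x acceptor exon pairs within
#'   a gene; `"transcript"`: pairs restricted to exons of one transcript.
#' @return `data.frame` with one row per junction: `accession`, `gene_id`,
#'   `donor_exon_id`, `acceptor_exon_id`, `nt` (donor 3' end + acceptor 5'
#'   end, reading orientation), `aa_f1`, `aa_f2`, `aa_f3` (three-frame
#'   translations, `*` marks stops) and `end_len`.
#' @details A 5'-terminal exon contributes only its 3' end (donor role); a
#'   3'-terminal exon only its 5' end (acceptor role). With multiple
#'   transcripts an exon is donor-eligible if any transcript places it before
#'   its last exon, and acceptor-eligible if any places it after its first.
#' @export
build_junction_db <- function(gene_models, genome, end_len = 54L,
                              pairing = c("gene", "transcript")) {
  pairing <- match.arg(pairing)
  gm <- validate_gene_models(gene_models, genome)
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)

  res <- list()
  for (g in unique(gm$gene_id)) {
    sub <- gm[gm$gene_id == g, , drop = FALSE]
    # eligibility per transcript, then union over transcripts per exon
    elig <- do.call(rbind, lapply(split(sub, sub$transcript_id), function(tx) {
      data.frame(exon_id = tx$exon_id,
                 donor = tx$exon_rank < max(tx$exon_rank),
                 acceptor = tx$exon_rank > 1L,
                 transcript_id = tx$transcript_id,
                 stringsAsFactors = FALSE)
    }))
    exons <- sub[!duplicated(sub$exon_id), , drop = FALSE]
    donor_ok <- vapply(exons$exon_id,
                       function(e) any(elig$donor[elig$exon_id == e]), logical(1))
    acc_ok <- vapply(exons$exon_id,
                     function(e) any(elig$acceptor[elig$exon_id == e]), logical(1))

    pairs <- if (pairing == "gene") {
      expand.grid(d = exons$exon_id[donor_ok], a = exons$exon_id[acc_ok],
                  stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(split(elig, elig$transcript_id), function(tx) {
        expand.grid(d = tx$exon_id[tx$donor], a = tx$exon_id[tx$acceptor],
                    stringsAsFactors = FALSE)
      }))
    }
    if (is.null(pairs) || !nrow(pairs)) next
    pairs <- pairs[!duplicated(pairs), , drop = FALSE]

    seq_of <- function(e) {
      r <- exons[exons$exon_id == e, ]
      extract_genomic(genome, r$chrom, r$start, r$end,
                      if (r$strand == "+") 1L else -1L)
    }
    exon_seq <- stats::setNames(vapply(exons$exon_id, seq_of, character(1)),
                                exons$exon_id)
    donor_end <- function(s) substr(s, max(1L, nchar(s) - end_len + 1L), nchar(s))
    acceptor_end <- function(s) substr(s, 1L, min(end_len, nchar(s)))

    nt <- paste0(vapply(exon_seq[pairs$d], donor_end, character(1)),
                 vapply(exon_seq[pairs$a], acceptor_end, character(1)))
    res[[g]] <- data.frame(
      accession = sprintf("JX.%s.%s.%s", g, pairs$d, pairs$a),
      gene_id = g, donor_exon_id = pairs$d, acceptor_exon_id = pairs$a,
      nt = nt,
      aa_f1 = vapply(nt, translate_frame, character(1), frame = 1L),
      aa_f2 = vapply(nt, translate_frame, character(1), frame = 2L),
      aa_f3 = vapply(nt, translate_frame, character(1), frame = 3L),
      end_len = end_len, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(accession = character(), gene_id = character(),
                      donor_exon_id = character(), acceptor_exon_id = character(),
                      nt = character(), aa_f1 = character(), aa_f2 = character(),
                      aa_f3 = character(), end_len = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Does a peptide occur in the junction translations?
#'
#' Exact substring test of `peptide` against all three frame translations of
#' every junction entry (stops break matches naturally).
#'
#' @param junctions output of [build_junction_db()].
#' @param peptide amino-acid string.
#' @return `TRUE` when the peptide occurs in at least one translation.
#' @export
junction_contains <- function(junctions, peptide) {
  if (!nrow(junctions)) return(FALSE)
  any(grepl(peptide, c(junctions$aa_f1, junctions$aa_f2, junctions$aa_f3),
            fixed = TRUE))
}

validate_gene_models <- function(gene_models, genome = NULL) {
  need <- c("chrom", "start", "end", "strand", "gene_id", "transcript_id",
            "exon_id", "exon_rank")
  miss <- setdiff(need, names(gene_models))
  if (length(miss)) {
    stop("gene models missing columns: ", paste(miss, collapse = ", "))
  }
  stopifnot(all(gene_models$strand %in% c("+", "-")))
  if (!is.null(genome)) {
    if (is(genome, "DNAStringSet")) genome <- as.character(genome)
    bad <- setdiff(unique(gene_models$chrom), names(genome))
    if (length(bad)) {
      stop("gene models reference chromosomes absent from genome: ",
           paste(bad, collapse = ", "))
    }
    len <- nchar(genome)[match(gene_models$chrom, names(genome))]
    if (any(gene_models$start < 1L | gene_models$end > len)) {
      stop("exon coordinates outside chromosome bounds")
    }
  }
  gene_models
}
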