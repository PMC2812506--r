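# Gene-model (GTF) I/O.
#
# Internally a gene-model table is a plain data frame with one row per exon
# per transcript: chrom, start, end (1-based inclusive), strand, gene_id,
# transcript_id, exon_id, exon_rank, phase. `phase` is the GTF frame value
# of the exon's coding sequence (bases to skip before the first complete
# codon), NA for non-coding exons.

#' Write / read gene models as GTF
#'
#' Each exon row becomes an `exon` feature plus, when `phase` is not `NA`,
#' a `CDS` feature with the frame column set. Reading reverses the mapping.
#'
#' @param gene_models gene-model table (see above).
#' @param path GTF file path.
#' @export
write_gene_models <- function(gene_models, path) {
  gm <- validate_gene_models(gene_models)
  if (is.null(gm$phase)) gm$phase <- NA_integer_
  coding <- !is.na(gm$phase)
  mk <- function(rows, type, phase) {
    GenomicRanges::GRanges(
      seqnames = rows$chrom,
      ranges = IRanges::IRanges(rows$start, rows$end),
      strand = rows$strand, type = type,
      gene_id = rows$gene_id, transcript_id = rows$transcript_id,
      exon_id = rows$exon_id, exon_number = rows$exon_rank, phase = phase
    )
  }
  gr <- c(mk(gm, "exon", NA_integer_),
          mk(gm[coding, , drop = FALSE], "CDS", gm$phase[coding]))
  gr <- gr[order(S4Vectors::mcols(gr)$transcript_id,
                 S4Vectors::mcols(gr)$exon_number)]
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname write_gene_models
#' @return `read_gene_models()`: the gene-model table.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  ex <- gr[mc$type == "exon"]
  cds <- gr[mc$type == "CDS"]
  gm <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(ex)),
    start = GenomicRanges::start(ex), end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_id = S4Vectors::mcols(ex)$gene_id,
    transcript_id = S4Vectors::mcols(ex)$transcript_id,
    exon_id = S4Vectors::mcols(ex)$exon_id,
    exon_rank = as.integer(S4Vectors::mcols(ex)$exon_number),
    stringsAsFactors = FALSE
  )
  key <- paste(gm$transcript_id, gm$exon_id)
  cds_key <- paste(S4Vectors::mcols(cds)$transcript_id,
                   S4Vectors::mcols(cds)$exon_id)
  gm$phase <- as.integer(S4Vectors::mcols(cds)$phase[match(key, cds_key)])
  gm[order(gm$transcript_id, gm$exon_rank), , drop = FALSE]
}
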