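# Peptide-to-genome mapping and annotation classification.

#' Genomic interval of a peptide within its parent six-frame entry
#'
#' Because a six-frame entry records the genomic span of its translated
#' nucleotides, a peptide's locus follows from its residue offset within the
#' parent: on the plus strand the interval starts `3 * offset_aa` after the
#' parent start; on the minus strand it ends `3 * offset_aa` before the
#' parent end.
#'
#' @param parent one-row data frame (or list) with `chrom`, `strand`,
#'   `start`, `end`, `aa` fields of the parent entry.
#' @param offset_aa 0-based residue offset of the peptide in the parent.
#' @param len_aa peptide length in residues.
#' @return list with `chrom`, `strand`, `start`, `end` (1-based inclusive).
#' @export
map_peptide_locus <- function(parent, offset_aa, len_aa) {
  if (offset_aa < 0 || len_aa < 1 ||
      offset_aa + len_aa > nchar(parent$aa)) {
    stop(sprintf("peptide span (offset %d, length %d) outside parent '%s'",
                 offset_aa, len_aa, parent$accession))
  }
  if (parent$strand == 1L) {
    start <- parent$start + 3L * offset_aa
    end <- start + 3L * len_aa - 1L
  } else {
    end <- parent$end - 3L * offset_aa
    start <- end - 3L * len_aa + 1L
  }
  list(chrom = parent$chrom, strand = as.integer(parent$strand),
       start = as.integer(start), end = as.integer(end))
}

#' Build an annotation index from a gene-model table
#'
#' Gene spans are defined operationally as the minimum exon start to the
#' maximum exon end per `gene_id`.
#'
#' @param gene_models gene-model table (see [build_junction_db()]) with an
#'   optional `phase` column on exons: the number of bases at the exon's 5'
#'   end belonging to a codon started in the previous exon (GTF frame
#'   convention), `NA` for non-coding exons.
#' @return list of class `annotation` with `genes` and `exons`
#'   (`GRanges`), and the original table.
#' @export
build_annotation <- function(gene_models) {
  gm <- validate_gene_models(gene_models)
  if (is.null(gm$phase)) gm$phase <- NA_integer_
  ex <- gm[!duplicated(gm$exon_id), , drop = FALSE]
  exons <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(ex$start, ex$end),
    strand = ex$strand, gene_id = ex$gene_id, exon_id = ex$exon_id,
    phase = ex$phase
  )
  spans <- do.call(rbind, lapply(split(ex, ex$gene_id), function(s) {
    data.frame(chrom = s$chrom[1L], start = min(s$start), end = max(s$end),
               strand = s$strand[1L], gene_id = s$gene_id[1L],
               stringsAsFactors = FALSE)
  }))
  genes <- GenomicRanges::GRanges(
    seqnames = spans$chrom, ranges = IRanges::IRanges(spans$start, spans$end),
    strand = spans$strand, gene_id = spans$gene_id
  )
  structure(list(genes = genes, exons = exons, table = gm),
            class = "annotation")
}

#' Classify a peptide locus against gene annotation
#'
#' A single-locus peptide receives exactly one label:
#' `multi_target` when the peptide matches more than one genomic locus;
#' `intergenic` when it overlaps no gene span; `intronic` when inside a gene
#' but overlapping no exon; `exonic_in_frame` / `exonic_not_in_frame` when
#' fully inside an exon, depending on whether its codon phase (and strand)
#' agree with the exon's annotated reading frame; `exonic_extending_5p` /
#' `_3p` when it partially overlaps an exon boundary into flanking sequence
#' (the exceeded edge named 5' or 3' in the exon's transcriptional
#' orientation). Gene/exon containment is strand-agnostic (an antisense
#' peptide inside an exon is still exonic, necessarily not in frame); the
#' in-frame test is positional, not a mere sequence-containment test, so
#' repeated subsequences cannot produce false in-frame calls.
#'
#' @param locus list from [map_peptide_locus()] (`chrom`, `strand`, `start`,
#'   `end`).
#' @param annotation result of [build_annotation()].
#' @param n_genomic_matches number of distinct genomic loci matching the
#'   peptide sequence (default 1).
#' @return list with `label`, `gene_id`, `exon_id` (NA where inapplicable).
#' @export
classify_locus <- function(locus, annotation, n_genomic_matches = 1L) {
  if (!locus$chrom %in% unique(annotation$table$chrom)) {
    stop(sprintf("chromosome '%s' absent from annotation space", locus$chrom))
  }
  if (n_genomic_matches > 1L) {
    return(list(label = "multi_target", gene_id = NA_character_,
                exon_id = NA_character_))
  }
  q <- GenomicRanges::GRanges(locus$chrom,
                              IRanges::IRanges(locus$start, locus$end))
  ex_hits <- GenomicRanges::findOverlaps(q, annotation$exons,
                                         ignore.strand = TRUE)
  if (length(ex_hits)) {
    idx <- S4Vectors::subjectHits(ex_hits)
    exons <- annotation$exons[idx]
    # prefer a containing exon; else classify against the first overlapped
    # exon (sorted), logging ambiguity across genes
    genes_hit <- unique(S4Vectors::mcols(exons)$gene_id)
    if (length(genes_hit) > 1L) {
      warning("peptide locus overlaps exons of multiple genes: ",
              paste(genes_hit, collapse = ", "), "; using first in sorted order")
    }
    o <- order(GenomicRanges::start(exons))
    exons <- exons[o]
    within <- GenomicRanges::start(exons) <= locus$start &
      GenomicRanges::end(exons) >= locus$end
    if (any(within)) {
      exon <- exons[which(within)[1L]]
      lab <- if (in_frame(locus, exon)) "exonic_in_frame" else "exonic_not_in_frame"
      return(list(label = lab,
                  gene_id = S4Vectors::mcols(exon)$gene_id,
                  exon_id = S4Vectors::mcols(exon)$exon_id))
    }
    exon <- exons[1L]
    ex_start <- GenomicRanges::start(exon)
    ex_end <- GenomicRanges::end(exon)
    ex_strand <- as.character(GenomicRanges::strand(exon))
    beyond_end <- locus$end > ex_end
    beyond_start <- locus$start < ex_start
    edge <- if (beyond_end && !beyond_start) "high"
            else if (beyond_start && !beyond_end) "low"
            else "both"
    lab <- if (edge == "both") {
      "exonic_extending_5p"   # spans the whole exon; report the 5' edge
    } else if ((edge == "high" && ex_strand == "+") ||
               (edge == "low" && ex_strand == "-")) {
      "exonic_extending_3p"
    } else {
      "exonic_extending_5p"
    }
    return(list(label = lab,
                gene_id = S4Vectors::mcols(exon)$gene_id,
                exon_id = S4Vectors::mcols(exon)$exon_id))
  }
  g_hits <- GenomicRanges::findOverlaps(q, annotation$genes,
                                        ignore.strand = TRUE)
  if (length(g_hits)) {
    gene <- annotation$genes[S4Vectors::subjectHits(g_hits)[1L]]
    return(list(label = "intronic",
                gene_id = S4Vectors::mcols(gene)$gene_id,
                exon_id = NA_character_))
  }
  list(label = "intergenic", gene_id = NA_character_, exon_id = NA_character_)
}

# Positional in-frame test: the peptide must lie on the exon's strand and
# start on a codon boundary of the exon's annotated reading frame. `phase`
# is the GTF frame value: bases to skip at the exon 5' end before the first
# complete codon.
in_frame <- function(locus, exon) {
  phase <- S4Vectors::mcols(exon)$phase
  if (is.na(phase)) return(FALSE)
  ex_strand <- as.character(GenomicRanges::strand(exon))
  pep_strand <- if (locus$strand == 1L) "+" else "-"
  if (ex_strand != pep_strand) return(FALSE)
  if (ex_strand == "+") {
    codon_start <- GenomicRanges::start(exon) + phase
    (locus$start - codon_start) %% 3L == 0L
  } else {
    codon_start <- GenomicRanges::end(exon) - phase
    (codon_start - locus$end) %% 3L == 0L
  }
}

#' Classify many loci
#'
#' @param loci data frame with `chrom`, `strand`, `start`, `end` and
#'   optionally `n_genomic_matches`.
#' @param annotation result of [build_annotation()].
#' @return input with `label`, `gene_id`, `exon_id` columns appended.
#' @export
classify_loci <- function(loci, annotation) {
  nm <- if (is.null(loci$n_genomic_matches)) rep(1L, nrow(loci)) else
    loci$n_genomic_matches
  res <- lapply(seq_len(nrow(loci)), function(i) {
    classify_locus(list(chrom = loci$chrom[i], strand = loci$strand[i],
                        start = loci$start[i], end = loci$end[i]),
                   annotation, nm[i])
  })
  loci$label <- vapply(res, `[[`, character(1), "label")
  loci$gene_id <- vapply(res, `[[`, character(1), "gene_id")
  loci$exon_id <- vapply(res, `[[`, character(1), "exon_id")
  loci
}

#' Count distinct genomic loci matching a peptide
#'
#' Scans the target six-frame entries for exact occurrences of the peptide
#' and counts the distinct genomic intervals they map to (entries in
#' different frames/strands can cover the same locus only with different
#' intervals, so interval identity is the right key).
#'
#' @param pep peptide sequence.
#' @param entries six-frame entry data frame (decoys are ignored).
#' @return integer count of distinct loci.
#' @export
count_genomic_loci <- function(pep, entries) {
  tgt <- entries[!isTRUE_vec(entries$is_decoy, nrow(entries)), , drop = FALSE]
  hit <- grepl(pep, tgt$aa, fixed = TRUE)
  if (!any(hit)) return(0L)
  tgt <- tgt[hit, , drop = FALSE]
  keys <- character(0)
  for (i in seq_len(nrow(tgt))) {
    offs <- gregexpr(pep, tgt$aa[i], fixed = TRUE)[[1L]]
    for (o in offs) {
      loc <- map_peptide_locus(tgt[i, ], o - 1L, nchar(pep))
      keys <- c(keys, paste(loc$chrom, loc$strand, loc$start, loc$end))
    }
  }
  length(unique(keys))
}

#' Export peptide loci as BED
#'
#' Conversion from 1-based inclusive to BED's 0-based half-open convention
#' happens at this boundary (delegated to `rtracklayer`).
#'
#' @param loci data frame with `chrom`, `start`, `end`, `strand` and
#'   optionally `name`.
#' @param path output BED path.
#' @export
loci_to_bed <- function(loci, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom, ranges = IRanges::IRanges(loci$start, loci$end),
    strand = ifelse(loci$strand == 1L | loci$strand == "+", "+", "-")
  )
  if (!is.null(loci$name)) names(gr) <- loci$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname loci_to_bed
#' @return `bed_to_loci()`: data frame with 1-based inclusive `start`/`end`.
#' @export
bed_to_loci <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                             -1L, 1L),
             stringsAsFactors = FALSE)
}
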