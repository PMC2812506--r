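# Pseudogene, repeat, EST and conservation filters on candidate loci.

#' Exact strand-aware DNA match against a reference sequence set
#'
#' A candidate's genomic coding sequence matches when it occurs verbatim
#' (100% identity, full length) as a substring of any reference sequence.
#' The query is tested in its reading orientation; its reverse complement is
#' additionally tested only when the reference set is declared unstranded.
#' Used in two modes: against a pseudogene cDNA set a match *excludes* the
#' candidate; against an EST set a match is retained as transcriptional
#' support (not an exclusion -- EST coverage is biased towards characterised
#' regions and rejects genuine novelty).
#'
#' @param query_dna nucleotide string (reading orientation of the peptide).
#' @param reference_set named character vector, `DNAStringSet`, or FASTA
#'   path of reference sequences.
#' @param stranded is the reference set stranded? (default `TRUE`)
#' @return list with `match` (logical) and `accession` (first matching
#'   reference name or `NA`).
#' @export
exact_dna_filter <- function(query_dna, reference_set, stranded = TRUE) {
  stopifnot(nzchar(query_dna))
  refs <- as_dna_set(reference_set)
  hits <- Biostrings::vcountPattern(query_dna, refs) > 0L
  if (!stranded && !any(hits)) {
    hits <- Biostrings::vcountPattern(revcomp(query_dna), refs) > 0L
  }
  list(match = any(hits),
       accession = if (any(hits)) names(refs)[which(hits)[1L]] else NA_character_)
}

as_dna_set <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(Biostrings::readDNAStringSet(x))
  }
  Biostrings::DNAStringSet(x)
}

#' Repeat-region overlap filter
#'
#' Fails when the peptide locus overlaps any repeat interval by at least one
#' nucleotide (closed-interval overlap, strand-agnostic).
#'
#' @param locus list/row with `chrom`, `start`, `end`.
#' @param repeats `GRanges` of repeat intervals (e.g. from [read_repeats()]).
#' @return `TRUE` when the locus overlaps a repeat (i.e. fails the filter).
#' @export
repeat_overlap <- function(locus, repeats) {
  q <- GenomicRanges::GRanges(locus$chrom,
                              IRanges::IRanges(locus$start, locus$end))
  # chromosomes absent from the repeat set simply cannot overlap
  suppressWarnings(
    GenomicRanges::countOverlaps(q, repeats, ignore.strand = TRUE) > 0L)
}

#' Length-normalised conservation score over a locus
#'
#' The per-base substitution-deficit score R (expected minus observed
#' substitutions) is summed over every position of the interval -- positions
#' absent from the track contribute 0 -- and divided by the interval length.
#' Conserved loci score positive, unconstrained loci near or below zero, and
#' unscored loci exactly zero.
#'
#' @param locus list/row with `chrom`, `start`, `end`.
#' @param track `GRanges` with a numeric `score` column giving the per-base
#'   R over its ranges (e.g. from [read_conservation()]).
#' @return numeric sigma-R value.
#' @export
conservation_sigma <- function(locus, track) {
  q <- GenomicRanges::GRanges(locus$chrom,
                              IRanges::IRanges(locus$start, locus$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, track, ignore.strand = TRUE))
  if (!length(hits)) return(0)
  sub <- track[S4Vectors::subjectHits(hits)]
  ov <- GenomicRanges::pintersect(sub, rep(q, length(sub)))
  sum(S4Vectors::mcols(sub)$score * GenomicRanges::width(ov)) /
    (locus$end - locus$start + 1)
}

#' Choose the conservation cutoff by a rank-sum comparison
#'
#' Compares the sigma-R distribution of known exonic peptides with that of
#' the candidates using a Wilcoxon rank-sum test after removing exact zeros
#' from both lists (zeros mean "no score available", not "not conserved"),
#' and returns the configured cutoff. Survivors of the conservation filter
#' satisfy `sigma >= cutoff`; the zero-stripping applies to cutoff selection
#' only, so an unscored candidate still survives the default cutoff of 0.
#'
#' @param exonic_sigmas sigma-R values of known exonic peptides.
#' @param candidate_sigmas sigma-R values of candidate peptides.
#' @param cutoff the cutoff to report (default 0).
#' @return list with `cutoff`, `statistic` (rank-sum U), `p_value`,
#'   `n_exonic`, `n_candidate` (counts after zero-stripping).
#' @export
choose_sigma_cutoff <- function(exonic_sigmas, candidate_sigmas, cutoff = 0) {
  ex <- exonic_sigmas[exonic_sigmas != 0]
  ca <- candidate_sigmas[candidate_sigmas != 0]
  if (!length(ex)) stop("no exonic sigma-R values left after removing zeros")
  if (!length(ca)) stop("no candidate sigma-R values left after removing zeros")
  wt <- stats::wilcox.test(ex, ca, exact = FALSE)
  list(cutoff = cutoff, statistic = unname(wt$statistic),
       p_value = wt$p.value, n_exonic = length(ex), n_candidate = length(ca))
}

#' Apply all locus filters to a candidate table
#'
#' Filters are independent predicates, so the surviving set does not depend
#' on the order of application. EST evidence is reported as a support
#' column, never as an exclusion.
#'
#' @param candidates data frame with `pep`, `chrom`, `strand`, `start`,
#'   `end` columns.
#' @param genome genome (named character vector or `DNAStringSet`) used to
#'   retrieve each candidate's coding DNA.
#' @param pseudogenes pseudogene cDNA set (FASTA path, character vector or
#'   `DNAStringSet`), or `NULL` to skip.
#' @param repeats repeat `GRanges`, or `NULL` to skip.
#' @param conservation conservation `GRanges` track, or `NULL` to skip.
#' @param ests EST sequence set, or `NULL` to skip the support column.
#' @param sigma_cutoff conservation survival threshold (default 0).
#' @return the input with columns `dna`, `pseudogene_fail`,
#'   `pseudogene_hit`, `repeat_fail`, `sigma`, `conservation_fail`,
#'   `est_support` and `pass` appended.
#' @export
apply_locus_filters <- function(candidates, genome, pseudogenes = NULL,
                                repeats = NULL, conservation = NULL,
                                ests = NULL, sigma_cutoff = 0) {
  n <- nrow(candidates)
  candidates$dna <- vapply(seq_len(n), function(i) {
    extract_genomic(genome, candidates$chrom[i], candidates$start[i],
                    candidates$end[i], candidates$strand[i])
  }, character(1))

  if (!is.null(pseudogenes)) {
    pg <- as_dna_set(pseudogenes)
    res <- lapply(candidates$dna, exact_dna_filter, reference_set = pg)
    candidates$pseudogene_fail <- vapply(res, `[[`, logical(1), "match")
    candidates$pseudogene_hit <- vapply(res, `[[`, character(1), "accession")
  } else {
    candidates$pseudogene_fail <- FALSE
    candidates$pseudogene_hit <- NA_character_
  }

  candidates$repeat_fail <- if (!is.null(repeats)) {
    vapply(seq_len(n), function(i)
      repeat_overlap(candidates[i, ], repeats), logical(1))
  } else rep(FALSE, n)

  if (!is.null(conservation)) {
    candidates$sigma <- vapply(seq_len(n), function(i)
      conservation_sigma(candidates[i, ], conservation), numeric(1))
    candidates$conservation_fail <- candidates$sigma < sigma_cutoff
  } else {
    candidates$sigma <- 0
    candidates$conservation_fail <- FALSE
  }

  candidates$est_support <- if (!is.null(ests)) {
    es <- as_dna_set(ests)
    vapply(candidates$dna, function(d)
      exact_dna_filter(d, es)$match, logical(1))
  } else rep(NA, n)

  candidates$pass <- !candidates$pseudogene_fail & !candidates$repeat_fail &
    !candidates$conservation_fail
  candidates
}

#' Read repeat intervals from BED
#'
#' BED's 0-based half-open convention is converted at this boundary.
#' @param path BED file path.
#' @return `GRanges` (1-based inclusive).
#' @export
read_repeats <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Read a per-base conservation track from bedGraph
#'
#' @param path bedGraph file path (`score` column holds per-base R).
#' @return `GRanges` with a `score` column.
#' @export
read_conservation <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}
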