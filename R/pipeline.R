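# End-to-end discovery pipeline on in-memory objects.

#' Run the full six-frame discovery pipeline
#'
#' Wires all stages together: builds the per-chromosome six-frame target and
#' decoy databases and the exon-junction database, runs the reference search
#' and the two-stage six-frame search, identifies orphan peptides, maps and
#' classifies their loci, applies the pseudogene/repeat/conservation filters
#' and assembles the funnel report.
#'
#' @param fixture a fixture list as returned by [generate_fixture()] (or any
#'   list with `genome`, `gene_models`, `reference`, and optionally
#'   `pseudogenes`, `ests`, `repeats`, `conservation`).
#' @param spectra named list of [spectrum()] objects.
#' @param params search parameters from [search_params()].
#' @param confidence_min identification confidence threshold (default 0.95).
#' @param sigma_cutoff conservation survival threshold (default 0).
#' @param min_len,require_kr passed to [translate_six_frame()].
#' @return list with the per-stage results: `unit_dbs`, `entries`,
#'   `junctions`, `reference_psms`, `prescreen`, `prescreen_fdr`,
#'   `amalgamated`, `second_psms`, `second_fdr`, `orphans`, `candidates`
#'   (classified and filtered), and `funnel`.
#' @export
run_discovery_pipeline <- function(fixture, spectra,
                                   params = search_params(),
                                   confidence_min = 0.95, sigma_cutoff = 0,
                                   min_len = 6L, require_kr = TRUE) {
  genome <- fixture$genome
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)

  # six-frame target + decoy databases, one unit per chromosome
  unit_dbs <- lapply(names(genome), function(ch) {
    tgt <- translate_six_frame(genome[[ch]], chrom = ch, min_len = min_len,
                               require_kr = require_kr)
    rbind(tgt, make_decoy(tgt))
  })
  names(unit_dbs) <- names(genome)
  entries <- do.call(rbind, lapply(unit_dbs, function(db)
    db[!db$is_decoy, , drop = FALSE]))
  rownames(entries) <- NULL

  junctions <- build_junction_db(fixture$gene_models, genome)
  annotation <- build_annotation(fixture$gene_models)

  # reference search (targets + their decoys, searched together)
  ref_db <- rbind(
    data.frame(accession = fixture$reference$accession,
               aa = fixture$reference$aa, is_decoy = FALSE,
               stringsAsFactors = FALSE),
    data.frame(accession = paste0("DECOY_", fixture$reference$accession),
               aa = vapply(fixture$reference$aa, function(s)
                 paste(rev(chars(s)), collapse = ""), character(1),
                 USE.NAMES = FALSE),
               is_decoy = TRUE, stringsAsFactors = FALSE))
  reference_psms <- search_spectra(spectra, ref_db, params)

  # stage 1: per-chromosome pre-screen
  pre <- prescreen(spectra, unit_dbs, confidence_min, params)
  sixframe_all <- do.call(rbind,
    pre$units[vapply(pre$units, nrow, integer(1)) > 0L])
  pre_fdr <- compute_fdr(
    length(unique(pre$target_hits$pep)),
    length(unique(pre$decoy_hits$pep[pre$decoy_hits$confidence >= confidence_min])))

  # stage 2: amalgamated competitive re-search
  amal <- build_amalgamated_db(fixture$reference, pre, unit_dbs)
  second_psms <- search_spectra(spectra, amal, params)
  sec_pep <- peptide_level(second_psms)
  sec_hi <- sec_pep[sec_pep$confidence >= confidence_min, , drop = FALSE]
  second_fdr <- compute_fdr(sum(!sec_hi$is_decoy), sum(sec_hi$is_decoy))

  # orphan identification on the pre-screen comparison
  orphans <- identify_orphans(
    sixframe_all, reference_psms, confidence_min, junctions,
    locus_count = function(pep) count_genomic_loci(pep, entries))

  # survivors of the second search: orphan peptides still assigned to a
  # six-frame target entry at high confidence
  surv <- sec_hi[!sec_hi$is_decoy &
                   sec_hi$pep %in% orphans$orphans$pep &
                   grepl("^SF\\.", sec_hi$accession), , drop = FALSE]

  candidates <- NULL
  if (nrow(surv)) {
    loci <- lapply(seq_len(nrow(surv)), function(i) {
      parent <- entries[entries$accession == surv$accession[i], , drop = FALSE]
      map_peptide_locus(parent[1L, ], surv$offset[i], nchar(surv$pep[i]))
    })
    candidates <- data.frame(
      pep = surv$pep, accession = surv$accession,
      confidence = surv$confidence,
      chrom = vapply(loci, `[[`, character(1), "chrom"),
      strand = vapply(loci, function(l) as.integer(l$strand), integer(1)),
      start = vapply(loci, function(l) as.integer(l$start), integer(1)),
      end = vapply(loci, function(l) as.integer(l$end), integer(1)),
      stringsAsFactors = FALSE)
    candidates$n_genomic_matches <- vapply(candidates$pep, function(p)
      count_genomic_loci(p, entries), integer(1))
    candidates <- classify_loci(candidates, annotation)
    candidates <- apply_locus_filters(
      candidates, genome,
      pseudogenes = fixture$pseudogenes, repeats = fixture$repeats,
      conservation = fixture$conservation, ests = fixture$ests,
      sigma_cutoff = sigma_cutoff)
  }

  # funnel assembly
  class_levels <- c("intergenic", "intronic", "exonic_not_in_frame",
                    "exonic_extending_5p", "exonic_extending_3p")
  if (!is.null(candidates) && nrow(candidates)) {
    cc <- table(factor(candidates$label, levels = class_levels))
    filt <- t(vapply(class_levels, function(cl) {
      sub <- candidates[candidates$label == cl, , drop = FALSE]
      c(identified = nrow(sub),
        pseudogene = sum(!sub$pseudogene_fail),
        repeats = sum(!sub$pseudogene_fail & !sub$repeat_fail),
        conservation = sum(sub$pass))
    }, numeric(4)))
    funnel <- do.call(funnel_report,
                      c(orphans$counts,
                        list(class_counts = as.integer(cc),
                             filter_counts = as.data.frame(filt))))
    names(funnel$class_counts) <- class_levels
  } else {
    funnel <- do.call(funnel_report, orphans$counts)
  }

  list(unit_dbs = unit_dbs, entries = entries, junctions = junctions,
       annotation = annotation, reference_psms = reference_psms,
       prescreen = pre, prescreen_fdr = pre_fdr, amalgamated = amal,
       second_psms = second_psms, second_fdr = second_fdr,
       orphans = orphans, candidates = candidates, funnel = funnel)
}
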