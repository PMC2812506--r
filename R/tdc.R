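# Two-stage target/decoy search orchestration, decoy-based FDR, orphan
# identification and the funnel report.
#
# Stage 1 ("pre-screen") searches the spectra against each per-chromosome
# target+decoy database separately, keeping high-confidence target hits and
# *all* decoy hits regardless of confidence. Stage 2 re-searches every
# spectrum against a single amalgamated database (reference proteome +
# stage-1 target parents + stage-1 decoy parents) so that all candidates
# compete directly, which is what brings the FDR down.

#' Per-unit pre-screening search
#'
#' @param spectra named list of [spectrum()] objects.
#' @param unit_dbs named list of entry data frames, one per search unit
#'   (typically one per chromosome), each containing both target and decoy
#'   entries.
#' @param confidence_min confidence threshold for retaining target hits
#'   (default 0.95); decoy hits are retained at any confidence.
#' @param params list from [search_params()].
#' @return list of class `prescreen_result` with `units` (per-unit PSM data
#'   frames), `target_hits` and `decoy_hits` (row-bound PSMs with a `unit`
#'   column).
#' @export
prescreen <- function(spectra, unit_dbs, confidence_min = 0.95,
                      params = search_params()) {
  if (is.null(names(unit_dbs)) || any(!nzchar(names(unit_dbs)))) {
    stop("unit_dbs must be a named list")
  }
  units <- lapply(names(unit_dbs), function(u) {
    db <- unit_dbs[[u]]
    if (is.null(db) || !nrow(db)) stop("missing or empty database for unit '", u, "'")
    psms <- search_spectra(spectra, db, params)
    if (nrow(psms)) psms$unit <- u
    psms
  })
  names(units) <- names(unit_dbs)
  all_psms <- do.call(rbind, units[vapply(units, nrow, integer(1)) > 0L])
  if (is.null(all_psms)) {
    all_psms <- data.frame(spectrum_id = character(), pep = character(),
                           accession = character(), offset = integer(),
                           shared_peaks = integer(), n_ions = integer(),
                           confidence = numeric(), is_decoy = logical(),
                           unit = character(), stringsAsFactors = FALSE)
  }
  structure(list(
    units = units,
    target_hits = all_psms[!all_psms$is_decoy &
                             all_psms$confidence >= confidence_min, , drop = FALSE],
    decoy_hits = all_psms[all_psms$is_decoy, , drop = FALSE],
    confidence_min = confidence_min
  ), class = "prescreen_result")
}

#' Amalgamated database for the second-stage search
#'
#' Reference entries plus the parent entries of all unique stage-1 target
#' hits and of all stage-1 decoy hits, de-duplicated by accession.
#'
#' @param reference_entries data frame with `accession`, `aa` (and optional
#'   `is_decoy`) for the reference proteome.
#' @param prescreen_result result of [prescreen()].
#' @param unit_dbs the same named list of databases given to [prescreen()]
#'   (used to look up parent entries by accession).
#' @return entry data frame (`accession`, `aa`, `is_decoy`).
#' @export
build_amalgamated_db <- function(reference_entries, prescreen_result, unit_dbs) {
  ref <- data.frame(accession = reference_entries$accession,
                    aa = reference_entries$aa,
                    is_decoy = isTRUE_vec(reference_entries$is_decoy,
                                          nrow(reference_entries)),
                    stringsAsFactors = FALSE)
  hit_acc <- unique(c(prescreen_result$target_hits$accession,
                      prescreen_result$decoy_hits$accession))
  pool <- do.call(rbind, lapply(unit_dbs, function(db) {
    data.frame(accession = db$accession, aa = db$aa,
               is_decoy = isTRUE_vec(db$is_decoy, nrow(db)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(pool)) pool <- ref[0L, , drop = FALSE]
  hits <- pool[pool$accession %in% hit_acc, , drop = FALSE]
  hits <- hits[!duplicated(hits$accession), , drop = FALSE]
  clash <- intersect(ref$accession, hits$accession)
  if (length(clash)) {
    stop("accession collision between reference and six-frame namespaces: ",
         paste(utils::head(clash, 5L), collapse = ", "))
  }
  out <- rbind(ref, hits)
  rownames(out) <- NULL
  out
}

#' Decoy-based false discovery rate
#'
#' `FDR% = 100 * FP / (FP + TP)` with the false positives estimated by the
#' decoy count and `FP + TP` by the accepted target count
#' (`method = "decoy_ratio"`). The concatenated-set variant
#' `100 * 2D / (T + D)` is available as `method = "concatenated"`. The
#' result is capped at 100; it is 0 when there are no hits at all.
#'
#' @param n_target accepted target identifications (count).
#' @param n_decoy accepted decoy identifications (count).
#' @param method estimator variant.
#' @return FDR in percent.
#' @export
compute_fdr <- function(n_target, n_decoy,
                        method = c("decoy_ratio", "concatenated")) {
  method <- match.arg(method)
  if (n_target < 0 || n_decoy < 0) stop("counts must be non-negative")
  if (n_target == 0 && n_decoy == 0) return(0)
  fdr <- switch(method,
    decoy_ratio = if (n_target == 0) Inf else 100 * n_decoy / n_target,
    concatenated = 100 * 2 * n_decoy / (n_target + n_decoy)
  )
  min(fdr, 100)
}

#' FDR as a function of the confidence threshold
#'
#' @param psms PSM data frame with `confidence` and `is_decoy` columns.
#' @param thresholds confidence thresholds to evaluate.
#' @param method passed to [compute_fdr()].
#' @return data frame with `threshold`, `n_target`, `n_decoy`, `fdr`.
#' @export
fdr_curve <- function(psms, thresholds, method = "decoy_ratio") {
  do.call(rbind, lapply(thresholds, function(t) {
    nt <- sum(!psms$is_decoy & psms$confidence >= t)
    nd <- sum(psms$is_decoy & psms$confidence >= t)
    data.frame(threshold = t, n_target = nt, n_decoy = nd,
               fdr = compute_fdr(nt, nd, method))
  }))
}

# Best-confidence collapse of PSMs to the peptide level.
peptide_level <- function(psms) {
  if (!nrow(psms)) {
    return(data.frame(pep = character(), confidence = numeric(),
                      accession = character(), offset = integer(),
                      is_decoy = logical(), stringsAsFactors = FALSE))
  }
  o <- order(psms$pep, -psms$confidence)
  p <- psms[o, , drop = FALSE]
  p <- p[!duplicated(p$pep), , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Identify orphan peptides
#'
#' Orphans are peptide sequences identified at or above the confidence
#' threshold in the six-frame search only: high-confidence six-frame target
#' peptides with no exact sequence match among high-confidence reference
#' peptides, after excluding (with a logged reason) peptides that match the
#' putative translated genome at more than one locus (`multi_target`) and
#' peptides that do occur in the reference search below the threshold
#' (`low_confidence_reference`). Reference-unique peptides are annotated as
#' junction-explained when their sequence occurs in the exon-junction
#' translations, and as low-confidence-explained when the six-frame search
#' found them below the threshold.
#'
#' @param sixframe_psms PSM data frame from the six-frame search (any
#'   confidence; decoys are ignored).
#' @param reference_psms PSM data frame from the reference-database search
#'   (any confidence; decoys are ignored).
#' @param confidence_min confidence threshold (default 0.95).
#' @param junctions optional junction database from [build_junction_db()].
#' @param locus_count optional function `pep -> count` giving the number of
#'   distinct genomic loci matching the peptide (defaults to 1 for all).
#' @return list of class `orphan_set`: `orphans` (peptide-level data frame),
#'   `excluded` (data frame `pep`, `reason`), `reference_unique` (data frame
#'   `pep`, `junction_explained`, `lowconf_sixframe`), plus the input counts
#'   used by [funnel_report()].
#' @export
identify_orphans <- function(sixframe_psms, reference_psms,
                             confidence_min = 0.95, junctions = NULL,
                             locus_count = NULL) {
  six <- peptide_level(sixframe_psms[!sixframe_psms$is_decoy, , drop = FALSE])
  ref <- peptide_level(reference_psms[!reference_psms$is_decoy, , drop = FALSE])
  six_hi <- six[six$confidence >= confidence_min, , drop = FALSE]
  ref_hi <- ref[ref$confidence >= confidence_min, , drop = FALSE]

  overlap <- intersect(six_hi$pep, ref_hi$pep)
  cand <- six_hi[!six_hi$pep %in% ref_hi$pep, , drop = FALSE]

  if (is.null(locus_count)) locus_count <- function(pep) 1L
  n_loci <- vapply(cand$pep, locus_count, numeric(1))
  multi <- cand$pep[n_loci > 1]
  cand <- cand[!cand$pep %in% multi, , drop = FALSE]

  ref_lo_peps <- setdiff(ref$pep, ref_hi$pep)
  lowconf <- cand$pep[cand$pep %in% ref_lo_peps]
  orphans <- cand[!cand$pep %in% lowconf, , drop = FALSE]

  excluded <- rbind(
    data.frame(pep = multi, reason = rep("multi_target", length(multi)),
               stringsAsFactors = FALSE),
    data.frame(pep = lowconf,
               reason = rep("low_confidence_reference", length(lowconf)),
               stringsAsFactors = FALSE)
  )

  ref_unique <- ref_hi[!ref_hi$pep %in% six_hi$pep, , drop = FALSE]
  six_lo_peps <- setdiff(six$pep, six_hi$pep)
  ref_unique_df <- data.frame(
    pep = ref_unique$pep,
    junction_explained = if (is.null(junctions)) rep(FALSE, nrow(ref_unique))
      else vapply(ref_unique$pep, junction_contains, logical(1),
                  junctions = junctions),
    lowconf_sixframe = ref_unique$pep %in% six_lo_peps,
    stringsAsFactors = FALSE
  )

  structure(list(
    orphans = orphans, excluded = excluded, reference_unique = ref_unique_df,
    counts = list(
      sixframe_total = nrow(six_hi), reference_total = nrow(ref_hi),
      overlap = length(overlap),
      junction_explained = sum(ref_unique_df$junction_explained),
      sixframe_lowconf_explained = sum(ref_unique_df$lowconf_sixframe),
      multi_target = length(multi), reference_lowconf = length(lowconf)
    )
  ), class = "orphan_set")
}

#' Stage-by-stage funnel report
#'
#' Computes the derived quantities of the discovery funnel from its stage
#' counts: `overlap_pct` (peptide-level correspondence between the two
#' searches, rounded to an integer), `adjusted_pct` (correspondence after
#' crediting junction-explained and low-confidence-explained
#' reference-unique peptides, truncated to two decimals),
#' `sixframe_unique`, `reference_unique` and `post_exclusion` (six-frame
#' unique peptides after removing multi-target and low-confidence-reference
#' matches). Optional per-class counts and per-filter survivor counts are
#' totalled.
#'
#' @param sixframe_total high-confidence six-frame peptide count.
#' @param reference_total high-confidence reference peptide count.
#' @param overlap peptides found by both searches.
#' @param junction_explained reference-unique peptides explained by exon
#'   junctions.
#' @param sixframe_lowconf_explained reference-unique peptides found by the
#'   six-frame search below the confidence threshold.
#' @param multi_target six-frame-unique peptides matching multiple loci.
#' @param reference_lowconf six-frame-unique peptides with low-confidence
#'   reference matches.
#' @param class_counts optional named integer vector of per-class peptide
#'   counts (e.g. intergenic/intronic/exonic).
#' @param filter_counts optional named list/data frame of per-class survivor
#'   counts per filter; each column is totalled.
#' @return list of class `funnel_report`.
#' @export
funnel_report <- function(sixframe_total, reference_total, overlap,
                          junction_explained = 0L,
                          sixframe_lowconf_explained = 0L,
                          multi_target = 0L, reference_lowconf = 0L,
                          class_counts = NULL, filter_counts = NULL) {
  counts <- c(sixframe_total, reference_total, overlap, junction_explained,
              sixframe_lowconf_explained, multi_target, reference_lowconf)
  if (any(counts < 0)) stop("stage counts must be non-negative")
  sixframe_unique <- sixframe_total - overlap
  reference_unique <- reference_total - overlap
  post_exclusion <- sixframe_unique - multi_target - reference_lowconf
  if (sixframe_unique < 0 || reference_unique < 0 || post_exclusion < 0) {
    stop("inconsistent funnel: a derived count is negative")
  }
  overlap_pct <- if (reference_total == 0) 0 else
    round(100 * overlap / reference_total)
  adjusted_pct <- if (reference_total == 0) 0 else
    trunc2(100 * (overlap + junction_explained + sixframe_lowconf_explained) /
             reference_total)
  rep <- list(
    sixframe_total = sixframe_total, reference_total = reference_total,
    overlap = overlap, junction_explained = junction_explained,
    sixframe_lowconf_explained = sixframe_lowconf_explained,
    multi_target = multi_target, reference_lowconf = reference_lowconf,
    sixframe_unique = sixframe_unique, reference_unique = reference_unique,
    post_exclusion = post_exclusion,
    overlap_pct = overlap_pct, adjusted_pct = adjusted_pct
  )
  if (!is.null(class_counts)) {
    rep$class_counts <- class_counts
    rep$class_total <- sum(class_counts)
  }
  if (!is.null(filter_counts)) {
    filter_counts <- as.data.frame(filter_counts)
    rep$filter_counts <- filter_counts
    rep$filter_totals <- colSums(filter_counts)
  }
  structure(rep, class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Discovery funnel\n")
  cat(sprintf("  six-frame >= threshold : %d\n", x$sixframe_total))
  cat(sprintf("  reference >= threshold : %d\n", x$reference_total))
  cat(sprintf("  overlap                : %d (%d%% of reference)\n",
              x$overlap, x$overlap_pct))
  cat(sprintf("  adjusted correspondence: %.2f%%\n", x$adjusted_pct))
  cat(sprintf("  six-frame unique       : %d\n", x$sixframe_unique))
  cat(sprintf("  reference unique       : %d\n", x$reference_unique))
  cat(sprintf("  excluded (multi-target): %d\n", x$multi_target))
  cat(sprintf("  excluded (low-conf ref): %d\n", x$reference_lowconf))
  cat(sprintf("  post-exclusion         : %d\n", x$post_exclusion))
  if (!is.null(x$class_counts)) {
    cat("  classes:",
        paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
              collapse = " "),
        sprintf(" total=%d\n", x$class_total))
  }
  if (!is.null(x$filter_totals)) {
    cat("  filter survivors:",
        paste(sprintf("%s=%d", names(x$filter_totals),
                      as.integer(x$filter_totals)), collapse = " "), "\n")
  }
  invisible(x)
}
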