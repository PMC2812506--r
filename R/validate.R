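# Spectral validation of candidate identifications.
#
# The fragmentation pattern of a synthetic peptide should closely resemble
# that of the real peptide with the same sequence. Candidates are therefore
# scored against synthetic-peptide spectra by counting common ions
# (common_ion_score), and the score's chance behaviour is characterised by
# an empirical null built from randomly drawn unrelated spectra; the FDR at
# a score threshold is the two-sample tail ratio of null to real scores
# (an Efron-style empirical null; a pure null-tail percentile mode is also
# available).

#' Build an empirical null distribution of similarity scores
#'
#' Repeatedly draws `set_size` spectra from the pool -- without replacement
#' across repetitions, so every drawn spectrum is used once -- and scores
#' each against every reference spectrum.
#'
#' @param pool named list of [spectrum()] objects to draw from (must be
#'   disjoint from the real candidate spectra).
#' @param references named list of reference (synthetic-peptide) spectra.
#' @param n_reps number of repetitions (default 7000).
#' @param set_size spectra drawn per repetition (default 10).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param min_mz,tol passed to [common_ion_score()].
#' @return list of class `null_distribution` with `scores` (length
#'   `n_reps * set_size * length(references)`), `n_reps`, `set_size`,
#'   `seed` and `query_ids`.
#' @export
build_null <- function(pool, references, n_reps = 7000L, set_size = 10L,
                       seed = 1L, min_mz = 160, tol = 0.2) {
  need <- n_reps * set_size
  if (length(pool) < need) {
    stop(sprintf(
      "pool exhausted: %d spectra needed for %d x %d without-replacement draws, %d available",
      need, n_reps, set_size, length(pool)))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  drawn <- sample.int(length(pool), need)
  scores <- numeric(need * length(references))
  k <- 0L
  for (qi in drawn) {
    for (ref in references) {
      k <- k + 1L
      scores[k] <- common_ion_score(pool[[qi]], ref, min_mz = min_mz, tol = tol)
    }
  }
  structure(list(scores = scores, n_reps = n_reps, set_size = set_size,
                 seed = seed,
                 query_ids = vapply(pool[drawn], `[[`, character(1), "id")),
            class = "null_distribution")
}

#' Empirical FDR curve from real and null score distributions
#'
#' For each candidate threshold `s`,
#' `FDR%(s) = 100 * Pr(null >= s) / Pr(real >= s)` (capped at 100), after
#' which the curve is made monotone non-increasing in `s` by a running
#' minimum. `mode = "null_tail"` instead reports the null tail percentile
#' alone.
#'
#' @param real_scores similarity scores of the real candidate pairs.
#' @param null a [build_null()] result (or numeric vector of null scores).
#' @param mode `"tail_ratio"` (default) or `"null_tail"`.
#' @return list of class `empirical_fdr` with a data frame `curve`
#'   (`score`, `fdr_raw`, `fdr`) over the pooled score grid.
#' @export
empirical_fdr <- function(real_scores, null, mode = c("tail_ratio", "null_tail")) {
  mode <- match.arg(mode)
  null_scores <- if (is.list(null)) null$scores else null
  if (!length(real_scores) || !length(null_scores)) {
    stop("both score sets must be non-empty")
  }
  grid <- sort(unique(c(real_scores, null_scores)))
  null_tail <- vapply(grid, function(s) mean(null_scores >= s), numeric(1))
  real_tail <- vapply(grid, function(s) mean(real_scores >= s), numeric(1))
  fdr_raw <- switch(mode,
    tail_ratio = ifelse(real_tail > 0, 100 * null_tail / real_tail, 0),
    null_tail = 100 * null_tail
  )
  fdr_raw <- pmin(fdr_raw, 100)
  # monotone non-increasing in score: the FDR credited to a threshold is the
  # best raw FDR among all thresholds at or below it (running minimum)
  fdr <- cummin(fdr_raw)
  structure(list(curve = data.frame(score = grid, fdr_raw = fdr_raw,
                                    fdr = fdr),
                 mode = mode),
            class = "empirical_fdr")
}

#' Score threshold attaining a target FDR
#'
#' @param fdr an [empirical_fdr()] result.
#' @param target_fdr target FDR in percent.
#' @return list with `threshold` (smallest score whose smoothed FDR is at or
#'   below the target, `NA` when unattainable), `attained` (the FDR at the
#'   threshold) and `min_fdr` (best achievable).
#' @export
threshold_at <- function(fdr, target_fdr) {
  curve <- fdr$curve
  ok <- curve$fdr <= target_fdr
  if (!any(ok)) {
    return(list(threshold = NA_real_, attained = NA_real_,
                min_fdr = min(curve$fdr)))
  }
  i <- which(ok)[1L]
  list(threshold = curve$score[i], attained = curve$fdr[i],
       min_fdr = min(curve$fdr))
}
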