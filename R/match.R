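# Peak matching and spectrum scoring.
#
# Matching two sorted m/z lists under a symmetric tolerance is a
# maximum-cardinality matching problem on an interval bigraph. Because all
# tolerance windows have equal width, the ascending two-pointer greedy --
# walk the query values in increasing order, pairing each with the smallest
# not-yet-used partner within +/- tol -- attains the maximum (exchange
# argument; the unit tests verify equality with an independent
# maximum-matching oracle on random instances).

# Count a maximum one-to-one matching between two ascending numeric vectors
# with |a_i - b_j| <= tol. O(n + m).
match_count <- function(a, b, tol) {
  i <- 1L; j <- 1L; count <- 0L
  na <- length(a); nb <- length(b)
  while (i <= na && j <= nb) {
    if (b[j] < a[i] - tol) {
      j <- j + 1L          # peak too low for this and all later ions
    } else if (b[j] > a[i] + tol) {
      i <- i + 1L          # no peak available for this ion
    } else {
      count <- count + 1L  # pair ion i with the smallest usable peak
      i <- i + 1L; j <- j + 1L
    }
  }
  count
}

#' Score a spectrum against a theoretical ion list
#'
#' Counts theoretical ions explainable by spectrum peaks within `+/- tol`
#' (each peak usable once; maximum one-to-one matching) and maps the matched
#' fraction through a declared logistic calibration to a confidence in
#' `[0, 1]`. The calibration stands in for a commercial engine's opaque
#' confidence scale: it is monotone in the shared-ion fraction, which is all
#' the downstream thresholding semantics require.
#'
#' @param spec a [spectrum()] object.
#' @param ions numeric vector of theoretical fragment m/z values.
#' @param tol fragment tolerance in Th (default 0.2).
#' @param calib logistic calibration `c(k, mid)`: confidence =
#'   `plogis(k * (fraction - mid))`.
#' @return list with `shared_peaks` (count) and `confidence`.
#' @export
match_score <- function(spec, ions, tol = 0.2,
                        calib = c(k = 12, mid = 0.5)) {
  if (!length(ions)) stop("ion list must be non-empty")
  shared <- match_count(sort(ions), spec$peaks[, 1L], tol)
  frac <- shared / length(ions)
  list(shared_peaks = shared,
       confidence = stats::plogis(calib[["k"]] * (frac - calib[["mid"]])))
}

#' Common-ion similarity between two spectra
#'
#' Both peak lists are first restricted to m/z strictly above `min_mz`
#' (dropping isobaric-label reporter and potential ammonium ions), then the
#' size of a maximum one-to-one matching within `+/- tol` is returned. The
#' score is symmetric and invariant to intensities.
#'
#' @param query,reference [spectrum()] objects.
#' @param min_mz low-mass cutoff in Th (default 160; peaks at or below are
#'   discarded from both spectra).
#' @param tol matching tolerance in Th (default 0.2).
#' @return integer count of common ions.
#' @export
common_ion_score <- function(query, reference, min_mz = 160, tol = 0.2) {
  a <- query$peaks[, 1L]
  b <- reference$peaks[, 1L]
  match_count(a[a > min_mz], b[b > min_mz], tol)
}
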