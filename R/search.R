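# Stand-in peptide-spectrum matcher.
#
# The commercial engine used to produce the original identifications is not
# reproducible; this module implements the same *contract* -- per spectrum,
# all database peptides within a precursor-mass window compete (targets and
# decoys in one pool) and the single best match is reported with a
# confidence in [0, 1] -- with an openly declared scorer (shared b/y ions
# through a logistic calibration). Externally produced PSM tables can be
# imported instead via read_psms().

#' Default search parameters
#'
#' @param tol_prec precursor mass window, Da (default 0.5).
#' @param tol_frag fragment tolerance, Th (default 0.2).
#' @param missed maximum missed cleavages (default 1).
#' @param mode tryptic digestion mode, `"full"` or `"semi"`.
#' @param min_pep_len shortest peptide considered (default 6).
#' @param max_pep_len longest peptide considered (default 30).
#' @param mods fixed-modification configuration (default [itraq_mmts()]).
#' @param calib logistic confidence calibration, see [match_score()].
#' @return a named list of parameters.
#' @export
search_params <- function(tol_prec = 0.5, tol_frag = 0.2, missed = 1L,
                          mode = "full", min_pep_len = 6L, max_pep_len = 30L,
                          mods = itraq_mmts(), calib = c(k = 12, mid = 0.5)) {
  list(tol_prec = tol_prec, tol_frag = tol_frag, missed = missed,
       mode = mode, min_pep_len = min_pep_len, max_pep_len = max_pep_len,
       mods = mods, calib = calib)
}

#' Digest a database into an indexed peptide table
#'
#' @param db entry data frame (`accession`, `aa`, optional `is_decoy`).
#' @param params list from [search_params()].
#' @return list with `peptides` (data frame: `pep`, `accession`, `offset`,
#'   `is_decoy`), `unique_peps` and `mass` (aligned with `unique_peps`,
#'   ascending).
#' @export
digest_database <- function(db, params = search_params()) {
  stopifnot(nrow(db) > 0L)
  is_decoy <- isTRUE_vec(db$is_decoy, nrow(db))
  pieces <- vector("list", nrow(db))
  for (i in seq_len(nrow(db))) {
    d <- digest(db$aa[i], missed = params$missed, mode = params$mode,
                min_len = params$min_pep_len)
    d <- d[nchar(d$pep) <= params$max_pep_len, , drop = FALSE]
    if (!nrow(d)) next
    d$accession <- db$accession[i]
    d$is_decoy <- is_decoy[i]
    pieces[[i]] <- d
  }
  peptides <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(peptides)) stop("database produced no peptides")
  # drop peptides with residues outside the standard alphabet (none should
  # arise from six-frame entries, but reference imports may carry X/U)
  ok <- grepl(sprintf("^[%s]+$", paste(AA_LETTERS, collapse = "")), peptides$pep)
  peptides <- peptides[ok, , drop = FALSE]
  uniq <- sort(unique(peptides$pep))
  mass <- vapply(uniq, peptide_mass, numeric(1), mods = params$mods,
                 USE.NAMES = FALSE)
  o <- order(mass)
  list(peptides = peptides, unique_peps = uniq[o], mass = mass[o])
}

#' Search spectra against a peptide database
#'
#' For each spectrum, candidate peptides are those whose neutral mass lies
#' within `tol_prec` of the precursor neutral mass (from `precursor_mz` and
#' `charge`); each candidate is scored with [match_score()] and the single
#' best peptide-spectrum match is kept. Ties are broken by the
#' lexicographically smallest peptide; among parents of the winning peptide,
#' targets beat decoys and then the smallest accession wins.
#'
#' @param spectra named list of [spectrum()] objects (charge required).
#' @param db entry data frame, or a prebuilt index from [digest_database()].
#' @param params list from [search_params()].
#' @return `data.frame` of PSMs: `spectrum_id`, `pep`, `accession`,
#'   `offset`, `shared_peaks`, `n_ions`, `confidence`, `is_decoy`. Spectra
#'   with no candidate in the mass window are reported in the
#'   `"unassigned"` attribute.
#' @export
search_spectra <- function(spectra, db, params = search_params()) {
  index <- if (is.data.frame(db)) digest_database(db, params) else db
  mass <- index$mass
  uniq <- index$unique_peps
  ion_cache <- new.env(parent = emptyenv())

  rows <- vector("list", length(spectra))
  unassigned <- character(0)
  for (si in seq_along(spectra)) {
    sp <- spectra[[si]]
    if (is.na(sp$charge)) stop("spectrum '", sp$id, "' has no charge")
    m0 <- sp$precursor_mz * sp$charge - sp$charge * PROTON_MASS
    lo <- findInterval(m0 - params$tol_prec, mass) + 1L
    hi <- findInterval(m0 + params$tol_prec, mass)
    if (hi < lo) {
      unassigned <- c(unassigned, sp$id)
      next
    }
    cand <- uniq[lo:hi]
    best_pep <- NA_character_; best_conf <- -1; best_shared <- 0L; best_n <- 0L
    for (pep in cand) {
      ions <- ion_cache[[pep]]
      if (is.null(ions)) {
        ions <- theoretical_ions(pep, params$mods)
        ion_cache[[pep]] <- ions
      }
      sc <- match_score(sp, ions, tol = params$tol_frag, calib = params$calib)
      if (sc$confidence > best_conf + 1e-12 ||
          (abs(sc$confidence - best_conf) <= 1e-12 &&
           !is.na(best_pep) && pep < best_pep)) {
        best_pep <- pep; best_conf <- sc$confidence
        best_shared <- sc$shared_peaks; best_n <- length(ions)
      }
    }
    parents <- index$peptides[index$peptides$pep == best_pep, , drop = FALSE]
    parents <- parents[order(parents$is_decoy, parents$accession), , drop = FALSE]
    rows[[si]] <- data.frame(
      spectrum_id = sp$id, pep = best_pep,
      accession = parents$accession[1L], offset = parents$offset[1L],
      shared_peaks = best_shared, n_ions = best_n, confidence = best_conf,
      is_decoy = parents$is_decoy[1L], stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(spectrum_id = character(), pep = character(),
                      accession = character(), offset = integer(),
                      shared_peaks = integer(), n_ions = integer(),
                      confidence = numeric(), is_decoy = logical(),
                      stringsAsFactors = FALSE)
  }
  attr(out, "unassigned") <- unassigned
  out
}

#' Import / export PSM tables
#'
#' Tab-separated with a header line naming the PSM columns, so results from
#' an external engine can replace the built-in matcher.
#'
#' @param psms PSM data frame.
#' @param path file path.
#' @export
write_psms <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psms
#' @return `read_psms()`: the PSM data frame.
#' @export
read_psms <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
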