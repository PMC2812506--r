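# Mascot generic format (MGF) I/O.
#
# A spectrum is a list with elements `id` (TITLE), `precursor_mz` (PEPMASS),
# `charge` (integer or NA) and `peaks` (two-column matrix: mz, intensity;
# rows sorted by ascending mz).

#' Construct a spectrum object
#'
#' @param id spectrum identifier.
#' @param precursor_mz precursor m/z (Th).
#' @param peaks two-column numeric matrix (mz, intensity); re-sorted by mz.
#' @param charge precursor charge (integer or NA).
#' @return a list of class `spectrum`.
#' @export
spectrum <- function(id, precursor_mz, peaks, charge = NA_integer_) {
  peaks <- matrix(as.numeric(peaks), ncol = 2L,
                  dimnames = list(NULL, c("mz", "intensity")))
  if (nrow(peaks) && any(peaks[, 1L] <= 0)) stop("all peak m/z must be > 0")
  peaks <- peaks[order(peaks[, 1L]), , drop = FALSE]
  structure(list(id = id, precursor_mz = precursor_mz,
                 charge = as.integer(charge), peaks = peaks),
            class = "spectrum")
}

#' Read spectra from an MGF file
#'
#' Honours `TITLE` (spectrum id), `PEPMASS` (first number) and `CHARGE`
#' (`2+` style); other headers are ignored.
#'
#' @param path MGF file path.
#' @return named list of [spectrum()] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends)) stop("unbalanced BEGIN/END IONS in ", path)
  out <- vector("list", length(begins))
  for (i in seq_along(begins)) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[hdr], "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[`, character(1), 1L))
    vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1))
    id <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else sprintf("index=%d", i)
    pm <- if ("PEPMASS" %in% keys) {
      as.numeric(strsplit(trimws(vals[match("PEPMASS", keys)]), "\\s+")[[1L]][1L])
    } else NA_real_
    ch <- if ("CHARGE" %in% keys) {
      as.integer(sub("^([0-9]+)\\+?.*$", "\\1", trimws(vals[match("CHARGE", keys)])))
    } else NA_integer_
    pk <- block[!hdr & nzchar(trimws(block))]
    peaks <- if (length(pk)) {
      m <- do.call(rbind, lapply(strsplit(trimws(pk), "\\s+"),
                                 function(x) as.numeric(x[1:2])))
      m
    } else matrix(numeric(0), ncol = 2L)
    out[[i]] <- spectrum(id, pm, peaks, ch)
  }
  stats::setNames(out, vapply(out, `[[`, character(1), "id"))
}

#' Write spectra to an MGF file
#'
#' @param spectra named list of [spectrum()] objects.
#' @param path output file path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$id), con)
    writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    if (!is.na(sp$charge)) writeLines(sprintf("CHARGE=%d+", sp$charge), con)
    if (nrow(sp$peaks)) {
      writeLines(sprintf("%.5f %.2f", sp$peaks[, 1L], sp$peaks[, 2L]), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}
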