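# Independent oracles, deliberately coded with different tools/algorithms
# than the implementation they check.

# Brute-force six-frame enumerator: character-level reverse complement,
# per-codon translation through seqinr, split at stops by hand.
oracle_sixframe <- function(seq, min_len = 6L, require_kr = TRUE) {
  comp <- function(x) chartr("ACGT", "TGCA", x)
  rc <- function(x) paste(rev(strsplit(comp(x), "")[[1]]), collapse = "")
  n <- nchar(seq)
  rows <- list()
  for (strand in c(1L, -1L)) {
    r <- if (strand == 1L) seq else rc(seq)
    for (frame in 1:3) {
      ncod <- (n - frame + 1L) %/% 3L
      if (ncod < 1L) next
      aa <- character(ncod)
      for (ci in seq_len(ncod)) {
        cod <- substr(r, frame + 3L * (ci - 1L), frame + 3L * ci - 1L)
        aa[ci] <- seqinr::translate(strsplit(cod, "")[[1]])
      }
      # walk codons, accumulating stop-to-stop runs
      run_start <- NA_integer_
      for (ci in seq_len(ncod + 1L)) {
        stop_here <- ci > ncod || aa[ci] == "*"
        if (!stop_here && is.na(run_start)) run_start <- ci
        if (stop_here && !is.na(run_start)) {
          pep <- paste(aa[run_start:(ci - 1L)], collapse = "")
          ok <- nchar(pep) >= min_len &&
            (!require_kr || grepl("K", pep) || grepl("R", pep))
          if (ok) {
            p1 <- frame + 3L * (run_start - 1L)
            p2 <- frame + 3L * (ci - 1L) - 1L
            if (strand == 1L) {
              st <- p1; en <- p2
            } else {
              st <- n - p2 + 1L; en <- n - p1 + 1L
            }
            rows[[length(rows) + 1L]] <-
              sprintf("%d|%d|%d|%d|%s", strand, frame, st, en, pep)
          }
          run_start <- NA_integer_
        }
      }
    }
  }
  sort(unlist(rows))
}

# Maximum-cardinality bipartite matching between two m/z lists within a
# tolerance, via igraph.
oracle_match <- function(a, b, tol) {
  if (!length(a) || !length(b)) return(0L)
  edges <- integer(0)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      if (abs(a[i] - b[j]) <= tol) edges <- c(edges, i, length(a) + j)
    }
  }
  if (!length(edges)) return(0L)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, length(a)), rep(TRUE, length(b))),
    edges = edges, directed = FALSE)
  igraph::max_bipartite_match(g)$matching_size
}

# Tryptic digestion by explicit enumeration over all boundary pairs.
oracle_digest_full <- function(aa_seq, missed) {
  n <- nchar(aa_seq)
  aa <- strsplit(aa_seq, "")[[1]]
  sites <- integer(0)
  for (i in seq_len(n - 1L)) {
    if (aa[i] %in% c("K", "R") && aa[i + 1L] != "P") sites <- c(sites, i)
  }
  bounds <- c(0L, sites, n)
  out <- character(0)
  for (ji in seq_along(bounds)) {
    for (ki in seq_along(bounds)) {
      if (ki > ji && (ki - ji - 1L) <= missed) {
        out <- c(out, sprintf("%d|%s", bounds[ji],
                              substr(aa_seq, bounds[ji] + 1L, bounds[ki])))
      }
    }
  }
  sort(out)
}

# Monoisotopic residue mass from elemental composition (independent of the
# package's residue-mass table).
oracle_residue_mass <- local({
  elements <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                O = 15.9949146221, S = 31.97207069)
  # residue (i.e. minus water) formulas of the 20 standard amino acids
  formulas <- list(
    G = c(C = 2, H = 3, N = 1, O = 1), A = c(C = 3, H = 5, N = 1, O = 1),
    S = c(C = 3, H = 5, N = 1, O = 2), P = c(C = 5, H = 7, N = 1, O = 1),
    V = c(C = 5, H = 9, N = 1, O = 1), T = c(C = 4, H = 7, N = 1, O = 2),
    C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
    L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
    N = c(C = 4, H = 6, N = 2, O = 2), D = c(C = 4, H = 5, N = 1, O = 3),
    Q = c(C = 5, H = 8, N = 2, O = 2), K = c(C = 6, H = 12, N = 2, O = 1),
    E = c(C = 5, H = 7, N = 1, O = 3), M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
    H = c(C = 6, H = 7, N = 3, O = 1), F = c(C = 9, H = 9, N = 1, O = 1),
    R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
    W = c(C = 11, H = 10, N = 2, O = 1)
  )
  vapply(formulas, function(f) sum(elements[names(f)] * f), numeric(1))
})

# Rank-sum U statistic by explicit pairwise comparison.
oracle_u_stat <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
  u
}

random_spectrum <- function(id, n_peaks, mz_range = c(100, 1500)) {
  spectrum(id, 500,
           cbind(runif(n_peaks, mz_range[1], mz_range[2]),
                 runif(n_peaks, 1, 100)),
           2L)
}
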