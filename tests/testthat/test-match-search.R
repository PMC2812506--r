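test_that("match_score counts exact peak/ion correspondences and handles empty spectra", {
  ions <- theoretical_ions("PEPTIDEK", no_mods())
  sp <- spectrum("s", 500, cbind(unname(ions), rep(1, length(ions))), 2L)
  sc <- match_score(sp, ions)
  expect_equal(sc$shared_peaks, length(ions))
  expect_gt(sc$confidence, 0.95)
  empty <- spectrum("e", 500, matrix(numeric(0), ncol = 2), 2L)
  sc0 <- match_score(empty, ions)
  expect_equal(sc0$shared_peaks, 0L)
  expect_lt(sc0$confidence, 0.01)
  expect_error(match_score(sp, numeric(0)), "non-empty")
})

test_that("peak matching equals an optimal bipartite matching oracle", {
  skip_if_not_installed("igraph")
  withr::with_seed(41, {
    for (i in 1:60) {
      na <- sample(1:20, 1); nb <- sample(1:20, 1)
      tol <- sample(c(0.2, 0.5, 2), 1)
      a <- sort(runif(na, 0, 50))
      b <- sort(runif(nb, 0, 50))
      expect_equal(sixframer:::match_count(a, b, tol),
                   oracle_match(a, b, tol))
    }
  })
})

test_that("similarity scoring is symmetric, intensity-invariant and floored at min m/z", {
  withr::with_seed(42, {
    for (i in 1:20) {
      x <- random_spectrum("x", sample(5:20, 1))
      y <- random_spectrum("y", sample(5:20, 1))
      expect_identical(common_ion_score(x, y), common_ion_score(y, x))
      y2 <- spectrum("y2", y$precursor_mz,
                     cbind(y$peaks[, 1], y$peaks[, 2] * 1000), y$charge)
      expect_identical(common_ion_score(x, y), common_ion_score(x, y2))
    }
  })
  # low-mass reporter/ammonium region is excluded from both spectra
  mz <- c(114, 115, 150, 300.1, 420.2, 515.3, 731.4, 990.5)
  sp <- spectrum("f", 600, cbind(mz, rep(1, length(mz))), 2L)
  expect_equal(common_ion_score(sp, sp), 5L)
  # identical spectra entirely above the floor self-match completely
  hi <- spectrum("h", 600, cbind(200 + 1:10 * 7, rep(1, 10)), 2L)
  expect_equal(common_ion_score(hi, hi), 10L)
})

test_that("the search returns the planted peptide and breaks ties deterministically", {
  pep <- "LVGDAAETFK"
  sp <- spectra_from_peptides(pep, n_noise_peaks = 0, seed = 1)
  db <- data.frame(
    accession = c("T1", "T2", "B"),
    aa = c(paste0("GGR", pep, "GG"), paste0("AAK", pep, "AA"), "MMMMRLLLLK"),
    is_decoy = FALSE, stringsAsFactors = FALSE)
  psm <- search_spectra(sp, db)
  expect_equal(nrow(psm), 1L)
  expect_equal(psm$pep, pep)
  expect_gt(psm$confidence, 0.95)
  # duplicate parents: smallest accession wins
  expect_equal(psm$accession, "T1")
  # determinism: identical inputs, identical output
  expect_identical(search_spectra(sp, db), psm)
  # no candidate in the precursor window -> reported unassigned
  far <- spectrum("far", 5000, cbind(500, 1), 2L)
  psm2 <- search_spectra(list(far = far), db)
  expect_equal(nrow(psm2), 0L)
  expect_equal(attr(psm2, "unassigned"), "far")
})

test_that("targets outrank decoys for spectra generated from target peptides", {
  db <- SMALL_DB[nchar(SMALL_DB$aa) >= 12, ][1:120, ]
  full <- rbind(db, make_decoy(db))
  prods <- digest(db$aa[7], missed = 0L, min_len = 8L)
  prods <- prods[nchar(prods$pep) <= 25L, ]
  pep <- prods$pep[which.max(nchar(prods$pep))]
  sp <- spectra_from_peptides(pep, n_noise_peaks = 10, seed = 2)
  psm <- search_spectra(sp, full)
  expect_equal(psm$pep, pep)
  expect_false(psm$is_decoy)
})

test_that("planted peptides are recovered at top rank among hundreds of distractors", {
  # 40 planted peptides, distractor database of ~500 ORFs
  db <- SMALL_DB[nchar(SMALL_DB$aa) >= 10, ]
  db <- db[1:min(500L, nrow(db)), ]
  withr::with_seed(44, {
    planted <- unique(unlist(lapply(sample(nrow(db), 60), function(i) {
      prods <- digest(db$aa[i], missed = 0L, min_len = 8L)
      prods <- prods[nchar(prods$pep) <= 20L, ]
      if (nrow(prods)) prods$pep[which.max(nchar(prods$pep))] else NULL
    })))[1:40]
  })
  planted <- planted[!is.na(planted)]
  sp <- spectra_from_peptides(planted, n_noise_peaks = 20, chimera_rate = 0.1,
                              seed = 3)
  psm <- search_spectra(sp, db)
  truth <- sub("^sim_\\d+_", "", psm$spectrum_id)
  recovery <- mean(psm$pep == truth)
  expect_gte(recovery, 0.9)
})

test_that("MGF files round-trip spectra", {
  sp <- spectra_from_peptides(c("ELVISLIVESK", "AAAGGGTTTR"),
                              n_noise_peaks = 5, seed = 9)
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sp, path)
  back <- read_mgf(path)
  expect_identical(names(back), names(sp))
  for (i in seq_along(sp)) {
    expect_equal(back[[i]]$precursor_mz, sp[[i]]$precursor_mz,
                 tolerance = 1e-6)
    expect_identical(back[[i]]$charge, sp[[i]]$charge)
    expect_equal(back[[i]]$peaks[, "mz"], sp[[i]]$peaks[, "mz"],
                 tolerance = 1e-5)
  }
  expect_error(read_mgf(withr::local_tempfile(lines = "BEGIN IONS")),
               "unbalanced")
})
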