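test_that("the decoy FDR formula matches direct arithmetic and is bounded", {
  expect_equal(compute_fdr(100, 0), 0)
  expect_equal(compute_fdr(40, 2), 5)
  expect_equal(compute_fdr(1000, 250), 25)
  expect_equal(compute_fdr(0, 0), 0)
  expect_equal(compute_fdr(0, 3), 100)
  expect_equal(compute_fdr(10, 30), 100)
  expect_equal(compute_fdr(40, 2, method = "concatenated"), 100 * 4 / 42)
  expect_error(compute_fdr(-1, 0), "non-negative")
})

test_that("FDR decreases as the threshold rises when decoys score below targets", {
  withr::with_seed(51, {
    for (i in 1:20) {
      nt <- sample(50:200, 1); nd <- sample(20:100, 1)
      psms <- data.frame(
        confidence = c(runif(nt, 0.5, 1), runif(nd, 0, 0.5)),
        is_decoy = rep(c(FALSE, TRUE), c(nt, nd)))
      curve <- fdr_curve(psms, seq(0, 1, by = 0.05))
      expect_true(all(diff(curve$fdr) <= 1e-9))
    }
  })
})

test_that("pre-screening keeps high-confidence targets and all decoys per unit", {
  pep <- c("LVGDAAETFK", "TTENWVDFLR")
  sp <- spectra_from_peptides(pep, n_noise_peaks = 0, seed = 4)
  tgt <- data.frame(accession = c("SF.u1.1", "SF.u1.2"),
                    aa = paste0("GGK", pep, "GG"),
                    is_decoy = FALSE, stringsAsFactors = FALSE)
  unit1 <- rbind(tgt, make_decoy(tgt))
  # a decoy-only unit still reports decoy hits but no targets
  dec <- make_decoy(data.frame(accession = c("SF.u2.1", "SF.u2.2"),
                               aa = paste0("AAK", pep, "AA"),
                               is_decoy = FALSE, stringsAsFactors = FALSE))
  pre <- prescreen(sp, list(u1 = unit1, u2 = dec), confidence_min = 0.95)
  expect_setequal(pre$target_hits$pep, pep)
  expect_true(all(pre$target_hits$unit == "u1"))
  expect_true(all(pre$decoy_hits$is_decoy))
  expect_true(any(pre$decoy_hits$unit == "u2"))
  # both units retain their own assignment of the same spectrum:
  # competition is deferred to the second stage
  unit2b <- data.frame(accession = "SF.u2.3", aa = paste0("AAK", pep[1], "AA"),
                       is_decoy = FALSE, stringsAsFactors = FALSE)
  pre2 <- prescreen(sp[1], list(u1 = unit1, u2 = unit2b), confidence_min = 0.9)
  expect_equal(sum(pre2$target_hits$pep == pep[1]), 2L)
  expect_error(prescreen(sp, list(u1 = unit1, u2 = NULL)), "u2")
})

test_that("the amalgamated database unions reference and hit parents without duplicates", {
  ref <- data.frame(accession = c("REF_A", "REF_B"), aa = c("MMMK", "WWWR"),
                    stringsAsFactors = FALSE)
  empty_pre <- structure(list(
    target_hits = data.frame(accession = character(0)),
    decoy_hits = data.frame(accession = character(0))),
    class = "prescreen_result")
  expect_identical(build_amalgamated_db(ref, empty_pre, list())$accession,
                   ref$accession)

  tgt <- data.frame(accession = c("SF.1", "SF.2"),
                    aa = c("GGKAAAAAAR", "GGKCCCCCCR"),
                    is_decoy = FALSE, stringsAsFactors = FALSE)
  units <- list(u1 = rbind(tgt, make_decoy(tgt)),
                u2 = rbind(tgt, make_decoy(tgt)))  # same accessions twice
  pre <- structure(list(
    target_hits = data.frame(accession = c("SF.1", "SF.1", "SF.2")),
    decoy_hits = data.frame(accession = c("DECOY_SF.1", "DECOY_SF.1"))),
    class = "prescreen_result")
  amal <- build_amalgamated_db(ref, pre, units)
  expect_equal(nrow(amal), nrow(ref) + 2L + 1L)
  expect_false(any(duplicated(amal$accession)))
  # accession collisions across namespaces are refused
  ref2 <- rbind(ref, data.frame(accession = "SF.1", aa = "KKKK"))
  expect_error(build_amalgamated_db(ref2, pre, units), "collision")
})

test_that("orphans are six-frame-only peptides, with exclusions logged by reason", {
  mk <- function(peps, confs, decoy = FALSE) {
    data.frame(spectrum_id = paste0("s", seq_along(peps)), pep = peps,
               accession = paste0("SF.", seq_along(peps)),
               offset = 0L, shared_peaks = 10L, n_ions = 12L,
               confidence = confs, is_decoy = decoy, stringsAsFactors = FALSE)
  }
  shared <- paste0("SHARED", 1:20, "R")
  novel <- paste0("NOVEL", 1:3, "K")
  multi <- "MULTIMULTIK"
  lowref <- "LOWCONFREFK"
  six <- mk(c(shared, novel, multi, lowref), rep(0.99, 25))
  ref <- mk(c(shared, lowref), c(rep(0.99, 20), 0.90))
  os <- identify_orphans(six, ref, confidence_min = 0.95,
                         locus_count = function(p) if (p == multi) 2L else 1L)
  expect_setequal(os$orphans$pep, novel)
  expect_equal(os$excluded$reason[os$excluded$pep == multi], "multi_target")
  expect_equal(os$excluded$reason[os$excluded$pep == lowref],
               "low_confidence_reference")
  expect_equal(os$counts$overlap, 20L)
  expect_equal(os$counts$multi_target, 1L)
  expect_equal(os$counts$reference_lowconf, 1L)
  # identical searches yield no orphans
  os2 <- identify_orphans(mk(shared, rep(0.99, 20)), mk(shared, rep(0.99, 20)))
  expect_equal(nrow(os2$orphans), 0L)
  # every six-frame peptide lands in exactly one terminal bucket
  buckets <- c(os$counts$overlap, nrow(os$orphans), nrow(os$excluded))
  expect_equal(sum(buckets), length(unique(six$pep)))
})

test_that("funnel arithmetic is additive and rejects inconsistent stages", {
  z <- funnel_report(0, 0, 0)
  expect_equal(z$overlap_pct, 0)
  expect_equal(z$post_exclusion, 0)
  fr <- funnel_report(100, 80, 60, junction_explained = 10,
                      sixframe_lowconf_explained = 5, multi_target = 7,
                      reference_lowconf = 3)
  expect_equal(fr$sixframe_unique, 40)
  expect_equal(fr$reference_unique, 20)
  expect_equal(fr$post_exclusion, 30)
  expect_equal(fr$overlap_pct, 75)
  expect_error(funnel_report(10, 8, 9), "negative")
  expect_error(funnel_report(10, 8, 6, multi_target = 5), "negative")
})
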