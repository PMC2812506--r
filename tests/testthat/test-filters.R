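test_that("pseudogene/EST matching is exact, full-length and strand-aware", {
  refs <- c(pg1 = "ACGTACGTACGTAAACCCGGG", pg2 = "TTTTGGGGCCCCAAAA")
  expect_true(exact_dna_filter("ACGTACGTACGTAAACCCGGG", refs)$match)
  expect_equal(exact_dna_filter("GGGGCCCC", refs)$accession, "pg2")
  # one mismatch breaks the match
  expect_false(exact_dna_filter("ACGTACGTACGTAAACCCGGA", refs)$match)
  # reverse complement only matches when the set is declared unstranded
  rc <- revcomp("CGTACGTAAACCC")   # present in pg1 on the other strand only
  expect_false(exact_dna_filter(rc, refs)$match)
  expect_true(exact_dna_filter(rc, refs, stranded = FALSE)$match)
})

test_that("substring matching equals a brute-force scan on random sets", {
  withr::with_seed(71, {
    refs <- vapply(1:50, function(i)
      paste(sample(c("A", "C", "G", "T"), sample(30:80, 1), TRUE),
            collapse = ""), character(1))
    names(refs) <- paste0("r", 1:50)
    hits_impl <- logical(100); hits_oracle <- logical(100)
    for (i in 1:100) {
      q <- if (i <= 50) {
        # half the queries are genuine substrings
        r <- refs[[sample(50, 1)]]
        a <- sample(nchar(r) - 10L, 1)
        substr(r, a, a + sample(5:10, 1))
      } else {
        paste(sample(c("A", "C", "G", "T"), 15, TRUE), collapse = "")
      }
      hits_impl[i] <- exact_dna_filter(q, refs)$match
      hits_oracle[i] <- any(vapply(refs, function(r)
        grepl(q, r, fixed = TRUE), logical(1)))
    }
    expect_identical(hits_impl, hits_oracle)
  })
})

test_that("repeat overlap uses closed intervals and matches a quadratic scan", {
  reps <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(100, 500), c(199, 599)))
  expect_false(repeat_overlap(list(chrom = "c1", start = 200, end = 300), reps))
  expect_true(repeat_overlap(list(chrom = "c1", start = 199, end = 300), reps))
  expect_false(repeat_overlap(list(chrom = "c2", start = 100, end = 300), reps))
  withr::with_seed(72, {
    rep_df <- data.frame(start = sort(sample(1:5000, 20)))
    rep_df$end <- rep_df$start + sample(10:100, 20, TRUE)
    gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(rep_df$start, rep_df$end))
    for (i in 1:100) {
      st <- sample(1:5000, 1); en <- st + sample(5:80, 1)
      got <- repeat_overlap(list(chrom = "c1", start = st, end = en), gr)
      want <- any(st <= rep_df$end & en >= rep_df$start)
      expect_identical(got, want)
    }
  })
})

test_that("sigma-R averages per-base scores with absent positions as zero", {
  track <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(101, 401), c(130, 415)),
                                  score = c(2, 3))
  # no coverage at all
  expect_equal(conservation_sigma(list(chrom = "c1", start = 900, end = 929),
                                  track), 0)
  # constant 2 over the whole interval
  expect_equal(conservation_sigma(list(chrom = "c1", start = 101, end = 130),
                                  track), 2)
  # 3.0 over exactly half of a 30-nt interval: 45/30
  expect_equal(conservation_sigma(list(chrom = "c1", start = 401, end = 430),
                                  track), 1.5)
  # splitting an interval and length-weighting the parts changes nothing
  withr::with_seed(73, {
    for (i in 1:20) {
      st <- sample(1:800, 1); w <- sample(10:60, 1)
      whole <- conservation_sigma(list(chrom = "c1", start = st,
                                      end = st + w - 1), track)
      cut <- sample(seq_len(w - 1), 1)
      left <- conservation_sigma(list(chrom = "c1", start = st,
                                     end = st + cut - 1), track)
      right <- conservation_sigma(list(chrom = "c1", start = st + cut,
                                      end = st + w - 1), track)
      expect_equal(whole, (left * cut + right * (w - cut)) / w,
                   tolerance = 1e-12)
    }
  })
})

test_that("the conservation cutoff test strips zeros and detects shifted distributions", {
  same <- c(rep(0, 5), 1:50)
  res <- choose_sigma_cutoff(same, same)
  expect_equal(res$cutoff, 0)
  expect_gt(res$p_value, 0.9)
  expect_equal(res$n_exonic, 50)
  withr::with_seed(74, {
    exonic <- rnorm(200, mean = 5, sd = 1)
    cand <- rnorm(200, mean = 0, sd = 1)
  })
  shifted <- choose_sigma_cutoff(exonic, cand)
  expect_lt(shifted$p_value, 0.01)
  # U statistic equals explicit pairwise counting on small lists
  withr::with_seed(75, {
    for (i in 1:10) {
      x <- sample(1:40, sample(5:15, 1), TRUE) / 2
      y <- sample(1:40, sample(5:15, 1), TRUE) / 2
      got <- choose_sigma_cutoff(c(x, 0), c(y, 0))
      expect_equal(got$statistic, oracle_u_stat(x[x != 0], y[y != 0]))
    }
  })
  expect_error(choose_sigma_cutoff(c(0, 0), 1:3), "exonic")
})

test_that("filters are order-independent and EST evidence never excludes", {
  fx <- SMALL_FX
  nv <- fx$manifest$novel_peptides
  ps <- fx$manifest$pseudogene_peptides
  cand <- rbind(nv[, c("pep", "chrom", "strand", "start", "end")],
                ps[, c("pep", "chrom", "strand", "start", "end")])
  res <- apply_locus_filters(cand, fx$genome, pseudogenes = fx$pseudogenes,
                             repeats = fx$repeats,
                             conservation = fx$conservation, ests = fx$ests)
  # survivor set = conjunction of independent predicates, any order
  expect_identical(res$pass,
                   !res$pseudogene_fail & !res$repeat_fail & !res$conservation_fail)
  expect_identical(res$pass,
                   !res$conservation_fail & !res$repeat_fail & !res$pseudogene_fail)
  # planted novels survive; pseudogene plants fail exactly the pseudogene filter
  is_novel <- cand$pep %in% nv$pep
  expect_true(all(res$pass[is_novel]))
  expect_true(all(res$pseudogene_fail[!is_novel]))
  expect_false(any(res$repeat_fail[!is_novel]))
  expect_false(any(res$conservation_fail[!is_novel]))
  # EST support is informational: it never contributes to pass/fail
  expect_true(any(!res$est_support))
})
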