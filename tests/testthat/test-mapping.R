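test_that("peptide loci follow the 3-nt-per-residue arithmetic on both strands", {
  # plus strand: a 9-residue peptide at the parent start spans 27 nt
  parent4 <- list(accession = "p4", chrom = "chr3", strand = 1L,
                  start = 197481979L, end = 197482005L, aa = "TQALVEILK")
  loc <- map_peptide_locus(parent4, 0L, 9L)
  expect_equal(loc$start, 197481979L)
  expect_equal(loc$end, 197482005L)
  # a 15-residue peptide spans 45 nt
  parent5 <- list(accession = "p5", chrom = "chr2", strand = 1L,
                  start = 194761171L, end = 194761215L,
                  aa = "SSGLYGGGGQSFDKP")
  loc5 <- map_peptide_locus(parent5, 0L, 15L)
  expect_equal(loc5$end, 194761215L)
  # whole-parent identity on both strands
  for (strand in c(1L, -1L)) {
    p <- list(accession = "x", chrom = "c", strand = strand,
              start = 1001L, end = 1030L, aa = "ABCDEFGHIJ")
    full <- map_peptide_locus(p, 0L, 10L)
    expect_equal(c(full$start, full$end), c(1001L, 1030L))
  }
  # interior peptide on the minus strand counts from the parent end
  p <- list(accession = "m", chrom = "c", strand = -1L,
            start = 1001L, end = 1030L, aa = "ABCDEFGHIJ")
  loc_m <- map_peptide_locus(p, 2L, 3L)
  expect_equal(c(loc_m$start, loc_m$end), c(1016L, 1024L))
  expect_error(map_peptide_locus(p, 8L, 3L), "outside parent")
})

test_that("peptide loci round-trip through extraction and translation per class", {
  mf <- SMALL_FX$manifest
  genome <- SMALL_FX$genome
  planted <- rbind(
    mf$known_peptides[, c("pep", "chrom", "strand", "start", "end")],
    mf$novel_peptides[, c("pep", "chrom", "strand", "start", "end")])
  for (i in seq_len(nrow(planted))) {
    nt <- extract_genomic(genome, planted$chrom[i], planted$start[i],
                          planted$end[i], planted$strand[i])
    expect_identical(translate_frame(nt, 1L), planted$pep[i])
  }
})

test_that("classification assigns the constructed annotation classes", {
  ann <- build_annotation(toy_gene_models())
  cls <- function(start, end, strand = 1L, n = 1L) {
    classify_locus(list(chrom = "chrT", strand = strand,
                        start = start, end = end), ann, n)$label
  }
  expect_equal(cls(500, 530), "intergenic")       # between the two genes
  expect_equal(cls(220, 250), "intronic")         # inside gA, between exons
  expect_equal(cls(2000, 2030), "intergenic")
  expect_equal(cls(101, 130), "exonic_in_frame")  # gA.e1 codons start at 101
  expect_equal(cls(102, 131), "exonic_not_in_frame")
  expect_equal(cls(101, 130, strand = -1L), "exonic_not_in_frame") # antisense
  # gA.e2 phase 2: codons start at 303
  expect_equal(cls(303, 332), "exonic_in_frame")
  expect_equal(cls(304, 333), "exonic_not_in_frame")
  # minus-strand gene gB.e2 phase 1: codons end at 1149 counting downwards
  expect_equal(cls(1120, 1149, strand = -1L), "exonic_in_frame")
  expect_equal(cls(1119, 1148, strand = -1L), "exonic_not_in_frame")
  # crossing an exon edge into the intron: 3' for plus-strand gA.e1
  expect_equal(cls(190, 210), "exonic_extending_3p")
  expect_equal(cls(95, 120), "exonic_extending_5p")
  # for minus-strand gB.e1, exceeding the genomic high edge is its 5' side
  expect_equal(cls(1390, 1410, strand = -1L), "exonic_extending_5p")
  expect_equal(cls(1290, 1310, strand = -1L), "exonic_extending_3p")
  # multi-locus peptides are set aside regardless of position
  expect_equal(cls(500, 530, n = 2L), "multi_target")
  expect_error(classify_locus(list(chrom = "chrZ", strand = 1L,
                                   start = 1, end = 10), ann),
               "absent from annotation")
})

test_that("classification is a partition and is invariant under strand mirroring", {
  gm <- toy_gene_models()
  ann <- build_annotation(gm)
  L <- 3000L
  mirror_gm <- gm
  mirror_gm$start <- L - gm$end + 1L
  mirror_gm$end <- L - gm$start + 1L
  mirror_gm$strand <- ifelse(gm$strand == "+", "-", "+")
  ann_m <- build_annotation(mirror_gm)
  labels <- character(0)
  withr::with_seed(61, {
    for (i in 1:200) {
      w <- sample(15:60, 1)
      st <- sample(seq_len(L - w), 1)
      strand <- sample(c(1L, -1L), 1)
      l1 <- classify_locus(list(chrom = "chrT", strand = strand,
                                start = st, end = st + w - 1L), ann)$label
      l2 <- classify_locus(list(chrom = "chrT", strand = -strand,
                                start = L - (st + w - 1L) + 1L,
                                end = L - st + 1L), ann_m)$label
      expect_identical(l2, l1)
      labels <- c(labels, l1)
    }
  })
  # exactly one label per locus, labels drawn from the expected set
  expect_length(labels, 200L)
  expect_true(all(labels %in% c("intergenic", "intronic", "exonic_in_frame",
                                "exonic_not_in_frame", "exonic_extending_5p",
                                "exonic_extending_3p")))
})

test_that("fixture loci are classified exactly as the manifest plants them", {
  ann <- build_annotation(SMALL_FX$gene_models)
  mf <- SMALL_FX$manifest
  all_p <- rbind(
    mf$known_peptides[, c("pep", "class", "chrom", "strand", "start", "end")],
    mf$novel_peptides[, c("pep", "class", "chrom", "strand", "start", "end")])
  got <- classify_loci(all_p, ann)
  expect_identical(got$label, all_p$class)
  # the classified counts partition the planted loci
  expect_equal(sum(table(got$label)), nrow(all_p))
})

test_that("genomic-locus counting agrees with a direct interval scan", {
  entries <- SMALL_DB
  # a planted novel peptide occurs at exactly one locus
  nv <- SMALL_FX$manifest$novel_peptides
  for (p in nv$pep) expect_equal(count_genomic_loci(p, entries), 1L)
  # an absent peptide occurs nowhere
  expect_equal(count_genomic_loci("WWWWWWWWWWNEVER", entries), 0L)
  # short motifs occur at many loci
  expect_gt(count_genomic_loci("KK", entries), 1L)
})

test_that("BED export/import converts coordinates bit-exactly", {
  loci <- data.frame(chrom = c("chr1", "chr2"), start = c(1L, 501L),
                     end = c(90L, 549L), strand = c(1L, -1L),
                     name = c("a", "b"), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".bed")
  loci_to_bed(loci, path)
  raw <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(raw$V2, c(0L, 500L))   # 0-based half-open starts
  expect_equal(raw$V3, c(90L, 549L))
  back <- bed_to_loci(path)
  expect_equal(back$start, loci$start)
  expect_equal(back$end, loci$end)
  expect_equal(back$strand, loci$strand)
})

test_that("gene models survive a GTF round trip including CDS phases", {
  gm <- SMALL_FX$gene_models
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gene_models(gm, path)
  back <- read_gene_models(path)
  o1 <- order(gm$transcript_id, gm$exon_rank)
  rownames(back) <- NULL
  gm_sorted <- gm[o1, ]
  rownames(gm_sorted) <- NULL
  expect_identical(back, gm_sorted)
})
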