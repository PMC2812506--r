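# Shared small fixture, built once per test run. One 20-kb chromosome,
# four genes, four novel ORFs (one of each class), two pseudogene plants.
small_fixture_config <- function() {
  fixture_config(chroms = 1L, chrom_len = 20000L, genes = 4L, novel = 4L,
                 pseudogenes = 2L, repeats = 3L)
}

SMALL_FX <- generate_fixture(small_fixture_config(), seed = 101L)

# Six-frame target database of the small fixture (built once, reused).
SMALL_DB <- translate_six_frame(SMALL_FX$genome[[1L]],
                                chrom = names(SMALL_FX$genome)[1L])

# A hand-made toy annotation: two genes on chr1 with known exon frames.
toy_gene_models <- function() {
  data.frame(
    chrom = "chrT",
    start = c(101L, 301L, 1001L, 1301L),
    end = c(200L, 400L, 1150L, 1400L),
    strand = c("+", "+", "-", "-"),
    gene_id = c("gA", "gA", "gB", "gB"),
    transcript_id = c("gA.t1", "gA.t1", "gB.t1", "gB.t1"),
    exon_id = c("gA.e1", "gA.e2", "gB.e2", "gB.e1"),
    exon_rank = c(1L, 2L, 2L, 1L),
    phase = c(0L, 2L, 1L, 0L),
    stringsAsFactors = FALSE
  )
}
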