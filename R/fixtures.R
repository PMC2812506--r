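# Synthetic fixture generation: a toy genome with annotated genes, planted
# novel ORFs of every annotation class, pseudogene-derived decoy peptides,
# repeat/conservation tracks and (separately) spectra with known ground
# truth -- so every stage of the discovery pipeline is testable without any
# external download.
#
# Layout per chromosome: an alternating sequence of random background gaps
# and "items" (gene blocks or standalone ORF cassettes), followed by a
# random background tail that hosts the repeat intervals and negative
# conservation windows. Every planted peptide is checked to occur at
# exactly one genomic locus; the construction is retried from a fresh
# derived seed if a random collision arises.

#' Fixture configuration
#'
#' Defaults define the standard study conditions of the simulated dataset:
#' two 50-kb chromosomes, ten three-exon genes, five novel ORFs (two
#' intergenic, one intronic, one exonic-not-in-frame, one
#' exonic-3'-extending), three pseudogene-derived plants and five repeat
#' intervals.
#'
#' @param chroms number of chromosomes.
#' @param chrom_len chromosome length (nt).
#' @param genes number of annotated genes.
#' @param novel number of planted novel ORFs.
#' @param pseudogenes number of pseudogene-derived plants.
#' @param repeats number of repeat intervals.
#' @param gap background gap between layout items (nt).
#' @return named list of settings.
#' @export
fixture_config <- function(chroms = 2L, chrom_len = 50000L, genes = 10L,
                           novel = 5L, pseudogenes = 3L, repeats = 5L,
                           gap = 400L) {
  list(chroms = chroms, chrom_len = chrom_len, genes = genes, novel = novel,
       pseudogenes = pseudogenes, repeats = repeats, gap = gap)
}

# --- small sequence helpers -------------------------------------------------

CODON_BY_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_aa <- function(n, exclude = character(0)) {
  paste(sample(setdiff(AA_LETTERS, exclude), n, replace = TRUE), collapse = "")
}

# Random codon choice for an amino-acid string.
aa_to_dna <- function(aa) {
  paste(vapply(chars(aa), function(a) {
    cods <- CODON_BY_AA[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

# A tryptic planted peptide: starts with a non-P residue, ends in R, no
# internal K/R/P so it is a clean 0-missed-cleavage product.
random_tryptic_pep <- function(len) {
  paste0(random_aa(len - 1L, exclude = c("K", "R", "P")), "R")
}

# ORF cassette around a peptide: stop + G K pep G + stop, returned with the
# coordinates (1-based, within the cassette) of the ORF and of the peptide.
make_cassette <- function(pep) {
  orf_aa <- paste0("GK", pep, "G")
  dna <- paste0("TAA", aa_to_dna(orf_aa), "TAA")
  list(dna = dna, orf_aa = orf_aa,
       orf_start = 4L, orf_end = 3L + 3L * nchar(orf_aa),
       pep_start = 10L, pep_end = 9L + 3L * nchar(pep))
}

# Map an interval [a, b] given in block-local coordinates of the *reading*
# strand to forward-genomic block-local coordinates.
orient <- function(a, b, block_len, strand) {
  if (strand == "+") c(a, b) else c(block_len - b + 1L, block_len - a + 1L)
}

# --- gene construction ------------------------------------------------------

# Exon lengths and intron/flank sizes of every fixture gene.
GENE_EXON_LEN <- c(70L, 60L, 50L)
GENE_INTRON_LEN <- 150L
GENE_FLANK <- 60L

# Build one gene block in transcript orientation, optionally hosting a
# planted cassette inside exon 2 (off-frame), inside intron 1, or straddling
# the exon 3 3' boundary. Returns the forward-genomic block plus feature
# offsets (block-local, forward-genomic coordinates).
build_gene <- function(gene_id, strand, host = c("none", "notinframe",
                                                 "intronic", "extend"),
                       host_pep = NULL, max_tries = 200L) {
  host <- match.arg(host)
  if (host %in% c("notinframe", "extend") && strand != "+") {
    stop("cassette-hosting genes are generated on the plus strand")
  }
  known_pep <- random_tryptic_pep(9L)
  n_aa <- sum(GENE_EXON_LEN) / 3L
  # protein: 10 residues, K, the known peptide, then filler (first not P)
  tail_len <- n_aa - 10L - 1L - nchar(known_pep)
  protein <- paste0(random_aa(10L), "K", known_pep,
                    random_aa(1L, exclude = "P"), random_aa(tail_len - 1L))

  cum <- cumsum(c(0L, GENE_EXON_LEN))
  phases <- (3L - cum[-length(cum)] %% 3L) %% 3L

  for (try in seq_len(max_tries)) {
    cds <- aa_to_dna(protein)
    exon_seq <- substring(cds, cum[-length(cum)] + 1L, cum[-1L])
    cassette <- NULL
    extend_tail <- NULL
    if (host == "notinframe") {
      cassette <- make_cassette(host_pep)
      # exon-local 0-based offset 3 puts the cassette one base off the
      # annotated codon phase of exon 2
      exon_seq[2L] <- paste0(substr(exon_seq[2L], 1L, 3L), cassette$dna,
                             substr(exon_seq[2L], 3L + nchar(cassette$dna) + 1L,
                                    nchar(exon_seq[2L])))
      stopifnot(nchar(exon_seq[2L]) == GENE_EXON_LEN[2L])
    } else if (host == "extend") {
      cassette <- make_cassette(host_pep)
      # peptide occupies the last 26 nt of exon 3 and runs 10 nt beyond it;
      # 26 keeps the cassette's stop codons out of phase with the CDS frame
      in_exon <- 26L
      pep_len_nt <- cassette$pep_end - cassette$pep_start + 1L
      head_len <- cassette$pep_start - 1L               # TAA + GK codons
      exon_part_start <- GENE_EXON_LEN[3L] - in_exon - head_len + 1L
      full <- cassette$dna
      split_at <- head_len + in_exon                    # nt kept inside exon
      exon_seq[3L] <- paste0(substr(exon_seq[3L], 1L, exon_part_start - 1L),
                             substr(full, 1L, split_at))
      extend_tail <- substr(full, split_at + 1L, nchar(full))
      stopifnot(nchar(exon_seq[3L]) == GENE_EXON_LEN[3L])
    }
    new_protein <- translate_frame(paste(exon_seq, collapse = ""), 1L)
    if (!grepl("*", new_protein, fixed = TRUE)) {
      protein_final <- new_protein
      break
    }
    if (try == max_tries) stop("could not embed cassette without a stop codon")
  }

  intron <- c(random_dna(GENE_INTRON_LEN), random_dna(GENE_INTRON_LEN))
  if (host == "intronic") {
    cassette <- make_cassette(host_pep)
    intron[1L] <- paste0(substr(intron[1L], 1L, 50L), cassette$dna,
                         substr(intron[1L], 50L + nchar(cassette$dna) + 1L,
                                GENE_INTRON_LEN))
    stopifnot(nchar(intron[1L]) == GENE_INTRON_LEN)
  }

  flank5 <- random_dna(GENE_FLANK)
  flank3 <- random_dna(GENE_FLANK)
  if (host == "extend") {
    flank3 <- paste0(extend_tail,
                     substr(flank3, nchar(extend_tail) + 1L, GENE_FLANK))
  }
  block_t <- paste0(flank5, exon_seq[1L], intron[1L], exon_seq[2L],
                    intron[2L], exon_seq[3L], flank3)
  L <- nchar(block_t)

  # transcript-oriented offsets
  starts_t <- cumsum(c(1L, GENE_FLANK, GENE_EXON_LEN[1L], GENE_INTRON_LEN,
                       GENE_EXON_LEN[2L], GENE_INTRON_LEN, GENE_EXON_LEN[3L]))
  exon_t <- rbind(c(starts_t[2L], starts_t[3L] - 1L),
                  c(starts_t[4L], starts_t[5L] - 1L),
                  c(starts_t[6L], starts_t[7L] - 1L))
  # known peptide: CDS nt 34..60 inside exon 1
  known_t <- c(exon_t[1L, 1L] + 33L, exon_t[1L, 1L] + 59L)

  cass_t <- NULL
  if (!is.null(cassette)) {
    base_t <- switch(host,
      notinframe = exon_t[2L, 1L] + 3L,
      intronic = exon_t[1L, 2L] + 1L + 50L,
      extend = exon_t[3L, 2L] - (cassette$pep_start - 1L + 26L) + 1L
    )
    cass_t <- list(
      orf = c(base_t + cassette$orf_start - 1L, base_t + cassette$orf_end - 1L),
      pep = c(base_t + cassette$pep_start - 1L, base_t + cassette$pep_end - 1L)
    )
  }

  block <- if (strand == "+") block_t else revcomp(block_t)
  flip <- function(ab) orient(ab[1L], ab[2L], L, strand)
  exons_g <- t(apply(exon_t, 1L, flip))
  list(
    gene_id = gene_id, strand = strand, block = block, length = L,
    protein = protein_final, known_pep = known_pep,
    exons = exons_g[order(exons_g[, 1L]), , drop = FALSE],
    exon_rank_of_sorted = order(order(exon_t[, 1L] * if (strand == "+") 1L else -1L)),
    exon_t = exon_t, phases = phases,
    known = flip(known_t),
    cassette = if (!is.null(cass_t)) {
      list(orf = flip(cass_t$orf), pep = flip(cass_t$pep),
           orf_aa = cassette$orf_aa)
    }
  )
}

# --- fixture assembly -------------------------------------------------------

#' Generate a synthetic proteogenomics fixture
#'
#' Builds a genome with annotated genes, planted novel ORFs, pseudogene
#' plants and auxiliary tracks; deterministic given the seed. Conservation
#' is planted at +2 over novel ORFs and -1 over background windows (absent
#' elsewhere), so the sigma-R >= 0 cutoff separates the classes by
#' construction; pseudogene plants are left unscored and are removed by the
#' pseudogene filter alone.
#'
#' @param config list from [fixture_config()].
#' @param seed integer master seed; all randomness derives from it.
#' @param out_dir optional directory: when given, writes `genome.fa`,
#'   `genes.gtf`, `reference_proteins.fa`, `pseudogenes.fa`, `ests.fa`,
#'   `repeats.bed`, `conservation.bedGraph` and `manifest.json`.
#' @return list with `genome` (named character), `gene_models` (table),
#'   `reference` (data frame: `accession`, `gene_id`, `aa`), `pseudogenes`,
#'   `ests` (named character), `repeats`, `conservation` (`GRanges`) and
#'   `manifest` (list; includes per-peptide ground truth).
#' @export
generate_fixture <- function(config = fixture_config(), seed = 1L,
                             out_dir = NULL) {
  seeds <- derive_seeds(seed, 25L)
  for (attempt in seq_len(20L)) {
    fx <- try(build_fixture_once(config, seeds[attempt]), silent = TRUE)
    if (!inherits(fx, "try-error")) break
    if (attempt == 20L) stop("fixture generation failed: ", fx)
  }
  fx$manifest$seed <- seed
  if (!is.null(out_dir)) write_fixture(fx, out_dir)
  fx
}

build_fixture_once <- function(config, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  if (config$genes < 2L || config$chroms < 1L) stop("need >= 2 genes, >= 1 chromosome")
  novel_classes <- c("exonic_not_in_frame", "exonic_extending_3p", "intronic",
                     rep("intergenic", max(0L, config$novel - 3L)))
  novel_classes <- novel_classes[seq_len(config$novel)]
  novel_peps <- vapply(seq_len(config$novel), function(i)
    random_tryptic_pep(if (novel_classes[i] == "exonic_extending_3p") 12L else 10L),
    character(1))
  pseudo_peps <- vapply(seq_len(config$pseudogenes), function(i)
    random_tryptic_pep(11L), character(1))

  # genes; the first two (plus strand) host the exonic cassettes, the third
  # hosts the intronic one
  strands <- rep(c("+", "-"), length.out = config$genes)
  strands[1:3] <- "+"
  genes <- vector("list", config$genes)
  for (i in seq_len(config$genes)) {
    host <- "none"; hp <- NULL
    if (config$novel >= 1L && i == 1L) { host <- "notinframe"; hp <- novel_peps[1L] }
    if (config$novel >= 2L && i == 2L) { host <- "extend"; hp <- novel_peps[2L] }
    if (config$novel >= 3L && i == 3L) { host <- "intronic"; hp <- novel_peps[3L] }
    genes[[i]] <- build_gene(sprintf("GENE%03d", i), strands[i], host, hp)
  }

  # standalone cassettes: intergenic novels and pseudogene plants
  standalone <- list()
  if (config$novel > 3L) {
    for (k in 4:config$novel) {
      standalone[[length(standalone) + 1L]] <- list(
        kind = "novel", idx = k, pep = novel_peps[k],
        strand = if (k %% 2L == 0L) "+" else "-")
    }
  }
  for (k in seq_len(config$pseudogenes)) {
    standalone[[length(standalone) + 1L]] <- list(
      kind = "pseudo", idx = k, pep = pseudo_peps[k], strand = "+")
  }

  # round-robin assignment of items to chromosomes
  items <- c(lapply(seq_along(genes), function(i) list(kind = "gene", idx = i)),
             standalone)
  chrom_of <- rep(seq_len(config$chroms), length.out = length(items))

  chrom_names <- sprintf("chr%d", seq_len(config$chroms))
  genome <- character(0)
  gene_rows <- list(); known_rows <- list(); novel_rows <- list()
  pseudo_rows <- list(); cons_rows <- list(); repeat_rows <- list()

  for (ci in seq_len(config$chroms)) {
    parts <- character(0); pos <- 0L
    for (ii in which(chrom_of == ci)) {
      it <- items[[ii]]
      parts <- c(parts, random_dna(config$gap)); pos <- pos + config$gap
      if (it$kind == "gene") {
        g <- genes[[it$idx]]
        at <- pos + 1L
        parts <- c(parts, g$block); pos <- pos + g$length
        sorted_ranks <- g$exon_rank_of_sorted
        for (e in seq_len(nrow(g$exons))) {
          gene_rows[[length(gene_rows) + 1L]] <- data.frame(
            chrom = chrom_names[ci],
            start = at + g$exons[e, 1L] - 1L, end = at + g$exons[e, 2L] - 1L,
            strand = g$strand, gene_id = g$gene_id,
            transcript_id = paste0(g$gene_id, ".t1"),
            exon_id = sprintf("%s.e%d", g$gene_id, sorted_ranks[e]),
            exon_rank = sorted_ranks[e],
            phase = g$phases[sorted_ranks[e]], stringsAsFactors = FALSE)
        }
        known_rows[[length(known_rows) + 1L]] <- data.frame(
          gene_id = g$gene_id, pep = g$known_pep, class = "exonic_in_frame",
          chrom = chrom_names[ci],
          strand = if (g$strand == "+") 1L else -1L,
          start = at + g$known[1L] - 1L, end = at + g$known[2L] - 1L,
          stringsAsFactors = FALSE)
        if (!is.null(g$cassette)) {
          idx <- it$idx
          cls <- c("exonic_not_in_frame", "exonic_extending_3p", "intronic")[idx]
          novel_rows[[length(novel_rows) + 1L]] <- data.frame(
            pep = novel_peps[idx], class = cls, chrom = chrom_names[ci],
            strand = if (g$strand == "+") 1L else -1L,
            start = at + g$cassette$pep[1L] - 1L,
            end = at + g$cassette$pep[2L] - 1L,
            orf_start = at + g$cassette$orf[1L] - 1L,
            orf_end = at + g$cassette$orf[2L] - 1L,
            host_gene = g$gene_id, stringsAsFactors = FALSE)
          cons_rows[[length(cons_rows) + 1L]] <- data.frame(
            chrom = chrom_names[ci], start = at + g$cassette$orf[1L] - 1L,
            end = at + g$cassette$orf[2L] - 1L, score = 2,
            stringsAsFactors = FALSE)
        }
      } else {
        cass <- make_cassette(it$pep)
        pad <- 20L
        block_r <- paste0(random_dna(pad), cass$dna, random_dna(pad))
        L <- nchar(block_r)
        block <- if (it$strand == "+") block_r else revcomp(block_r)
        at <- pos + 1L
        parts <- c(parts, block); pos <- pos + L
        orf <- orient(pad + cass$orf_start, pad + cass$orf_end, L, it$strand)
        pepi <- orient(pad + cass$pep_start, pad + cass$pep_end, L, it$strand)
        row <- data.frame(
          pep = it$pep, chrom = chrom_names[ci],
          strand = if (it$strand == "+") 1L else -1L,
          start = at + pepi[1L] - 1L, end = at + pepi[2L] - 1L,
          orf_start = at + orf[1L] - 1L, orf_end = at + orf[2L] - 1L,
          stringsAsFactors = FALSE)
        if (it$kind == "novel") {
          row$class <- "intergenic"; row$host_gene <- NA_character_
          novel_rows[[length(novel_rows) + 1L]] <-
            row[, c("pep", "class", "chrom", "strand", "start", "end",
                    "orf_start", "orf_end", "host_gene")]
          cons_rows[[length(cons_rows) + 1L]] <- data.frame(
            chrom = chrom_names[ci], start = row$orf_start, end = row$orf_end,
            score = 2, stringsAsFactors = FALSE)
        } else {
          pseudo_rows[[length(pseudo_rows) + 1L]] <- row
        }
      }
    }
    tail_needed <- config$chrom_len - pos
    if (tail_needed < 7000L) {
      stop("config infeasible: planted items do not fit in chromosome ", ci)
    }
    parts <- c(parts, random_dna(tail_needed))
    genome[chrom_names[ci]] <- paste(parts, collapse = "")

    # repeats and negative conservation windows live in the background tail
    tail_start <- pos + 500L
    for (r in seq_len(config$repeats)) {
      if ((r %% config$chroms) + 1L == ci) {
        repeat_rows[[length(repeat_rows) + 1L]] <- data.frame(
          chrom = chrom_names[ci], start = tail_start + (r - 1L) * 400L,
          end = tail_start + (r - 1L) * 400L + 199L, stringsAsFactors = FALSE)
      }
    }
    cons_rows[[length(cons_rows) + 1L]] <- data.frame(
      chrom = chrom_names[ci], start = config$chrom_len - 1900L,
      end = config$chrom_len - 1600L, score = -1, stringsAsFactors = FALSE)
  }

  gene_models <- do.call(rbind, gene_rows)
  known <- do.call(rbind, known_rows)
  novel <- if (length(novel_rows)) do.call(rbind, novel_rows) else NULL
  pseudo <- if (length(pseudo_rows)) do.call(rbind, pseudo_rows) else NULL

  # every planted peptide must occur at exactly one genomic locus
  cols <- c("chrom", "strand", "start", "end")
  planted <- rbind(known[, cols],
                   if (!is.null(novel)) novel[, cols],
                   if (!is.null(pseudo)) pseudo[, cols])
  for (i in seq_len(nrow(planted))) {
    dna <- extract_genomic(genome, planted$chrom[i], planted$start[i],
                           planted$end[i], planted$strand[i])
    n_hits <- sum(vapply(genome, function(s) {
      Biostrings::countPattern(dna, Biostrings::DNAString(s)) +
        Biostrings::countPattern(revcomp(dna), Biostrings::DNAString(s))
    }, numeric(1)))
    if (n_hits != 1L) stop("planted peptide DNA is not unique in the genome")
  }

  reference <- data.frame(
    accession = paste0("REF_", vapply(genes, `[[`, character(1), "gene_id")),
    gene_id = vapply(genes, `[[`, character(1), "gene_id"),
    aa = vapply(genes, `[[`, character(1), "protein"),
    is_decoy = FALSE, stringsAsFactors = FALSE)

  # pseudogene cDNA records: planted region plus flank, same strand
  pseudogenes <- character(0)
  if (!is.null(pseudo)) {
    for (i in seq_len(nrow(pseudo))) {
      s <- extract_genomic(genome, pseudo$chrom[i],
                           max(1L, pseudo$orf_start[i] - 15L),
                           pseudo$orf_end[i] + 15L, pseudo$strand[i])
      pseudogenes[sprintf("PSEUDO%02d", i)] <- s
    }
  }
  pseudogenes["PSEUDO_UNRELATED"] <- random_dna(300L)

  # EST support: spliced cDNA of the first two genes + the first novel locus
  ests <- character(0)
  for (i in 1:2) {
    gm_g <- gene_models[gene_models$gene_id == genes[[i]]$gene_id, ]
    gm_g <- gm_g[order(gm_g$exon_rank), ]
    cdna <- paste(vapply(seq_len(nrow(gm_g)), function(e)
      extract_genomic(genome, gm_g$chrom[e], gm_g$start[e], gm_g$end[e],
                      if (gm_g$strand[e] == "+") 1L else -1L), character(1)),
      collapse = "")
    ests[sprintf("EST_%s", genes[[i]]$gene_id)] <- cdna
  }
  if (!is.null(novel) && nrow(novel)) {
    ests["EST_NOVEL1"] <- extract_genomic(genome, novel$chrom[1L],
                                          novel$orf_start[1L] - 10L,
                                          novel$orf_end[1L] + 10L,
                                          novel$strand[1L])
  }

  repeats_df <- do.call(rbind, repeat_rows)
  repeats <- GenomicRanges::GRanges(
    repeats_df$chrom, IRanges::IRanges(repeats_df$start, repeats_df$end))
  cons_df <- do.call(rbind, cons_rows)
  conservation <- GenomicRanges::GRanges(
    cons_df$chrom, IRanges::IRanges(cons_df$start, cons_df$end),
    score = cons_df$score)

  manifest <- list(
    config = config, known_peptides = known, novel_peptides = novel,
    pseudogene_peptides = pseudo, repeats = repeats_df,
    conservation_design = cons_df
  )
  list(genome = genome, gene_models = gene_models, reference = reference,
       pseudogenes = pseudogenes, ests = ests, repeats = repeats,
       conservation = conservation, manifest = manifest)
}

write_fixture <- function(fx, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(fx$genome),
                              p("genome.fa"), width = 60L)
  write_gene_models(fx$gene_models, p("genes.gtf"))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(stats::setNames(fx$reference$aa,
                                            fx$reference$accession)),
    p("reference_proteins.fa"), width = 60L)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(fx$pseudogenes),
                              p("pseudogenes.fa"), width = 60L)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(fx$ests),
                              p("ests.fa"), width = 60L)
  rtracklayer::export(fx$repeats, p("repeats.bed"), format = "BED")
  rtracklayer::export(fx$conservation, p("conservation.bedGraph"),
                      format = "bedGraph")
  jsonlite::write_json(fx$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", na = "null")
  invisible(out_dir)
}

#' Simulate MS/MS spectra for a set of peptides
#'
#' Each peptide yields one spectrum containing its full singly charged b/y
#' ladder with random intensities, plus uniform noise peaks; with
#' probability `chimera_rate` the ladder of a second, randomly chosen
#' peptide is merged in (a chimeric spectrum). Precursor m/z is computed
#' from the peptide mass and charge.
#'
#' @param peptides character vector of peptide sequences.
#' @param charge precursor charge applied to all spectra (default 2).
#' @param n_noise_peaks noise peaks per spectrum (default 20).
#' @param chimera_rate fraction of spectra receiving a second ladder.
#' @param seed integer seed.
#' @param mods fixed-modification configuration.
#' @param prefix spectrum id prefix.
#' @return named list of [spectrum()] objects (ids encode the true peptide).
#' @export
spectra_from_peptides <- function(peptides, charge = 2L, n_noise_peaks = 20L,
                                  chimera_rate = 0, seed = 1L,
                                  mods = itraq_mmts(), prefix = "sim") {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out <- vector("list", length(peptides))
  for (i in seq_along(peptides)) {
    ions <- theoretical_ions(peptides[i], mods)
    mz <- unname(ions)
    intensity <- runif(length(mz), 200, 1000)
    if (n_noise_peaks > 0L) {
      mz <- c(mz, runif(n_noise_peaks, 150, 1600))
      intensity <- c(intensity, runif(n_noise_peaks, 10, 100))
    }
    if (chimera_rate > 0 && length(peptides) > 1L &&
        runif(1L) < chimera_rate) {
      j <- sample(setdiff(seq_along(peptides), i), 1L)
      jons <- unname(theoretical_ions(peptides[j], mods))
      mz <- c(mz, jons)
      intensity <- c(intensity, runif(length(jons), 100, 400))
    }
    out[[i]] <- spectrum(sprintf("%s_%04d_%s", prefix, i, peptides[i]),
                         precursor_mz(peptides[i], charge, mods),
                         cbind(mz, intensity), charge)
  }
  stats::setNames(out, vapply(out, `[[`, character(1), "id"))
}

#' Simulate pure-noise spectra
#'
#' Spectra with uniformly distributed peaks and random precursors, carrying
#' no planted peptide; used for empirical-null pools and FDR calibration.
#'
#' @param n number of spectra.
#' @param n_peaks peaks per spectrum.
#' @param charge precursor charge.
#' @param mass_range neutral-mass range the random precursors span (Da).
#' @param seed integer seed.
#' @param prefix spectrum id prefix.
#' @return named list of [spectrum()] objects.
#' @export
noise_spectra <- function(n, n_peaks = 60L, charge = 2L,
                          mass_range = c(900, 2200), seed = 1L,
                          prefix = "noise") {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    m <- runif(1L, mass_range[1L], mass_range[2L])
    mz <- runif(n_peaks, 150, 1600)
    out[[i]] <- spectrum(sprintf("%s_%04d", prefix, i),
                         (m + charge * PROTON_MASS) / charge,
                         cbind(mz, runif(n_peaks, 10, 300)), charge)
  }
  stats::setNames(out, vapply(out, `[[`, character(1), "id"))
}
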