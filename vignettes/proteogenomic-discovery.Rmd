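---
title: "Discovering protein-coding regions from MS/MS data with sixframer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering protein-coding regions from MS/MS data with sixframer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Conventional peptide identification searches tandem mass spectra against a
database of known proteins, so it can never report a peptide that is absent
from that database. `sixframer` implements the complementary discovery
strategy: translate the *entire* genome in all six reading frames, search
the spectra against that vastly larger database of putative proteins, and
then use genome annotation, sequence-conservation and spectral validation to
separate genuine novel coding regions from the flood of chance matches that
a database this large inevitably produces.

The pipeline has six stages, each exposed as ordinary functions:

1. **Database construction** (`translate_six_frame`, `make_decoy`,
   `build_junction_db`): every stop-to-stop segment of every frame on both
   strands becomes a putative protein whose genomic coordinates travel with
   it in its FASTA header. Segments shorter than six residues, or containing
   neither lysine nor arginine (and therefore unable to yield a tryptic
   peptide), are dropped. A reversed-sequence decoy of equal size
   accompanies every target database. Because linear genomic translation
   cannot represent peptides spanning splice junctions, an exon-junction
   database is built from the gene models: the 3' end (up to 54 nt) of each
   donor-eligible exon is concatenated with the 5' end of each
   acceptor-eligible exon of the same gene and translated in three frames.
2. **Search** (`digest`, `theoretical_ions`, `match_score`,
   `search_spectra`): in-silico tryptic digestion (cleavage after K/R except
   before P, one missed cleavage by default), singly charged b/y fragment
   ladders with fixed MMTS (+45.98772 Da on C) and 4-plex isobaric label
   (+144.10207 Da on K and the N-terminus) modifications, and a
   peptide-spectrum matcher in which all database peptides within the
   precursor-mass window — targets and decoys alike — compete and the single
   best match per spectrum is kept.
3. **Two-stage target/decoy control** (`prescreen`,
   `build_amalgamated_db`, `compute_fdr`): the spectra are first searched
   per chromosome (the pre-screen), keeping high-confidence target hits and
   *all* decoy hits; the surviving entries are then pooled with the
   reference proteome into one amalgamated database and every spectrum is
   re-searched so that candidates from different chromosomes, the reference
   and the decoys compete directly. The FDR is estimated as
   `100 * decoys / targets` among accepted identifications.
4. **Orphan identification and mapping** (`identify_orphans`,
   `map_peptide_locus`, `classify_locus`): peptides found only by the
   six-frame search are mapped back to the genome through their parent
   entry's coordinates (3 nt per residue from the recorded offset) and
   classified against the annotation as intergenic, intronic, exonic
   in-frame / not-in-frame, or exon-extending; peptides matching multiple
   loci, or matching the reference below the confidence threshold, are
   excluded with a logged reason.
5. **Annotation filters** (`exact_dna_filter`, `repeat_overlap`,
   `conservation_sigma`, `choose_sigma_cutoff`): candidates whose coding DNA
   occurs verbatim (same strand, full length) in a pseudogene cDNA set are
   removed, as are candidates overlapping repeat intervals; per-base
   substitution-deficit conservation scores are averaged over each locus
   (absent positions counting 0) and candidates below the cutoff (default
   0) are removed. EST evidence is reported as a support column but never
   excludes a candidate: transcript-evidence databases are biased toward
   already-characterised regions and would reject genuine novelty.
6. **Spectral validation** (`common_ion_score`, `build_null`,
   `empirical_fdr`): candidates are compared with spectra of synthetic
   peptides of the same sequence by counting common ions above m/z 160
   (excluding isobaric-reporter and ammonium ions), and the score's chance
   behaviour is estimated from repeated draws of unrelated spectra scored
   against the same references; the FDR at a score threshold is the
   null-to-real tail ratio, made monotone by a running minimum.

## A worked example

```{r, eval = FALSE}
library(sixframer)

fx <- generate_fixture(fixture_config(), seed = 1)
peps <- c(fx$manifest$known_peptides$pep,
          fx$manifest$novel_peptides$pep,
          fx$manifest$pseudogene_peptides$pep)
spectra <- c(spectra_from_peptides(peps, n_noise_peaks = 20,
                                   chimera_rate = 0.1, seed = 2),
             noise_spectra(30, seed = 3))
res <- run_discovery_pipeline(fx, spectra)
res$funnel
res$candidates[, c("pep", "label", "sigma", "pseudogene_fail", "pass")]
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_len` | 6 aa | shortest six-frame segment kept |
| `require_kr` | `TRUE` | drop segments that cannot yield a tryptic peptide |
| `end_len` | 54 nt | exon end length in the junction database |
| `tol_prec` | 0.5 Da | precursor mass window of the search |
| `tol_frag` | 0.2 Th | fragment/peak matching tolerance |
| `missed` | 1 | missed cleavages in the digest |
| `confidence_min` | 0.95 | identification acceptance threshold |
| `sigma_cutoff` | 0 | conservation survival threshold |
| `min_mz` | 160 Th | low-mass floor of the common-ion score |
| `n_reps`, `set_size` | 7000, 10 | null-distribution sampling design |

The tolerances are appropriate for quadrupole/time-of-flight data; both are
configurable everywhere they appear. The confidence scale itself is a
declared logistic calibration of the shared-ion fraction
(`plogis(12 * (fraction - 0.5))`): the commercial engine that produced the
original identifications is closed and irreproducible, so this package
implements the same *contract* — competitive best-per-spectrum assignment
with a monotone confidence in [0, 1] — with an open scorer, and makes no
claim that its confidence values are numerically equivalent to any
commercial engine's. Externally produced PSM tables can be imported with
`read_psms()` to bypass the built-in matcher entirely.

## Design decisions

**Peak matching is optimal, not nearest-first.** Matching two peak lists
under a symmetric tolerance is a maximum-cardinality matching problem on an
interval bigraph. A "nearest pair first" greedy can strand peaks (ions
{0, 1} against peaks {0.6, 1.59} at tolerance 1 pair only once, though two
pairs exist), so `sixframer` uses the ascending two-pointer greedy, which
provably attains the maximum for equal-width windows; the tests verify
equality with an independent maximum-matching oracle on random instances.

**Ambiguity codons terminate segments.** A codon containing an IUPAC
ambiguity letter cannot be translated reliably. Skipping it would emit an
amino-acid sequence spanning a genomic gap while claiming contiguous
coordinates, so by default such codons end the current segment exactly as a
stop codon does; a `skip` mode exists and flags affected entries as
non-contiguous.

**Junction pairing is all donors x all acceptors per gene.** This captures
annotated junctions, exon skipping and alternative junction use in one
sweep; a within-transcript mode is available. A 5'-terminal exon
contributes only its 3' end and a 3'-terminal exon only its 5' end.

**The in-frame test is positional.** A peptide is exonic-in-frame only if
it lies on the exon's strand and starts on a codon boundary of the exon's
annotated reading frame. Sequence containment alone would misclassify
repeated subsequences.

**Orphan exclusion order.** Multi-locus peptides are set aside first, then
peptides with low-confidence reference matches; each exclusion carries its
reason so the funnel buckets partition the input exactly.

**FDR estimator.** `FP ~ decoys`, `FP + TP ~ targets`
(`100 * D / T`); the concatenated-set variant `100 * 2D / (T + D)` is
available by flag. The estimate is only guaranteed monotone in the
threshold when decoy scores do not dominate target scores, which is the
regime in which the estimator is meaningful; the property tests generate
that regime explicitly.

**Validation FDR.** The two-sample tail ratio (an empirical-null argument)
is the default realisation of "FDR from a null distribution"; a pure
null-tail percentile mode is available. The curve is monotonised by a
running minimum, i.e. each threshold is credited with the best raw FDR
achievable at or below it.

## What the synthetic fixtures emulate — and what they do not

`generate_fixture()` builds, deterministically from one seed: two 50-kb
chromosomes; ten three-exon genes (both strands, non-codon-aligned exon
boundaries, so CDS phases 0/1/2 all occur), each carrying one known tryptic
peptide inside exon 1; five novel ORF cassettes — intergenic (both
strands), intronic, exonic-not-in-frame (one base out of phase inside an
exon) and exonic-3'-extending (26 nt inside the terminal exon, 10 nt
beyond it); three pseudogene plants whose loci are copied into the
pseudogene cDNA set; repeat intervals and conservation planted at +2 over
novel ORFs, -1 over background windows and absent elsewhere, so the
`sigma >= 0` cutoff separates the classes by construction. Every planted
peptide is verified to occur at exactly one genomic locus. Spectra carry
the full b/y ladder with random intensities, uniform noise peaks and
optionally a second peptide's ladder (chimeric spectra).

The fixtures do **not** emulate realistic fragment-intensity models,
isotope envelopes, retention time, post-translational modifications, or the
sheer scale of a real genome; passing tests therefore demonstrate the
correctness of the pipeline's logic and arithmetic, not identification
performance on real instrument data. In particular, the planted spectra
contain their complete theoretical ladders, so near-perfect recovery is
expected by construction.

The decoy-calibration check accepts identifications at a deliberately low
confidence working point (0.02) so that chance matches are actually
accepted and both the decoy-estimated and the realised false-match rate are
nonzero; at stringent thresholds both are zero on these clean fixtures and
the comparison would be vacuous.

## Problem sizes

The test suite and the acceptance script run the full pipeline on the
default two-chromosome, 50-kb-per-chromosome fixture (about 6,000 six-frame
entries per chromosome before decoys, roughly 50 spectra), the
oracle-equivalence checks on sequences up to 10 kb, and the decoy
calibration on 520 spectra against a 20-kb single-chromosome database.
These sizes exercise every code path in minutes on a single core; all of
them scale linearly with sequence length and spectrum count.

## Known limitations

* Six-frame entries are linear genomic peptides; spliced peptides are
  handled only through the junction database, not by split intervals.
* Protein-level inference, PTM discovery, isobaric-reporter quantification
  and q-value/posterior error estimation are out of scope.
* The pseudogene/EST matcher scans contiguous reference records; a match
  spanning two records would be missed (none arise here).
* `compute_fdr` is a point estimate; no uncertainty is attached.
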