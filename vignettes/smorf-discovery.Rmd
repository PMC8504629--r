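---
title: "Methods: discovery and classification of translated smORFs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovery and classification of translated smORFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the computational model behind `smorfkit`: what each
stage computes, the coordinate conventions, the default parameters and why
they have the values they do, and the design of the synthetic data generator
used to validate the pipeline.

## Problem statement

Small open reading frames (smORFs, here at most 100 codons) are
systematically under-annotated: they occur by chance in any transcript
sequence, so sequence alone cannot distinguish a translated smORF from noise.
Ribosome profiling (Ribo-Seq) resolves this: ribosome-protected fragments
(RPFs) place elongating ribosomes on the transcriptome with sub-codon
precision. A genuinely translated ORF shows three diagnostic signals:

1. **Triplet periodicity** — P-sites (the ribosomal decoding position within
   each footprint) fall predominantly on the first nucleotide of each codon
   of the translated frame.
2. **Sustained coverage** — P-sites appear along the full ORF body, not just
   at one hot spot.
3. **Termination** — footprint density drops sharply after the stop codon,
   because ribosomes are released there.

The pipeline turns these signals into per-ORF scores and applies a filter
cascade, yielding a non-redundant set of confidently translated smORFs.

## Coordinate conventions

All genomic intervals are **0-based, half-open**, stored as integer matrices
with columns `start`, `end`, rows in ascending genomic order. Transcript
coordinates are 0-based offsets into the spliced sequence, read 5'→3' in
transcript orientation (minus-strand transcripts are reverse-complemented on
extraction). GTF input (1-based, closed) is converted on read; `stop_codon`
records are merged into the CDS, so a CDS interval always includes its stop
codon. ORF intervals `[tx_start, tx_end)` likewise include the stop codon;
`length_codons` excludes it.

## Stage 1: ORF scanning

`scan_orfs_in_sequence()` enumerates maximal ORFs in all three reading frames
of the spliced sequence:

* an ORF runs from a permitted start codon (default `ATG`) to the next
  in-frame stop codon (`TAA`, `TAG`, `TGA`); ORFs without an in-frame stop
  are not reported;
* per (frame, stop) pair only the **5'-most** qualifying start is reported
  (the first-start rule); downstream in-frame starts sharing the stop are
  recorded as `alt_starts`, not emitted as separate ORFs;
* length bounds (default 5–100 codons, stop excluded) apply to the reported
  ORF.

The scanner is validated against an exhaustive oracle that tests every
(frame, stop, start) combination on random kilobase sequences
(`tests/testthat/test-acceptance.R`).

`scan_transcripts()` runs the scanner on every transcript, projects each ORF
through the exon structure to genomic blocks (`project_to_genome()`, itself
checked against a per-base mapping oracle), and translates it with the
standard genetic code. Transcripts with more than 10 % ambiguous bases are
skipped with a warning.

## Stage 2: positional classification

`classify_orf()` places each ORF relative to the annotated CDS of its host
transcript (both in transcript coordinates, CDS including its stop):

| class                 | definition                                             |
|-----------------------|--------------------------------------------------------|
| `canonical`           | identical to the CDS                                   |
| `canonical_extended`  | same stop, start upstream of the CDS start             |
| `canonical_truncated` | same stop, start downstream (in-frame by construction) |
| `nuORF`               | entirely upstream of the CDS start                     |
| `ouORF`               | starts upstream, ends at/inside the CDS, different stop|
| `ndORF`               | entirely downstream of the CDS end                     |
| `odORF`               | starts inside the CDS, ends past its end               |
| `ncORF`               | host transcript has no CDS                             |
| `internal`            | fully inside the CDS, different stop — **discarded**   |

`internal` ORFs are discarded because in-frame they are indistinguishable
from the host CDS signal and out-of-frame their metrics are dominated by the
overlapping frame. A transcript with a CDS but a non-coding biotype is
classified by CDS presence, with a warning.

## Stage 3: P-site calibration

RPF 5' ends sit a fixed distance upstream of the P-site, but that distance
depends on read length (and library chemistry), so it is estimated from the
data. For each candidate read length (default 25–34 nt),
`metagene_offsets()`:

1. histograms read 5' ends relative to annotated start codons of
   protein-coding transcripts over a window of −40…+20 nt;
2. takes the offset as the negated position of the tallest upstream peak —
   initiating ribosomes pause with the start codon in the P-site, producing
   that peak;
3. rejects the read length if fewer than 100 reads were usable (too sparse
   to calibrate) or if, after applying the offset, fewer than 50 % of CDS
   P-sites fall in frame 0 (offset does not capture real periodicity).

`build_psite_track()` then walks each accepted read's offset along its
CIGAR-aware reference blocks in transcript orientation (minus-strand reads
from their rightmost base), producing a strand-aware P-site count track.
Junction-spanning reads are handled exactly; reads of rejected lengths are
dropped but still count toward the library size.

## Stage 4: translation metrics

With `F1, F2, F3` the P-site counts in the three frames of the ORF
(frame 1 = the ORF's own frame), over **interior** codons only (first and
last codon excluded, to avoid initiation/termination pauses):

* **ORFScore** = `log2(1 + Σ (Fi − F̄)² / F̄)`, negated when an off-frame
  count exceeds the in-frame count. Before summing, codons whose total count
  exceeds the 97.5th percentile of per-codon totals within the ORF are
  scaled down to that percentile, so single-position pile-ups cannot fake
  periodicity.
* **Codon coverage** = fraction of interior codons with ≥ 1 frame-0 P-site.
* **Ribosome release score (RRS)** = (RPF density in ORF / RPF density
  downstream) ÷ (RNA-Seq density in ORF / RNA-Seq density downstream), with
  a pseudocount of 1 on every raw count. The downstream region runs from the
  stop to `min(stop + 150, transcript end)`. Two refinements:
  * for upstream-type ORFs (start 5' of the CDS start, stop not shared with
    the CDS) the region is additionally capped at the CDS start — the main
    CDS is itself translated, and its footprints would mask release. When
    the capped region is empty the RRS is reported `NA` and its filter is
    skipped rather than failing the ORF.
  * the RNA densities use a **per-base coverage** track rather than 5'-end
    counts: 5' ends are structurally absent from the final read-length of a
    transcript, which would inflate the RNA ratio for 3'-terminal ORFs.
    RPF densities use P-sites, which do not suffer this edge effect.
* **FPKM** = `count × 10⁹ / (length × library size)`; RNA FPKM uses RNA
  5'-end counts (one count per read, unambiguous assignment).
* **TE** (translation efficiency) = RPF FPKM / RNA FPKM, `NA` when the RNA
  FPKM is 0.

## Stage 5: filter cascade and collapse

Filters are applied as a conjunction; each ORF is charged to the first stage
it fails (reported in `stage_counts`):

| filter               | default | rationale                                    |
|----------------------|---------|----------------------------------------------|
| host RNA FPKM        | ≥ 1     | the transcript must be detectably expressed  |
| codon coverage       | ≥ 0.5   | translation along the body, not a hot spot   |
| ORFScore             | ≥ 6     | strong triplet periodicity                   |
| RRS                  | ≥ 5     | ribosomes released at the stop (skipped when `NA`) |

Survivors are classified, then `collapse_unique()`:

1. merges records with identical genomic blocks (the same ORF seen on
   several isoforms) into one record listing all hosts; the retained class
   follows the precedence `canonical > canonical_extended >
   canonical_truncated > ouORF > nuORF > odORF > ndORF > ncORF`;
2. discards `internal` records;
3. removes any ORF whose genomic codon-start positions are a strict subset
   of another retained ORF's — a nested, in-frame sub-ORF (typically exposed
   by a truncated isoform) is evidence of the longer ORF, not of an
   independent one.

Outputs: a BED12+ table (standard 12 columns plus class, hosts, metrics and
the peptide as column 25), a per-ORF metrics TSV, the class composition, the
offset table and a JSON run report echoing every effective parameter.

## The synthetic world

`make_world()` builds a fully self-contained validation dataset — genome
FASTA, GTF, coordinate-sorted RPF/RNA BAMs and a ground-truth manifest —
from a single seed. Design principles:

* **Known ORF sets by construction.** All background sequence is scrubbed of
  `ATG` trigrams (the `T` is replaced by `C`, a substitution that can create
  neither a new start nor a stop codon), and planted ORF stops are
  restricted to `TAA`/`TAG` so scrubbing can never touch them. Every ORF the
  scanner should find is therefore planted deliberately, and the scanner's
  output can be compared against the manifest *exactly*.
* **All eight classes planted**, on both strands, on spliced multi-exon
  transcripts, including the overlap classes (`ouORF`/`odORF`) whose CDS
  head/tail codons are hand-designed so the overlapping frames read through
  cleanly.
* **An isoform pair** sharing one ORF on a common exon (exercises the
  isoform merge) and a **nested trap**: a long ORF with an internal in-frame
  ATG, plus a shorter isoform that exposes the internal ATG as its own ORF
  (exercises nested removal). The nested ORF is 40 codons — the same length
  scale as the other planted smORFs — so it reliably survives the score
  filters and reaches the collapse stage it is designed to test.
* **Untranslated decoys** receive either no footprints or uniform,
  non-periodic read-through signal spilling past the stop — the failure mode
  the ORFScore and RRS filters are designed to reject.

Study conditions (generator defaults, fixed before evaluation): mean P-site
depth 4 per codon; frame fidelity 0.85 (off-frame P-sites at ±1 nt); read
lengths 28 and 30 nt with true 5' offsets 12 and 13; a 3× initiation pause
on the first codon; RNA coverage 10× at abundance 1 with a 1/2/4 abundance
ladder on three decoys; TE multipliers 0.75/1/1.5 across transcripts. Reads
are emitted as SAM text and converted to BAM, so the entire world is
reproducible byte-for-byte from the seed.

`simulate_orf_signal()` is a lightweight companion that generates frame and
region counts for a single ORF (terminating-periodic or read-through), used
to measure score discrimination (AUROC) over many replicates.

## Determinism

Given identical inputs and parameters the pipeline is fully deterministic —
there is no sampling anywhere in the discovery path — and `make_world()` is
deterministic given its seed. Both properties are asserted byte-for-byte in
the acceptance tests.

## Limitations

* Genomes are held in memory as R strings; the package targets toy- to
  small-genome scales (validation worlds, bacteria, compact eukaryotes),
  not mammalian whole-genome runs.
* Uniqueness of mapping is approximated by a MAPQ threshold (default ≥ 10).
* Only `ATG` starts are scanned by default; near-cognate starts can be
  enabled via `start_codons` but share the same first-start rule.
* The conservation column in the BED12+ output is a placeholder (`NA`);
  no phylogenetic scoring is implemented.
* RNA-Seq is treated as unstranded-protocol-free: reads are counted on
  their aligned strand.

## Worked example

```{r example}
library(smorfkit)

world <- make_world("world", seed = 1)
res <- run_smorf_pipeline(world$paths$genome, world$paths$gtf,
                          world$paths$ribo_bam, world$paths$rna_bam,
                          out_dir = "results")
print(res)
tidy(res)      # one row per unique smORF
glance(res)    # one-row run summary
autoplot(res, type = "composition")
```
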