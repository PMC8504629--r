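# Translation-evidence metrics: ORFScore (triplet-periodicity bias), codon
# coverage, ribosome release score, FPKM and translation efficiency.

#' ORFScore: log2-scaled frame-bias statistic
#'
#' A chi-square-style statistic on P-site counts by reading frame,
#' `log2(1 + sum_i (F_i - Fbar)^2 / Fbar)` with `Fbar = (F1+F2+F3)/3`,
#' negated when frame 1 does not hold the maximum. All-zero counts score 0.
#'
#' @param frame_counts numeric vector `c(F1, F2, F3)` of P-site counts in the
#'   three frames (frame 1 = the ORF's own reading frame).
#' @return signed real score.
#' @export
orf_score <- function(frame_counts) {
  stopifnot(length(frame_counts) == 3L)
  if (any(frame_counts < 0)) abort("negative frame counts")
  tot <- sum(frame_counts)
  if (tot == 0) return(0)
  fbar <- tot / 3
  s <- log2(1 + sum((frame_counts - fbar)^2 / fbar))
  if (frame_counts[2] > frame_counts[1] || frame_counts[3] > frame_counts[1]) -s else s
}

# Per-codon P-site counts for an ORF: a matrix codons x 3 frames, first and
# last codon rows included (callers exclude them as needed).
orf_codon_counts <- function(blocks, strand, chrom, track) {
  pos <- blocks_tx_order_positions(blocks, strand)
  stopifnot(length(pos) %% 3L == 0L)
  counts <- track_counts(track, chrom, strand, pos)
  matrix(counts, ncol = 3L, byrow = TRUE)
}

#' Frame counts for an ORF with peak capping
#'
#' Sums P-site counts by frame over the interior codons (first and last codon
#' excluded). Codons whose total count exceeds the 97.5th percentile of
#' per-codon totals within the ORF are scaled down to that percentile, so
#' initiation/termination pauses and single-position pile-ups cannot dominate
#' the frame statistic.
#'
#' @param blocks genomic block matrix of the ORF.
#' @param strand,chrom location of the ORF.
#' @param track P-site track.
#' @return numeric vector `c(F1, F2, F3)`.
#' @export
orf_frame_counts <- function(blocks, strand, chrom, track) {
  m <- orf_codon_counts(blocks, strand, chrom, track)
  n <- nrow(m)
  if (n <= 2L) return(c(0, 0, 0))
  m <- m[2:(n - 1L), , drop = FALSE]
  tot <- rowSums(m)
  cap <- quantile(tot, 0.975, names = FALSE)
  over <- tot > cap & tot > 0
  if (any(over)) m[over, ] <- m[over, , drop = FALSE] * (cap / tot[over])
  colSums(m)
}

#' Fraction of interior codons with in-frame P-site signal
#'
#' @inheritParams orf_frame_counts
#' @return fraction in `[0, 1]` of interior codons (first and last excluded)
#'   whose frame-0 position carries at least one P-site.
#' @export
codon_coverage <- function(blocks, strand, chrom, track) {
  m <- orf_codon_counts(blocks, strand, chrom, track)
  n <- nrow(m)
  if (n < 1L) abort("zero-length ORF")
  if (n <= 2L) return(0)
  mean(m[2:(n - 1L), 1] >= 1L)
}

#' Ribosome release score
#'
#' Ratio of RPF density inside the ORF to RPF density downstream of its stop
#' codon, normalised by the same ratio in RNA-Seq coverage. A pseudocount of 1
#' is added to each raw count so the score stays finite on sparse data. High
#' values indicate that ribosomes are released at the stop codon.
#'
#' @param rpf_orf,rpf_down raw RPF P-site counts in the ORF and downstream
#'   region.
#' @param rna_orf,rna_down raw RNA-Seq counts in the same regions.
#' @param len_orf,len_down region lengths in nt (`len_down` > 0).
#' @return positive real score, or `NA` when `len_down` is zero.
#' @export
rrs <- function(rpf_orf, rpf_down, rna_orf, rna_down, len_orf, len_down) {
  if (is.na(len_down) || len_down <= 0) return(NA_real_)
  rpf_ratio <- ((rpf_orf + 1) / len_orf) / ((rpf_down + 1) / len_down)
  rna_ratio <- ((rna_orf + 1) / len_orf) / ((rna_down + 1) / len_down)
  rpf_ratio / rna_ratio
}

#' Fragments per kilobase per million mapped reads
#'
#' @param count read (or P-site) count on the feature.
#' @param feature_len feature length in nt (> 0).
#' @param library_size total mapped reads in the library (> 0).
#' @return FPKM value.
#' @export
fpkm <- function(count, feature_len, library_size) {
  if (any(feature_len <= 0)) abort("zero-length feature")
  if (any(library_size <= 0)) abort("library size must be positive")
  count * 1e9 / (feature_len * library_size)
}

#' Translation efficiency
#'
#' @param rpf_fpkm,rna_fpkm FPKM of ribosome footprints and RNA-Seq reads on
#'   the same feature.
#' @return `rpf_fpkm / rna_fpkm`, or `NA` when `rna_fpkm` is 0.
#' @export
translation_efficiency <- function(rpf_fpkm, rna_fpkm) {
  ifelse(rna_fpkm > 0, rpf_fpkm / rna_fpkm, NA_real_)
}

# Raw count of track signal within a block set (all frames).
blocks_track_count <- function(blocks, strand, chrom, track) {
  pos <- blocks_tx_order_positions(blocks, strand)
  sum(track_counts(track, chrom, strand, pos))
}

#' Score scanned ORFs against RPF and RNA tracks
#'
#' Computes, per ORF row: frame counts and ORFScore, interior codon coverage,
#' RPF and RNA FPKM (P-site and RNA 5'-end counts over the ORF blocks), TE,
#' and the ribosome release score. The RRS downstream region runs from the
#' ORF stop to `min(cds_start, stop + downstream_window, transcript end)` for
#' upstream-type ORFs (start 5' of the annotated CDS start, stop not shared
#' with the CDS), and to `min(stop + downstream_window, transcript end)`
#' otherwise; when the region is empty the RRS is reported missing.
#'
#' @param orfs tibble from [scan_transcripts()] (one row per ORF-transcript
#'   pair).
#' @param transcripts transcript tibble (for exon structures and CDS spans).
#' @param rpf_track P-site track from [build_psite_track()].
#' @param rna_track RNA 5'-end track from [build_end_track()] (FPKM/TE
#'   counting).
#' @param rna_cov_track RNA per-base coverage track from
#'   [build_coverage_track()], used for the RNA densities in the RRS;
#'   defaults to `rna_track`.
#' @param downstream_window maximum downstream-region length in nt
#'   (default 150).
#' @return `orfs` with columns `frame_counts` (list), `orf_score`, `coverage`,
#'   `rpf_count`, `rna_count`, `rpf_fpkm`, `rna_fpkm`, `te`, `rrs` added.
#' @export
score_orfs <- function(orfs, transcripts, rpf_track, rna_track,
                       rna_cov_track = rna_track,
                       downstream_window = 150L) {
  rpf_lib <- attr(rpf_track, "library_size")
  rna_lib <- attr(rna_track, "library_size")
  tx_index <- setNames(seq_len(nrow(transcripts)), transcripts$transcript_id)
  spans <- lapply(seq_len(nrow(transcripts)), function(i) cds_tx_span(transcripts[i, ]))

  res <- lapply(seq_len(nrow(orfs)), function(i) {
    b <- orfs$blocks[[i]]
    chrom <- orfs$chrom[i]; strand <- orfs$strand[i]
    fc <- orf_frame_counts(b, strand, chrom, rpf_track)
    cov <- codon_coverage(b, strand, chrom, rpf_track)
    rpf_n <- blocks_track_count(b, strand, chrom, rpf_track)
    rna_n <- blocks_track_count(b, strand, chrom, rna_track)
    len <- block_width(b)
    rpf_f <- fpkm(rpf_n, len, rpf_lib)
    rna_f <- fpkm(rna_n, len, rna_lib)

    ti <- tx_index[[orfs$transcript_id[i]]]
    tx <- transcripts[ti, ]
    Ltx <- block_width(tx$exons[[1]])
    sp <- spans[[ti]]
    stop_pos <- orfs$tx_end[i]
    lim <- min(stop_pos + downstream_window, Ltx)
    # upstream-type ORFs (start 5' of the CDS, not sharing its stop): the main
    # CDS is itself translated and would mask release, so cap at cds_start
    if (!is.null(sp) && orfs$tx_start[i] < sp[1] && stop_pos != sp[2]) {
      lim <- min(lim, sp[1])
    }
    rrs_val <- NA_real_
    if (lim > stop_pos) {
      db <- project_to_genome(tx, c(stop_pos, lim))
      rpf_d <- blocks_track_count(db, strand, chrom, rpf_track)
      rna_c <- blocks_track_count(b, strand, chrom, rna_cov_track)
      rna_d <- blocks_track_count(db, strand, chrom, rna_cov_track)
      rrs_val <- rrs(rpf_n, rpf_d, rna_c, rna_d, len, lim - stop_pos)
    }
    tibble(frame_counts = list(fc), orf_score = orf_score(fc), coverage = cov,
           rpf_count = rpf_n, rna_count = rna_n, rpf_fpkm = rpf_f,
           rna_fpkm = rna_f, te = translation_efficiency(rpf_f, rna_f),
           rrs = rrs_val)
  })
  dplyr::bind_cols(orfs, bind_rows(res))
}
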