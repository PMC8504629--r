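# Alignment reading -----------------------------------------------------

#' Read primary, uniquely-mapping alignments from a BAM file
#'
#' Secondary, supplementary and unmapped records are excluded; uniqueness is
#' enforced through a mapping-quality threshold. Per-read reference blocks
#' (CIGAR-aware, so junction-spanning reads are handled) are returned in
#' ascending genomic order.
#'
#' @param bam path to an indexed BAM file.
#' @param min_mapq minimum mapping quality (default 10).
#' @return tibble: `chrom`, `strand`, `qwidth`, and list-column `blocks`
#'   (0-based half-open reference blocks). Attribute `n_dropped` counts
#'   excluded records.
#' @export
read_alignments <- function(bam, min_mapq = 10L) {
  stopifnot_scalar_path(bam)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("mapq"))
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  n_total <- Rsamtools::countBam(bam)$records
  mapq <- S4Vectors::mcols(gal)$mapq
  ok <- !is.na(mapq) & mapq >= min_mapq
  gal <- gal[ok]
  if (length(gal) == 0L) abort(sprintf("no usable alignments in %s", bam))
  rng <- GenomicAlignments::grglist(gal)
  starts <- as.list(IRanges::start(rng))
  ends <- as.list(IRanges::end(rng))
  blocks <- lapply(seq_along(gal), function(i) {
    block_mat(starts[[i]] - 1L, ends[[i]])
  })
  out <- tibble(
    chrom = as.character(GenomicAlignments::seqnames(gal)),
    strand = as.character(GenomicAlignments::strand(gal)),
    qwidth = GenomicAlignments::qwidth(gal),
    blocks = blocks
  )
  attr(out, "n_dropped") <- n_total - nrow(out)
  out
}

# 5'-end genomic position of each read in transcript orientation.
read_5p_end <- function(reads) {
  vapply(seq_len(nrow(reads)), function(i) {
    b <- reads$blocks[[i]]
    if (reads$strand[i] == "-") b[nrow(b), "end"] - 1L else b[1, "start"]
  }, integer(1))
}

# Walk `offset` reference bases from the 5' end of a read (transcript
# orientation) and return the genomic position reached.
walk_from_5p <- function(blocks, strand, offset) {
  pos <- blocks_tx_order_positions(blocks, strand)
  if (offset >= length(pos)) return(NA_integer_)
  pos[offset + 1L]
}

# Position track --------------------------------------------------------

# A track is a list keyed by "chrom|strand"; each element holds sorted
# integer `pos` and integer `count`. Attributes: n_assigned, library_size.
make_track <- function(chrom, strand, pos, library_size) {
  keep <- !is.na(pos)
  chrom <- chrom[keep]; strand <- strand[keep]; pos <- pos[keep]
  key <- paste(chrom, strand, sep = "|")
  tr <- lapply(split(pos, key), function(p) {
    tb <- table(p)
    list(pos = as.integer(names(tb)), count = as.integer(tb))
  })
  attr(tr, "n_assigned") <- length(pos)
  attr(tr, "library_size") <- library_size
  class(tr) <- "smorf_track"
  tr
}

#' Counts at genomic positions in a track
#'
#' @param track a track from [build_psite_track()] or [build_end_track()].
#' @param chrom,strand location.
#' @param positions integer vector of genomic positions (0-based).
#' @return integer vector of counts (0 where absent).
#' @export
track_counts <- function(track, chrom, strand, positions) {
  el <- track[[paste(chrom, strand, sep = "|")]]
  if (is.null(el)) return(rep(0L, length(positions)))
  idx <- match(positions, el$pos)
  out <- el$count[idx]
  out[is.na(out)] <- 0L
  out
}

#' Total counts in a track
#' @param track a track object.
#' @return integer total (equals the number of assigned reads).
#' @export
track_total <- function(track) {
  sum(vapply(track, function(el) sum(el$count), numeric(1)))
}

# Metagene calibration ---------------------------------------------------

#' Estimate per-read-length P-site offsets from a start-codon metagene
#'
#' For each read length, the 5' ends of reads are histogrammed relative to the
#' annotated start codons of protein-coding transcripts over a window
#' `[-40, +20]` (transcript coordinates). The P-site offset is the negated
#' position of the tallest peak upstream of the start. Read lengths with fewer
#' than `min_reads` usable reads, or whose offset places fewer than
#' `min_frame0_frac` of CDS P-sites in frame 0, are rejected.
#'
#' @param bam RPF BAM path (or a prefetched tibble from [read_alignments()]).
#' @param transcripts transcript tibble; only rows with a CDS whose spliced
#'   length is divisible by 3 are used.
#' @param lengths candidate read lengths (default 25:34 nt).
#' @param min_mapq mapping-quality threshold.
#' @param min_reads minimum usable reads per length (default 100).
#' @param min_frame0_frac minimum frame-0 fraction after offsetting
#'   (default 0.5).
#' @return tibble: `read_length`, `offset`, `n_reads`, `frame0_frac`,
#'   `accepted`. Rows for rejected lengths are retained with
#'   `accepted = FALSE`.
#' @export
metagene_offsets <- function(bam, transcripts, lengths = 25:34,
                             min_mapq = 10L, min_reads = 100L,
                             min_frame0_frac = 0.5) {
  reads <- if (is.data.frame(bam)) bam else read_alignments(bam, min_mapq)
  cal <- transcripts[vapply(seq_len(nrow(transcripts)), function(i) {
    sp <- cds_tx_span(transcripts[i, ])
    !is.null(sp) && (sp[2] - sp[1]) %% 3L == 0L
  }, logical(1)), , drop = FALSE]
  if (nrow(cal) == 0L) abort("no protein-coding transcripts with in-frame CDS for calibration")

  # lookup: genomic position -> (rel position to start codon) per chrom|strand,
  # plus a frame label over the full CDS for the frame-0 check
  rel_key <- character(0); rel_val <- integer(0)
  frame_key <- character(0); frame_val <- integer(0)
  for (i in seq_len(nrow(cal))) {
    tx <- cal[i, ]
    exons <- tx$exons[[1]]
    L <- block_width(exons)
    sp <- cds_tx_span(tx)
    rel <- -40:20
    tpos <- sp[1] + rel
    okt <- tpos >= 0L & tpos < L
    g <- tx_to_genome_pos(exons, tx$strand, tpos[okt])
    rel_key <- c(rel_key, paste(tx$chrom, tx$strand, g, sep = "|"))
    rel_val <- c(rel_val, rel[okt])
    cpos <- seq.int(sp[1], sp[2] - 1L)
    gc_ <- tx_to_genome_pos(exons, tx$strand, cpos)
    frame_key <- c(frame_key, paste(tx$chrom, tx$strand, gc_, sep = "|"))
    frame_val <- c(frame_val, (cpos - sp[1]) %% 3L)
  }
  # overlapping windows from different transcripts: keep first occurrence
  dup <- duplicated(rel_key); rel_key <- rel_key[!dup]; rel_val <- rel_val[!dup]
  dup <- duplicated(frame_key); frame_key <- frame_key[!dup]; frame_val <- frame_val[!dup]

  p5 <- read_5p_end(reads)
  k5 <- paste(reads$chrom, reads$strand, p5, sep = "|")

  res <- lapply(lengths, function(Lr) {
    sel <- reads$qwidth == Lr
    rel <- rel_val[match(k5[sel], rel_key)]
    rel <- rel[!is.na(rel)]
    upstream <- rel[rel < 0L]
    n_use <- length(rel)
    if (n_use < min_reads || length(upstream) == 0L) {
      return(tibble(read_length = Lr, offset = NA_integer_, n_reads = n_use,
                    frame0_frac = NA_real_, accepted = FALSE))
    }
    tb <- table(upstream)
    off <- -as.integer(names(tb)[which.max(tb)])
    # frame distribution of P-sites after applying the offset
    idx <- which(sel)
    psite <- vapply(idx, function(j)
      walk_from_5p(reads$blocks[[j]], reads$strand[j], off), integer(1))
    kk <- paste(reads$chrom[idx], reads$strand[idx], psite, sep = "|")
    fr <- frame_val[match(kk, frame_key)]
    fr <- fr[!is.na(fr)]
    f0 <- if (length(fr) == 0L) 0 else mean(fr == 0L)
    tibble(read_length = Lr, offset = off, n_reads = n_use,
           frame0_frac = f0, accepted = f0 >= min_frame0_frac)
  })
  out <- bind_rows(res)
  rejected <- out$read_length[!out$accepted]
  if (length(rejected) > 0L) {
    inform(sprintf("read lengths rejected during calibration: %s",
                   paste(rejected, collapse = ", ")))
  }
  out
}

#' Build a strand-aware P-site count track
#'
#' Each accepted read contributes one count at the genomic position reached by
#' walking its per-length 5'-end offset along the read's reference blocks in
#' transcript orientation (for minus-strand reads the walk starts from the
#' rightmost base). Reads of rejected lengths are dropped.
#'
#' @param bam RPF BAM path (or a tibble from [read_alignments()]).
#' @param offsets offset table from [metagene_offsets()].
#' @param min_mapq mapping-quality threshold.
#' @return a track object; `attr(, "library_size")` is the number of accepted
#'   primary alignments in the BAM (before length selection) and
#'   `attr(, "n_assigned")` the number of reads contributing P-sites.
#' @export
build_psite_track <- function(bam, offsets, min_mapq = 10L) {
  reads <- if (is.data.frame(bam)) bam else read_alignments(bam, min_mapq)
  acc <- offsets[offsets$accepted, , drop = FALSE]
  if (nrow(acc) == 0L) abort("no accepted read lengths in offset table")
  off <- setNames(acc$offset, acc$read_length)
  library_size <- nrow(reads)
  sel <- as.character(reads$qwidth) %in% names(off)
  reads2 <- reads[sel, , drop = FALSE]
  o <- off[as.character(reads2$qwidth)]
  single <- vapply(reads2$blocks, nrow, integer(1)) == 1L
  pos <- integer(nrow(reads2))
  if (any(single)) {
    b1s <- vapply(reads2$blocks[single], function(b) b[1, "start"], integer(1))
    b1e <- vapply(reads2$blocks[single], function(b) b[1, "end"], integer(1))
    pos[single] <- ifelse(reads2$strand[single] == "-",
                          b1e - 1L - o[single], b1s + o[single])
  }
  for (i in which(!single)) {
    pos[i] <- walk_from_5p(reads2$blocks[[i]], reads2$strand[i], o[i])
  }
  tr <- make_track(reads2$chrom, reads2$strand, pos, library_size)
  attr(tr, "n_dropped_length") <- sum(!sel)
  tr
}

#' Build a 5'-end count track for RNA-Seq reads
#'
#' RNA reads are never offset; each primary alignment contributes one count at
#' its 5'-end genomic position, giving an unambiguous per-read assignment
#' used for FPKM/expression counting.
#'
#' @inheritParams build_psite_track
#' @return a track object.
#' @export
build_end_track <- function(bam, min_mapq = 10L) {
  reads <- if (is.data.frame(bam)) bam else read_alignments(bam, min_mapq)
  make_track(reads$chrom, reads$strand, read_5p_end(reads), nrow(reads))
}

#' Build a per-base coverage track
#'
#' Each read contributes one count at every reference position it covers
#' (strand-aware). Used for the RNA densities in the ribosome release score,
#' where per-base coverage is the appropriate notion of density.
#'
#' @inheritParams build_psite_track
#' @return a track object; `attr(, "library_size")` is the read count.
#' @export
build_coverage_track <- function(bam, min_mapq = 10L) {
  reads <- if (is.data.frame(bam)) bam else read_alignments(bam, min_mapq)
  per_read <- lapply(seq_len(nrow(reads)), function(i) {
    b <- reads$blocks[[i]]
    unlist(lapply(seq_len(nrow(b)), function(k)
      seq.int(b[k, "start"], b[k, "end"] - 1L)), use.names = FALSE)
  })
  n <- lengths(per_read)
  tr <- make_track(rep(reads$chrom, n), rep(reads$strand, n),
                   unlist(per_read, use.names = FALSE), nrow(reads))
  attr(tr, "n_assigned") <- nrow(reads)
  tr
}
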