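STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Scan a spliced sequence for small ORFs
#'
#' Enumerates maximal ORFs in all three reading frames: each ORF runs from the
#' first permitted start codon after the previous in-frame stop to the next
#' in-frame stop codon. ORFs without an in-frame stop before the sequence end
#' are not reported. In-frame downstream start codons before the same stop are
#' recorded as alternative starts, not emitted as separate ORFs, so at most
#' one ORF is reported per (frame, stop) pair.
#'
#' @param seq spliced nucleotide sequence (character scalar, ACGTN).
#' @param min_codons,max_codons inclusive bounds on ORF length in codons,
#'   stop codon excluded. Defaults 5 and 100.
#' @param start_codons permitted start codons (default `"ATG"`).
#' @return tibble with columns `tx_start`, `tx_end` (0-based half-open offsets
#'   into `seq`; `tx_end` is one past the stop codon), `length_codons` (stop
#'   excluded) and list-column `alt_starts` (offsets of in-frame downstream
#'   start codons sharing the stop).
#' @export
scan_orfs_in_sequence <- function(seq, min_codons = 5L, max_codons = 100L,
                                  start_codons = "ATG") {
  stopifnot(min_codons >= 1L)
  seq <- toupper(seq)
  n <- nchar(seq)
  out <- list()
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 2L) next
    starts0 <- f + 3L * (seq_len(ncod) - 1L)          # 0-based codon starts
    codons <- substring(seq, starts0 + 1L, starts0 + 3L)
    is_stop <- codons %in% STOP_CODONS
    is_start <- codons %in% start_codons
    prev_stop <- 0L                                    # codon index (1-based) of last stop
    for (s in which(is_stop)) {
      cand <- which(is_start[seq_len(s - 1L)])
      cand <- cand[cand > prev_stop]
      prev_stop <- s
      if (length(cand) == 0L) next
      k0 <- cand[1]
      len <- s - k0
      if (len < min_codons || len > max_codons) next
      out[[length(out) + 1L]] <- tibble(
        tx_start = starts0[k0], tx_end = starts0[s] + 3L,
        length_codons = len,
        alt_starts = list(starts0[cand[-1]])
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(tx_start = integer(0), tx_end = integer(0),
                  length_codons = integer(0), alt_starts = list()))
  }
  arrange(bind_rows(out), .data$tx_start, .data$tx_end)
}

#' Project a transcript interval onto the genome
#'
#' Maps a 0-based half-open interval in spliced-transcript coordinates through
#' the exon structure to a set of genomic blocks (ascending genomic order).
#'
#' @param transcript one transcript row/list with `exons` and `strand`.
#' @param tx_interval length-2 integer vector `c(start, end)`.
#' @return integer block matrix (columns `start`, `end`).
#' @export
project_to_genome <- function(transcript, tx_interval) {
  tx <- as.list(transcript)
  exons <- if (is.list(tx$exons) && !is.matrix(tx$exons)) tx$exons[[1]] else tx$exons
  a <- tx_interval[1]; b <- tx_interval[2]
  L <- block_width(exons)
  if (a < 0L || b > L || a >= b) {
    abort(sprintf("transcript interval [%d,%d) out of range (length %d)", a, b, L))
  }
  if (tx$strand == "-") { tmp <- a; a <- L - b; b <- L - tmp }
  widths <- exons[, "end"] - exons[, "start"]
  cum <- cumsum(c(0L, widths))
  res_s <- integer(0); res_e <- integer(0)
  for (i in seq_len(nrow(exons))) {
    lo <- max(a, cum[i]); hi <- min(b, cum[i + 1L])
    if (lo < hi) {
      res_s <- c(res_s, exons[i, "start"] + (lo - cum[i]))
      res_e <- c(res_e, exons[i, "start"] + (hi - cum[i]))
    }
  }
  block_mat(res_s, res_e)
}

#' Translate a nucleotide sequence with the standard genetic code
#'
#' The trailing stop codon, if present, is dropped from the peptide. Codons
#' containing characters outside ACGT translate to `X`. An internal stop codon
#' is an error.
#'
#' @param seq nucleotide string with length divisible by 3.
#' @return peptide string.
#' @export
translate_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) abort("sequence length not divisible by 3")
  codons <- substring(seq, seq(1, n, 3), seq(3, n, 3))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  if (length(aa) > 0 && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) abort("internal stop codon in ORF sequence")
  paste(aa, collapse = "")
}

#' Scan transcripts for putative smORFs
#'
#' Runs [scan_orfs_in_sequence()] on the spliced sequence of every transcript,
#' projects each ORF to genomic blocks and attaches its nucleotide and peptide
#' sequence. Transcripts whose spliced sequence contains more than 10%
#' ambiguous bases (N) are skipped with a warning.
#'
#' @param transcripts tibble from [read_gtf()].
#' @param genome named sequence set from [read_genome()].
#' @param min_codons,max_codons,start_codons see [scan_orfs_in_sequence()].
#' @return tibble with one row per (transcript, ORF): transcript metadata,
#'   `tx_start`, `tx_end`, `length_codons`, `alt_starts`, genomic `blocks`
#'   (list-column), `orf_id` (`chrom:start-end:strand` over the genomic span),
#'   `orf_seq` and `peptide`.
#' @export
scan_transcripts <- function(transcripts, genome, min_codons = 5L,
                             max_codons = 100L, start_codons = "ATG") {
  rows <- lapply(seq_len(nrow(transcripts)), function(i) {
    tx <- transcripts[i, ]
    s <- spliced_sequence(tx, genome)
    if (mean(strsplit(s, "")[[1]] == "N") > 0.10) {
      warn(sprintf("skipping transcript %s: >10%% ambiguous bases",
                   tx$transcript_id))
      return(NULL)
    }
    orfs <- scan_orfs_in_sequence(s, min_codons, max_codons, start_codons)
    if (nrow(orfs) == 0L) return(NULL)
    orfs$transcript_id <- tx$transcript_id
    orfs$gene_id <- tx$gene_id
    orfs$chrom <- tx$chrom
    orfs$strand <- tx$strand
    orfs$biotype <- tx$biotype
    orfs$blocks <- lapply(seq_len(nrow(orfs)), function(j) {
      project_to_genome(tx, c(orfs$tx_start[j], orfs$tx_end[j]))
    })
    orfs$orf_seq <- substring(s, orfs$tx_start + 1L, orfs$tx_end)
    orfs$peptide <- vapply(orfs$orf_seq, translate_orf, character(1),
                           USE.NAMES = FALSE)
    orfs
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(tx_start = integer(0), tx_end = integer(0),
                  length_codons = integer(0), alt_starts = list(),
                  transcript_id = character(0), gene_id = character(0),
                  chrom = character(0), strand = character(0),
                  biotype = character(0), blocks = list(),
                  orf_seq = character(0), peptide = character(0),
                  orf_id = character(0)))
  }
  out$orf_id <- vapply(seq_len(nrow(out)), function(i) {
    b <- out$blocks[[i]]
    sprintf("%s:%d-%d:%s", out$chrom[i], b[1, "start"], b[nrow(b), "end"],
            out$strand[i])
  }, character(1))
  out
}
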