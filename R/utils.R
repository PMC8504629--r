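# Coordinate conventions used throughout:
#   * genomic intervals are 0-based, half-open, stored as integer matrices with
#     columns "start","end", rows sorted by ascending genomic start;
#   * transcript coordinates are 0-based offsets into the spliced sequence,
#     read 5'->3' in transcript orientation (minus-strand transcripts are
#     reverse-complemented on extraction).

block_mat <- function(start, end) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  m[order(m[, "start"]), , drop = FALSE]
}

block_width <- function(blocks) {
  if (is.null(blocks) || nrow(blocks) == 0L) return(0L)
  sum(blocks[, "end"] - blocks[, "start"])
}

#' Reverse complement of a nucleotide string
#'
#' Thin wrapper over [chartr()] handling the ACGTN alphabet case-insensitively.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements (upper case).
#' @keywords internal
revcomp <- function(x) {
  x <- toupper(x)
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Map transcript offsets -> genomic positions (vectorised, per-base).
# Returns integer vector of genomic positions (0-based) for each tx offset.
tx_to_genome_pos <- function(exons, strand, tpos) {
  L <- block_width(exons)
  stopifnot(all(tpos >= 0L), all(tpos < L))
  if (strand == "-") tpos <- L - 1L - tpos
  widths <- exons[, "end"] - exons[, "start"]
  cum <- cumsum(c(0L, widths))
  idx <- findInterval(tpos, cum, rightmost.closed = FALSE, left.open = FALSE)
  as.integer(exons[idx, "start"] + (tpos - cum[idx]))
}

# Map genomic positions -> transcript offsets; NA for positions outside exons.
genome_to_tx_pos <- function(exons, strand, gpos) {
  widths <- exons[, "end"] - exons[, "start"]
  cum <- cumsum(c(0L, widths))
  L <- sum(widths)
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_len(nrow(exons))) {
    inside <- gpos >= exons[i, "start"] & gpos < exons[i, "end"]
    out[inside] <- cum[i] + (gpos[inside] - exons[i, "start"])
  }
  if (strand == "-") out <- L - 1L - out
  out
}

# Genomic positions of a block set walked in transcript orientation.
blocks_tx_order_positions <- function(blocks, strand) {
  pos <- unlist(lapply(seq_len(nrow(blocks)), function(i) {
    seq.int(blocks[i, "start"], blocks[i, "end"] - 1L)
  }), use.names = FALSE)
  if (strand == "-") rev(pos) else pos
}

# Key used to identify an ORF by its exact genomic block structure.
blocks_key <- function(chrom, strand, blocks) {
  paste0(chrom, strand, paste(blocks[, "start"], blocks[, "end"],
                              sep = "-", collapse = ","))
}

stopifnot_scalar_path <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    abort("`path` must be a single file path.")
  }
}
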