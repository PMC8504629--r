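#' smORF positional class vocabulary
#'
#' Class labels ordered by the precedence used when records from different
#' transcript isoforms are merged (highest first).
#' @export
orf_class_levels <- c("canonical", "canonical_extended", "canonical_truncated",
                      "ouORF", "nuORF", "odORF", "ndORF", "ncORF")

#' Default set of non-coding transcript biotypes
#'
#' Biotypes whose ORFs are labelled `ncORF` when the host transcript has no
#' annotated CDS.
#' @export
noncoding_biotypes_default <- c(
  "lncRNA", "lincRNA", "antisense", "processed_transcript",
  "pseudogene", "processed_pseudogene", "unprocessed_pseudogene",
  "transcribed_processed_pseudogene", "transcribed_unprocessed_pseudogene",
  "polymorphic_pseudogene"
)

# CDS span in spliced-transcript coordinates, [start, end) including the stop
# codon; NULL when the transcript has no CDS.
cds_tx_span <- function(transcript) {
  tx <- as.list(transcript)
  cds <- if (is.list(tx$cds) && !is.matrix(tx$cds)) tx$cds[[1]] else tx$cds
  if (is.null(cds) || (is.matrix(cds) && nrow(cds) == 0L)) return(NULL)
  exons <- if (is.list(tx$exons) && !is.matrix(tx$exons)) tx$exons[[1]] else tx$exons
  gfirst <- cds[1, "start"]
  glast <- cds[nrow(cds), "end"] - 1L
  t1 <- genome_to_tx_pos(exons, tx$strand, c(gfirst, glast))
  if (anyNA(t1)) abort("CDS interval not contained in exons")
  c(min(t1), max(t1) + 1L)
}

#' Classify an ORF by its position relative to the annotated CDS
#'
#' Decision tree in spliced-transcript coordinates (5'->3'), with the
#' annotated CDS spanning `[cds_start, cds_end)` including its stop codon:
#' no CDS gives `ncORF`; an ORF identical to the CDS is `canonical`; sharing
#' the stop with an upstream start is `canonical_extended`, with a downstream
#' in-frame start `canonical_truncated`; entirely upstream of the CDS start is
#' `nuORF`; starting upstream and ending at/inside the CDS (different stop) is
#' `ouORF`; entirely downstream of the CDS end is `ndORF`; starting inside the
#' CDS and ending past its end is `odORF`. An ORF fully inside the CDS with a
#' different stop is `internal` and is never emitted by the pipeline.
#'
#' @param tx_start,tx_end ORF interval in transcript coordinates
#'   (0-based half-open; `tx_end` is one past the stop codon).
#' @param cds_start,cds_end annotated CDS interval in transcript coordinates
#'   including the stop codon, or `NA`/`NULL` when the transcript is
#'   non-coding.
#' @return a single class label (see [orf_class_levels]), or `"internal"`.
#' @export
classify_orf <- function(tx_start, tx_end, cds_start = NA, cds_end = NA) {
  if (is.null(cds_start) || is.na(cds_start)) return("ncORF")
  if (tx_start == cds_start && tx_end == cds_end) return("canonical")
  if (tx_end == cds_end) {
    if (tx_start < cds_start) return("canonical_extended")
    return("canonical_truncated")      # same stop implies in-frame
  }
  if (tx_end <= cds_start) return("nuORF")
  if (tx_start < cds_start) return("ouORF")
  if (tx_start >= cds_end) return("ndORF")
  if (tx_end > cds_end) return("odORF")
  "internal"
}

#' Classify scanned ORFs against their host transcripts
#'
#' Adds an `orf_class` column to the output of [scan_transcripts()]. The host
#' is treated as coding whenever it carries an annotated CDS; a transcript
#' with a CDS but a non-coding biotype is classified by CDS presence with a
#' warning.
#'
#' @param orfs tibble from [scan_transcripts()].
#' @param transcripts tibble from [read_gtf()].
#' @return `orfs` with `orf_class` (character) added; rows classified
#'   `internal` are retained here and dropped by [collapse_unique()].
#' @export
classify_orfs <- function(orfs, transcripts) {
  spans <- lapply(seq_len(nrow(transcripts)), function(i) cds_tx_span(transcripts[i, ]))
  names(spans) <- transcripts$transcript_id
  bt <- setNames(transcripts$biotype, transcripts$transcript_id)
  conflict <- vapply(transcripts$transcript_id, function(id) {
    !is.null(spans[[id]]) && bt[[id]] %in% noncoding_biotypes_default
  }, logical(1))
  if (any(conflict)) {
    warn(sprintf("%d transcript(s) with non-coding biotype carry a CDS; classified by CDS presence",
                 sum(conflict)))
  }
  orfs$orf_class <- vapply(seq_len(nrow(orfs)), function(i) {
    sp <- spans[[orfs$transcript_id[i]]]
    if (is.null(sp)) classify_orf(orfs$tx_start[i], orfs$tx_end[i])
    else classify_orf(orfs$tx_start[i], orfs$tx_end[i], sp[1], sp[2])
  }, character(1))
  orfs
}

# Genomic positions of the first base of each codon, in transcript order.
frame0_positions <- function(blocks, strand) {
  pos <- blocks_tx_order_positions(blocks, strand)
  pos[seq(1, length(pos), by = 3L)]
}

#' Collapse classified ORFs to a unique, non-nested set
#'
#' ORFs with identical genomic blocks (found on several transcript isoforms)
#' are merged into one record listing all host transcripts; the retained class
#' follows the precedence in [orf_class_levels] and per-ORF metric columns are
#' taken from the highest-precedence row. ORFs classified `internal` are
#' discarded. Finally, any ORF whose genomic codon-start positions are a
#' strict subset of another retained ORF's (same chromosome and strand, hence
#' nested in the same frame) is removed.
#'
#' @param orfs classified ORF tibble (from [classify_orfs()], possibly with
#'   metric columns added).
#' @return tibble with one row per unique ORF, list-columns
#'   `host_transcripts` and `gene_ids`, ordered by genomic position. The
#'   counts of merged and nested-removed rows are attached as attributes
#'   `n_internal`, `n_merged`, `n_nested`.
#' @export
collapse_unique <- function(orfs) {
  n_internal <- sum(orfs$orf_class == "internal")
  orfs <- orfs[orfs$orf_class != "internal", , drop = FALSE]
  if (nrow(orfs) == 0L) {
    out <- orfs
    out$host_transcripts <- list()
    out$gene_ids <- list()
    attr(out, "n_internal") <- n_internal
    attr(out, "n_merged") <- 0L
    attr(out, "n_nested") <- 0L
    return(out)
  }
  key <- vapply(seq_len(nrow(orfs)), function(i)
    blocks_key(orfs$chrom[i], orfs$strand[i], orfs$blocks[[i]]), character(1))
  prec <- match(orfs$orf_class, orf_class_levels)
  # deterministic representative: best class, then transcript id
  ord <- order(key, prec, orfs$transcript_id)
  orfs <- orfs[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  hosts <- split(orfs$transcript_id, key)
  genes <- split(orfs$gene_id, key)
  rep_rows <- orfs[first, , drop = FALSE]
  rep_rows$host_transcripts <- lapply(key[first], function(k) sort(unique(hosts[[k]])))
  rep_rows$gene_ids <- lapply(key[first], function(k) sort(unique(genes[[k]])))
  n_merged <- nrow(orfs) - nrow(rep_rows)

  # nested removal on the unique set
  f0 <- lapply(seq_len(nrow(rep_rows)), function(i)
    frame0_positions(rep_rows$blocks[[i]], rep_rows$strand[i]))
  nested <- rep(FALSE, nrow(rep_rows))
  for (i in seq_len(nrow(rep_rows))) {
    for (j in seq_len(nrow(rep_rows))) {
      if (i == j || nested[i]) next
      if (rep_rows$chrom[i] != rep_rows$chrom[j] ||
          rep_rows$strand[i] != rep_rows$strand[j]) next
      if (length(f0[[i]]) < length(f0[[j]]) && all(f0[[i]] %in% f0[[j]])) {
        nested[i] <- TRUE
      }
    }
  }
  out <- rep_rows[!nested, , drop = FALSE]
  out <- out[order(out$chrom,
                   map_int(out$blocks, function(b) b[1, "start"]),
                   out$strand), , drop = FALSE]
  attr(out, "n_internal") <- n_internal
  attr(out, "n_merged") <- n_merged
  attr(out, "n_nested") <- sum(nested)
  out
}

#' Class composition summary
#'
#' @param records classified (and usually collapsed) ORF tibble.
#' @return tibble with `orf_class`, `count` and `fraction`; fractions sum
#'   to 1. Empty input gives an empty table.
#' @export
class_composition <- function(records) {
  if (nrow(records) == 0L) {
    return(tibble(orf_class = character(0), count = integer(0),
                  fraction = numeric(0)))
  }
  out <- count(records, .data$orf_class, name = "count")
  out$fraction <- out$count / sum(out$count)
  arrange(out, desc(.data$count))
}
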