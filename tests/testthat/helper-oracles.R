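# Independent reference implementations ("oracles") used to validate the
# production code. They are written for clarity, not speed, and share no code
# with the package internals.

ORACLE_STOPS <- c("TAA", "TAG", "TGA")

# Exhaustive ORF enumeration. For every (frame, stop codon) pair, a candidate
# start is any in-frame permitted start codon upstream of the stop with no
# stop codon strictly between; the reported ORF uses the 5'-most candidate
# (first-start rule), the rest become alternative starts. Length bounds apply
# to the reported ORF only.
oracle_scan <- function(seq, min_codons = 5L, max_codons = 100L,
                        start_codons = "ATG") {
  seq <- toupper(seq)
  n <- nchar(seq)
  rows <- list()
  for (f in 0:2) {
    if (n - f < 6L) next
    pos <- seq.int(f, n - 3L, by = 3L)
    cods <- substring(seq, pos + 1L, pos + 3L)
    for (jidx in which(cods %in% ORACLE_STOPS)) {
      cand <- integer(0)
      for (iidx in which(cods %in% start_codons)) {
        if (iidx >= jidx) next
        between <- if (iidx + 1L <= jidx - 1L) {
          cods[(iidx + 1L):(jidx - 1L)]
        } else character(0)
        if (!any(between %in% ORACLE_STOPS)) cand <- c(cand, pos[iidx])
      }
      if (length(cand) == 0L) next
      i0 <- min(cand)
      len <- (pos[jidx] - i0) %/% 3L
      if (len < min_codons || len > max_codons) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        tx_start = i0, tx_end = pos[jidx] + 3L, length_codons = len,
        alt_starts = list(sort(setdiff(cand, i0))))
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(tx_start = integer(0), tx_end = integer(0),
                          length_codons = integer(0), alt_starts = list()))
  }
  out <- dplyr::bind_rows(rows)
  out[order(out$tx_start, out$tx_end), , drop = FALSE]
}

# Interval-logic classifier oracle: derive the class from explicit region
# predicates over the ORF [os, oe) and CDS [cs, ce) (stop included).
oracle_classify <- function(os, oe, cs = NA, ce = NA) {
  if (is.null(cs) || is.na(cs)) return("ncORF")
  starts_upstream <- os < cs
  starts_inside <- os >= cs && os < ce
  starts_downstream <- os >= ce
  ends_upstream <- oe <= cs
  ends_inside <- oe > cs && oe < ce
  ends_at_cds_stop <- oe == ce
  ends_downstream <- oe > ce
  if (ends_at_cds_stop) {
    if (os == cs) return("canonical")
    if (starts_upstream) return("canonical_extended")
    return("canonical_truncated")
  }
  if (starts_upstream && ends_upstream) return("nuORF")
  if (starts_upstream && (ends_inside || ends_downstream)) return("ouORF")
  if (starts_downstream) return("ndORF")
  if (starts_inside && ends_downstream) return("odORF")
  if (starts_inside && ends_inside) return("internal")
  stop("unreachable ORF/CDS configuration")
}

# Random ORF/CDS configuration generator, biased towards boundary cases.
oracle_random_config <- function() {
  has_cds <- runif(1) > 0.1
  cs <- ce <- NA_integer_
  if (has_cds) {
    cs <- sample(60:400, 1)
    ce <- cs + 3L * sample(10:100, 1)
  }
  mode <- if (!has_cds) "free" else {
    sample(c("free", "same_stop", "same_start", "abut_start", "abut_end",
             "identical"), 1, prob = c(0.5, 0.15, 0.1, 0.1, 0.1, 0.05))
  }
  if (mode == "free") {
    os <- sample(0:700, 1)
    oe <- os + 3L * sample(2:120, 1)
  } else if (mode == "same_stop") {
    oe <- ce
    os <- max(0L, oe - 3L * sample(2:130, 1))
  } else if (mode == "same_start") {
    os <- cs
    oe <- os + 3L * sample(2:130, 1)
  } else if (mode == "abut_start") {
    oe <- cs
    os <- max(0L, oe - 3L * sample(2:20, 1))
  } else if (mode == "abut_end") {
    os <- ce
    oe <- os + 3L * sample(2:40, 1)
  } else {
    os <- cs
    oe <- ce
  }
  list(os = os, oe = oe, cs = cs, ce = ce)
}

# Per-base projection oracle: expand an exon structure into the genomic
# position of every transcript base (transcript order), independent of the
# package's interval arithmetic.
oracle_tx_base_positions <- function(exons, strand) {
  pos <- unlist(lapply(seq_len(nrow(exons)), function(i) {
    seq.int(exons[i, "start"], exons[i, "end"] - 1L)
  }))
  if (strand == "-") rev(pos) else pos
}

# Rank-based AUROC (probability that a positive outscores a negative).
oracle_auroc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  np <- length(pos)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(neg))
}
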