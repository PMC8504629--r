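#' Read a genome FASTA into a named sequence set
#'
#' Loads every chromosome as an upper-case character string. Suitable for the
#' toy- to small-genome scale this package targets; sequences are held in
#' memory.
#'
#' @param path path to a (possibly multi-record) FASTA file.
#' @return named character vector, one element per chromosome.
#' @export
read_genome <- function(path) {
  stopifnot_scalar_path(path)
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  # FASTA headers may carry descriptions after the first token
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Read transcript models from a GTF file
#'
#' Parses exon, CDS and stop_codon records into one transcript model per
#' `transcript_id`. Coordinates are converted from the GTF convention
#' (1-based, closed) to 0-based half-open; exons are sorted in ascending
#' genomic order. Attribute parsing accepts both the `key "value";` and
#' `key=value` dialects; the biotype is read from `transcript_biotype`,
#' falling back to `gene_biotype`. Stop-codon records are merged into the CDS
#' block list so the CDS interval always includes the stop codon.
#'
#' @param path path to a GTF file.
#' @param biotypes optional character vector; when given, only transcripts
#'   whose biotype is in this set are returned.
#' @param genome optional named sequence set from [read_genome()]; transcripts
#'   on chromosomes absent from it are dropped with a warning.
#' @return a tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `biotype`, and list-columns `exons` and `cds` holding
#'   integer block matrices (columns `start`, `end`; `cds` may be `NULL`).
#' @export
read_gtf <- function(path, biotypes = NULL, genome = NULL) {
  stopifnot_scalar_path(path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lnum <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) abort("no records in GTF file")

  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad) > 0L) {
    abort(sprintf("unparseable GTF line %d: expected 9 tab-separated fields",
                  lnum[bad[1]]))
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:9)), ncol = 9, byrow = TRUE)
  type <- m[, 3]
  use <- type %in% c("exon", "CDS", "stop_codon")
  m <- m[use, , drop = FALSE]
  lnum <- lnum[use]
  if (nrow(m) == 0L) abort("GTF contains no exon/CDS records")

  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end)) {
    abad <- which(is.na(start) | is.na(end))[1]
    abort(sprintf("unparseable GTF line %d: non-numeric coordinates", lnum[abad]))
  }

  strand <- m[, 7]
  badstrand <- !(strand %in% c("+", "-"))
  if (any(badstrand)) {
    warn(sprintf("skipping %d GTF record(s) with unknown strand symbol",
                 sum(badstrand)))
    ok <- !badstrand
    m <- m[ok, , drop = FALSE]
    start <- start[ok]; end <- end[ok]; strand <- strand[ok]
  }

  attr_get <- function(attrs, key) {
    # GTF dialect: key "value"; -- GFF-ish dialect: key=value
    pat1 <- paste0(key, "\\s+\"([^\"]*)\"")
    pat2 <- paste0(key, "=([^;]+)")
    hit <- regmatches(attrs, regexec(pat1, attrs))
    val <- vapply(hit, function(h) if (length(h) == 2) h[2] else NA_character_,
                  character(1))
    miss <- is.na(val)
    if (any(miss)) {
      hit2 <- regmatches(attrs[miss], regexec(pat2, attrs[miss]))
      val[miss] <- vapply(hit2, function(h) {
        if (length(h) == 2) gsub("\"", "", trimws(h[2])) else NA_character_
      }, character(1))
    }
    val
  }

  attrs <- m[, 9]
  tx_id <- attr_get(attrs, "transcript_id")
  gene_id <- attr_get(attrs, "gene_id")
  tx_bt <- attr_get(attrs, "transcript_biotype")
  g_bt <- attr_get(attrs, "gene_biotype")
  if (anyNA(tx_id)) {
    abort(sprintf("unparseable GTF line %d: missing transcript_id",
                  lnum[which(is.na(tx_id))[1]]))
  }

  rec <- tibble(
    transcript_id = tx_id, gene_id = gene_id %||% NA_character_,
    chrom = m[, 1], type = m[, 3], strand = strand,
    start = start - 1L, end = end,   # to 0-based half-open
    biotype = dplyr::coalesce(tx_bt, g_bt, "unknown")
  )

  merge_blocks <- function(s, e) {
    o <- order(s)
    s <- s[o]; e <- e[o]
    ks <- s[1]; ke <- e[1]
    outs <- integer(0); oute <- integer(0)
    for (i in seq_along(s)[-1]) {
      if (s[i] <= ke) ke <- max(ke, e[i]) else {
        outs <- c(outs, ks); oute <- c(oute, ke); ks <- s[i]; ke <- e[i]
      }
    }
    block_mat(c(outs, ks), c(oute, ke))
  }

  split_rec <- split(rec, rec$transcript_id)
  rows <- lapply(split_rec, function(r) {
    ex <- r[r$type == "exon", ]
    if (nrow(ex) == 0L) return(NULL)
    cd <- r[r$type %in% c("CDS", "stop_codon"), ]
    tibble(
      transcript_id = r$transcript_id[1],
      gene_id = r$gene_id[1],
      chrom = r$chrom[1],
      strand = r$strand[1],
      biotype = r$biotype[1],
      exons = list(merge_blocks(ex$start, ex$end)),
      cds = list(if (nrow(cd) == 0L) NULL else merge_blocks(cd$start, cd$end))
    )
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L) {
    warn(sprintf("dropping %d transcript(s) with no exon records", dropped))
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0L) abort("no transcripts with exon records in GTF")

  if (!is.null(biotypes)) out <- out[out$biotype %in% biotypes, ]
  if (!is.null(genome)) {
    missing_chrom <- !(out$chrom %in% names(genome))
    if (any(missing_chrom)) {
      warn(sprintf("dropping %d transcript(s) on chromosomes absent from the genome",
                   sum(missing_chrom)))
      out <- out[!missing_chrom, ]
    }
  }
  arrange(out, .data$chrom, .data$transcript_id)
}

#' Spliced transcript sequence
#'
#' Concatenates exon sequences 5'->3' in transcript orientation;
#' minus-strand transcripts are reverse-complemented.
#'
#' @param transcript one row of the tibble from [read_gtf()] (or any list with
#'   `chrom`, `strand` and an `exons` block matrix).
#' @param genome named sequence set from [read_genome()].
#' @return a single nucleotide string.
#' @export
spliced_sequence <- function(transcript, genome) {
  tx <- as.list(transcript)
  exons <- if (is.list(tx$exons) && !is.matrix(tx$exons)) tx$exons[[1]] else tx$exons
  chromseq <- genome[[tx$chrom]]
  if (is.null(chromseq)) abort(sprintf("chromosome %s not in genome", tx$chrom))
  if (any(exons[, "end"] > nchar(chromseq)) || any(exons[, "start"] < 0L)) {
    abort(sprintf("exon outside chromosome bounds for transcript %s",
                  tx$transcript_id %||% "?"))
  }
  parts <- substring(chromseq, exons[, "start"] + 1L, exons[, "end"])
  s <- paste(parts, collapse = "")
  if (tx$strand == "-") revcomp(s) else s
}

bed12_extra_cols <- c(
  "orf_class", "host_transcripts", "orf_score", "rrs", "coverage",
  "rpf_fpkm", "rna_fpkm", "te", "conservation_score", "length_codons",
  "gene_ids", "frame_counts", "peptide"
)

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", x))

#' Write classified smORFs as a BED12+ table
#'
#' Columns 1-12 are standard BED12 (0-based half-open, blockStarts relative to
#' chromStart). Additional tab-separated columns carry the class, host
#' transcripts, translation metrics, an optional conservation score and -- as
#' the final column (column 25) -- the amino-acid sequence. The header line is
#' prefixed with `#`.
#'
#' @param records classified smORF tibble (see [run_smorf_pipeline()]).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_bed12_plus <- function(records, path) {
  stopifnot_scalar_path(path)
  if (nrow(records) > 0 &&
      any(vapply(records$blocks, function(b) is.null(b) || nrow(b) == 0, logical(1)))) {
    abort("record lacking genomic blocks")
  }
  hdr <- paste0("#", paste(c(
    "chrom", "chromStart", "chromEnd", "name", "score", "strand",
    "thickStart", "thickEnd", "itemRgb", "blockCount", "blockSizes",
    "blockStarts", bed12_extra_cols), collapse = "\t"))
  if (nrow(records) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  cstart <- map_int(records$blocks, function(b) b[1, "start"])
  cend <- map_int(records$blocks, function(b) b[nrow(b), "end"])
  sizes <- map_chr(records$blocks, function(b)
    paste(b[, "end"] - b[, "start"], collapse = ","))
  bstarts <- map_chr(records$blocks, function(b)
    paste(b[, "start"] - b[1, "start"], collapse = ","))
  score <- ifelse(is.na(records$orf_score), 0,
                  pmin(1000L, pmax(0L, as.integer(round(records$orf_score * 100)))))
  lines <- paste(
    records$chrom, cstart, cend, records$orf_id, score, records$strand,
    cstart, cend, "0",
    map_int(records$blocks, nrow), sizes, bstarts,
    as.character(records$orf_class),
    map_chr(records$host_transcripts, paste, collapse = ","),
    fmt_num(records$orf_score), fmt_num(records$rrs), fmt_num(records$coverage),
    fmt_num(records$rpf_fpkm), fmt_num(records$rna_fpkm), fmt_num(records$te),
    fmt_num(records$conservation_score), records$length_codons,
    map_chr(records$gene_ids, paste, collapse = ","),
    map_chr(records$frame_counts, paste, collapse = ";"),
    records$peptide,
    sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read back a BED12+ table written by [write_bed12_plus()]
#'
#' @param path file path.
#' @return a tibble with genomic blocks reconstructed as a list-column.
#' @export
read_bed12_plus <- function(path) {
  stopifnot_scalar_path(path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(0), orf_id = character(0),
                  strand = character(0), blocks = list()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  num <- function(i) as.numeric(vapply(f, function(x) {
    v <- x[i]; if (identical(v, "NA")) NA_character_ else v
  }, character(1)))
  chr_ <- function(i) vapply(f, `[`, character(1), i)
  blocks <- lapply(f, function(x) {
    cstart <- as.integer(x[2])
    sizes <- as.integer(strsplit(x[11], ",")[[1]])
    rel <- as.integer(strsplit(x[12], ",")[[1]])
    block_mat(cstart + rel, cstart + rel + sizes)
  })
  tibble(
    chrom = chr_(1), orf_id = chr_(4), strand = chr_(6), blocks = blocks,
    orf_class = chr_(13),
    host_transcripts = lapply(strsplit(chr_(14), ","), identity),
    orf_score = num(15), rrs = num(16), coverage = num(17),
    rpf_fpkm = num(18), rna_fpkm = num(19), te = num(20),
    conservation_score = num(21), length_codons = as.integer(num(22)),
    gene_ids = lapply(strsplit(chr_(23), ","), identity),
    peptide = chr_(25)
  )
}
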