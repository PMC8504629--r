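# Synthetic test world: a toy genome + GTF with planted smORFs of every
# positional class, 3-nt-periodic RPF reads with per-length 5' P-site offsets,
# and uniform RNA-Seq reads. All sequence content outside planted start codons
# is scrubbed of ATG trigrams, so the set of ORFs on every transcript is known
# exactly by construction.

SENSE_CODONS <- NULL  # initialised on load; sense codons excluding ATG

.onLoad <- function(libname, pkgname) {
  gc_ <- Biostrings::GENETIC_CODE
  utils::assignInMyNamespace("SENSE_CODONS",
                             setdiff(names(gc_)[gc_ != "*"], "ATG"))
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Replace the T of every ATG trigram with C, except at `keep` (0-based start
# offsets). The substitution can create neither a new ATG nor a stop codon.
scrub_atg <- function(s, keep = integer(0)) {
  repeat {
    hits <- gregexpr("ATG", s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) break
    todo <- setdiff(hits - 1L, keep)
    if (length(todo) == 0L) break
    for (h in todo) substr(s, h + 2L, h + 2L) <- "C"
  }
  s
}

# ORF nucleotide sequence of `n_codons` coding codons plus a stop.
# Stops are restricted to TAA/TAG so that scrubbing a flanking ATG can never
# touch the stop codon.
orf_nt <- function(n_codons, stop = "TAA", inner_atg_at = integer(0)) {
  body <- sample(SENSE_CODONS, n_codons - 1L, replace = TRUE)
  s <- paste0("ATG", paste(body, collapse = ""), stop)
  for (off in inner_atg_at) {           # 0-based, multiple of 3
    substr(s, off + 1L, off + 3L) <- "ATG"
  }
  s
}

sense_run <- function(n_codons) {
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

# --- cassette builders --------------------------------------------------
# Each returns: seq (spliced), keep (ATG offsets to preserve), cds_tx
# (interval incl stop or NULL), plants (tibble of intended scanner output
# with class + translated flag), regions (translated regions to cover with
# periodic RPF reads: tx interval + boost flag).

cassette_plain <- function() {
  cds <- paste0("ATG", sense_run(149L), "TAA")
  seq <- paste0(rand_dna(60), cds, rand_dna(100))
  list(seq = seq, keep = 60L, cds_tx = c(60L, 60L + 453L),
       plants = NULL,
       regions = tibble(tx_start = 60L, tx_end = 513L, boost = TRUE))
}

cassette_uorf <- function() {
  nu <- orf_nt(30L)                       # [10,103)
  cds <- paste0("ATG", sense_run(119L), "TAA")   # [160,523)
  nd <- orf_nt(25L)                       # [543,621)
  seq <- paste0(rand_dna(10), nu, rand_dna(57), cds,
                rand_dna(20), nd, rand_dna(52))
  list(seq = seq, keep = c(10L, 160L, 543L), cds_tx = c(160L, 523L),
       plants = tibble(tx_start = c(10L, 543L), tx_end = c(103L, 621L),
                       orf_class = c("nuORF", "ndORF"), translated = TRUE),
       regions = tibble(tx_start = c(10L, 160L, 543L),
                        tx_end = c(103L, 523L, 621L),
                        boost = c(TRUE, TRUE, TRUE)))
}

cassette_ouorf <- function() {
  # ouORF [54,177): 40 codons, ends 7 nt inside the CDS (frame +1 rel. CDS);
  # odORF [523,646): 40 codons, starts 10 nt before the CDS end (frame +2).
  # CDS head/tail codons are fixed so both overlap frames read through
  # cleanly and stop exactly where intended.
  ou_part <- paste0("ATG", sense_run(37L), "CC")       # 116 nt, [54,170)
  cds <- paste0("ATG", "CTA", "AAA", sense_run(114L),
                "CCA", "TGC", sense_run(1L), "TAA")     # 121 codons, [170,533)
  utr3 <- paste0("CC", sense_run(36L), "TAA", rand_dna(67))  # 180 nt
  seq <- paste0(rand_dna(54), ou_part, cds, utr3)
  list(seq = seq, keep = c(54L, 170L, 523L), cds_tx = c(170L, 533L),
       plants = tibble(tx_start = c(54L, 523L), tx_end = c(177L, 646L),
                       orf_class = c("ouORF", "odORF"), translated = TRUE),
       regions = tibble(tx_start = c(54L, 170L, 523L),
                        tx_end = c(177L, 533L, 646L),
                        boost = c(TRUE, TRUE, TRUE)))
}

cassette_canonical <- function() {
  cds <- orf_nt(40L)                      # [50,173)
  seq <- paste0(rand_dna(50), cds, rand_dna(120))
  list(seq = seq, keep = 50L, cds_tx = c(50L, 173L),
       plants = tibble(tx_start = 50L, tx_end = 173L,
                       orf_class = "canonical", translated = TRUE),
       regions = tibble(tx_start = 50L, tx_end = 173L, boost = TRUE))
}

cassette_extended <- function() {
  # annotated CDS [60,153); in-frame upstream ATG at 48 with no stop between
  ext <- paste0("ATG", sense_run(3L))     # [48,60)
  cds <- orf_nt(30L)                      # [60,153), starts ATG (kept)
  seq <- paste0(rand_dna(48), ext, cds, rand_dna(100))
  list(seq = seq, keep = c(48L, 60L), cds_tx = c(60L, 153L),
       plants = tibble(tx_start = 48L, tx_end = 153L,
                       orf_class = "canonical_extended", translated = TRUE),
       regions = tibble(tx_start = 48L, tx_end = 153L, boost = TRUE))
}

cassette_truncated <- function() {
  # annotated CDS [50,143) initiates at CTG; first in-frame ATG at 62
  cds <- paste0("CTG", sense_run(3L), "ATG", sense_run(25L), "TAA")
  seq <- paste0(rand_dna(50), cds, rand_dna(110))
  list(seq = seq, keep = 62L, cds_tx = c(50L, 143L),
       plants = tibble(tx_start = 62L, tx_end = 143L,
                       orf_class = "canonical_truncated", translated = TRUE),
       regions = tibble(tx_start = 62L, tx_end = 143L, boost = TRUE))
}

cassette_ncorf <- function(utr5 = 70L, n_codons = 33L, utr3 = 100L,
                           translated = TRUE) {
  o <- orf_nt(n_codons)
  len <- (n_codons + 1L) * 3L
  seq <- paste0(rand_dna(utr5), o, rand_dna(utr3))
  list(seq = seq, keep = utr5, cds_tx = NULL,
       plants = tibble(tx_start = utr5, tx_end = utr5 + len,
                       orf_class = "ncORF", translated = translated),
       regions = if (translated) {
         tibble(tx_start = utr5, tx_end = utr5 + len, boost = TRUE)
       } else NULL)
}

# --- genomic placement --------------------------------------------------

new_world_state <- function(chrom_sizes) {
  list(
    chroms = lapply(chrom_sizes, function(n) rand_dna(n)),
    cursor = lapply(chrom_sizes, function(n) 1000L),
    tx = list(), seqs = character(0), gtf = character(0)
  )
}

# Write the spliced sequence of a transcript into a chromosome, splitting it
# into exons of the given (transcript-order) lengths with random introns.
embed_transcript <- function(st, id, gene, biotype, strand, chrom, cas,
                             exon_lengths, abundance = 1, te_mult = 1,
                             at = NULL, exons_override = NULL) {
  seq <- scrub_atg(cas$seq, cas$keep)
  L <- nchar(seq)
  stopifnot(sum(exon_lengths) == L)
  if (is.null(exons_override)) {
    gstart <- at %||% st$cursor[[chrom]]
    n_ex <- length(exon_lengths)
    introns <- if (n_ex > 1L) sample(100:300, n_ex - 1L, replace = TRUE) else integer(0)
    glens <- if (strand == "-") rev(exon_lengths) else exon_lengths
    starts <- gstart + cumsum(c(0L, glens[-n_ex] + introns))
    exons <- block_mat(starts, starts + glens)
  } else {
    exons <- exons_override
    gstart <- exons[1, "start"]
  }
  # transcript-order segments of the spliced sequence
  cum <- cumsum(c(0L, exon_lengths))
  segs <- substring(seq, cum[-length(cum)] + 1L, cum[-1L])
  n_ex <- length(exon_lengths)
  for (i in seq_len(n_ex)) {
    gi <- if (strand == "-") n_ex + 1L - i else i
    gseq <- if (strand == "-") revcomp(segs[i]) else segs[i]
    substr(st$chroms[[chrom]], exons[gi, "start"] + 1L, exons[gi, "end"]) <- gseq
  }
  st$cursor[[chrom]] <- max(st$cursor[[chrom]],
                            exons[n_ex, "end"] + sample(500:1500, 1L))
  tx <- tibble(transcript_id = id, gene_id = gene, chrom = chrom,
               strand = strand, biotype = biotype,
               exons = list(exons),
               cds = list(if (is.null(cas$cds_tx)) NULL else
                 project_to_genome(list(exons = exons, strand = strand), cas$cds_tx)))
  st$tx[[id]] <- c(as.list(tx), list(
    spliced = seq, abundance = abundance, te_mult = te_mult,
    plants = cas$plants, regions = cas$regions, cds_tx = cas$cds_tx))
  st
}

world_gtf_lines <- function(st) {
  out <- character(0)
  for (id in names(st$tx)) {
    t <- st$tx[[id]]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
                     t$gene_id, id, t$biotype)
    ex <- t$exons[[1]]
    span <- c(ex[1, "start"], ex[nrow(ex), "end"])
    mk <- function(type, s, e) {
      sprintf("%s\tsmorfkit\t%s\t%d\t%d\t.\t%s\t.\t%s",
              t$chrom, type, s + 1L, e, t$strand, attrs)
    }
    out <- c(out, mk("transcript", span[1], span[2]))
    for (i in seq_len(nrow(ex))) out <- c(out, mk("exon", ex[i, 1], ex[i, 2]))
    cds <- t$cds[[1]]
    if (!is.null(cds)) {
      for (i in seq_len(nrow(cds))) out <- c(out, mk("CDS", cds[i, 1], cds[i, 2]))
    }
  }
  out
}

# --- read simulation ----------------------------------------------------

# Periodic footprints over a translated transcript region. P-sites sit on
# codon starts with probability `fidelity` (otherwise +/- 1 nt); the first
# codon is boosted `init_boost`-fold to emulate the initiation pause.
sim_rpf_region <- function(t, region_start, region_end, lambda, fidelity,
                           read_lengths, offsets, init_boost, boost) {
  cod <- seq.int(region_start, region_end - 3L, by = 3L)
  lam <- rep(lambda, length(cod))
  if (boost) lam[1] <- lambda * init_boost
  counts <- rpois(length(cod), lam)
  p <- rep(cod, counts)
  if (length(p) == 0L) return(NULL)
  eps <- sample(c(0L, -1L, 1L), length(p), replace = TRUE,
                prob = c(fidelity, (1 - fidelity) / 2, (1 - fidelity) / 2))
  p <- p + eps
  Lr <- sample(read_lengths, length(p), replace = TRUE)
  off <- offsets[as.character(Lr)]
  five <- p - off
  Ltx <- block_width(t$exons[[1]])
  ok <- five >= 0L & (five + Lr) <= Ltx
  five <- five[ok]; Lr <- Lr[ok]
  if (length(five) == 0L) return(NULL)
  tibble(chrom = t$chrom, strand = t$strand,
         blocks = lapply(seq_along(five), function(i) {
           project_to_genome(list(exons = t$exons[[1]], strand = t$strand),
                             c(five[i], five[i] + Lr[i]))
         }))
}

# Non-periodic read-through footprints: uniform P-site positions across the
# ORF and `overhang` nt past its stop (untranslated decoy signal).
sim_rpf_readthrough <- function(t, region_start, region_end, mu_per_nt,
                                read_lengths, offsets, overhang = 60L) {
  Ltx <- block_width(t$exons[[1]])
  hi <- min(region_end + overhang, Ltx)
  n <- rpois(1L, mu_per_nt * (hi - region_start))
  if (n == 0L) return(NULL)
  p <- sample(seq.int(region_start, hi - 1L), n, replace = TRUE)
  Lr <- sample(read_lengths, n, replace = TRUE)
  off <- offsets[as.character(Lr)]
  five <- p - off
  ok <- five >= 0L & (five + Lr) <= Ltx
  five <- five[ok]; Lr <- Lr[ok]
  if (length(five) == 0L) return(NULL)
  tibble(chrom = t$chrom, strand = t$strand,
         blocks = lapply(seq_along(five), function(i) {
           project_to_genome(list(exons = t$exons[[1]], strand = t$strand),
                             c(five[i], five[i] + Lr[i]))
         }))
}

sim_rna <- function(t, abundance, rna_cov, read_len = 50L) {
  Ltx <- block_width(t$exons[[1]])
  if (Ltx <= read_len) return(NULL)
  n <- rpois(1L, abundance * Ltx * rna_cov / read_len)
  if (n == 0L) return(NULL)
  s <- sample(seq.int(0L, Ltx - read_len), n, replace = TRUE)
  tibble(chrom = t$chrom, strand = t$strand,
         blocks = lapply(s, function(x) {
           project_to_genome(list(exons = t$exons[[1]], strand = t$strand),
                             c(x, x + read_len))
         }))
}

write_sam <- function(reads, path, chroms, prefix) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), nchar(chroms)))
  if (is.null(reads) || nrow(reads) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  pos <- map_int(reads$blocks, function(b) b[1, "start"])
  ord <- order(match(reads$chrom, names(chroms)), pos)
  reads <- reads[ord, , drop = FALSE]
  pos <- pos[ord]
  lines <- vapply(seq_len(nrow(reads)), function(i) {
    b <- reads$blocks[[i]]
    sizes <- b[, "end"] - b[, "start"]
    gaps <- if (nrow(b) > 1L) b[-1L, "start"] - b[-nrow(b), "end"] else integer(0)
    cig <- paste0(sizes[1], "M")
    if (length(gaps) > 0L) {
      cig <- paste0(cig, paste0(gaps, "N", sizes[-1L], "M", collapse = ""))
    }
    sq <- paste(substring(chroms[[reads$chrom[i]]],
                          b[, "start"] + 1L, b[, "end"]), collapse = "")
    flag <- if (reads$strand[i] == "-") 16L else 0L
    sprintf("%s%06d\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s",
            prefix, i, flag, reads$chrom[i], pos[i] + 1L, cig, sq,
            strrep("I", nchar(sq)))
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Generate the synthetic test world
#'
#' Builds a self-contained two-chromosome world: genome FASTA, GTF with
#' multi-exon protein-coding, lncRNA and pseudogene transcripts on both
#' strands, planted smORFs of every positional class (plus an isoform pair
#' sharing one ORF and a nested-ORF trap), coordinate-sorted RPF and RNA
#' alignments (SAM and indexed BAM), and a ground-truth manifest.
#'
#' Translated features receive 3-nt-periodic footprints (P-sites on codon
#' starts with probability `fidelity`, read lengths 28/30 nt with 5' offsets
#' 12/13, a 3x initiation pause on the first codon, terminating at the stop
#' codon). Untranslated decoy ORFs receive either no footprints or uniform
#' non-periodic read-through signal. RNA reads are uniform over exons,
#' proportional to transcript abundance.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed; all randomness flows from it.
#' @param n_decoys number of untranslated decoy ORFs (default 10).
#' @param depth mean P-sites per codon on translated features (default 4).
#' @param fidelity frame-0 fidelity of P-site placement (default 0.85).
#' @param decoy_mode `"readthrough"` (uniform non-periodic decoy footprints)
#'   or `"none"` (decoys get RNA reads only).
#' @param rna_cov mean RNA-Seq coverage per transcript at abundance 1.
#' @param classes smORF classes to plant (default: all eight).
#' @return invisibly, the manifest: a list with `params`, `paths`,
#'   `transcripts` (incl. spliced sequences and abundances) and `orfs`
#'   (planted ORFs with class, translated flag, genomic blocks, peptide and
#'   expectation labels).
#' @export
make_world <- function(out_dir, seed = 1L, n_decoys = 10L, depth = 4,
                       fidelity = 0.85, decoy_mode = c("readthrough", "none"),
                       rna_cov = 10, classes = orf_class_levels) {
  decoy_mode <- match.arg(decoy_mode)
  bad <- setdiff(classes, orf_class_levels)
  if (length(bad) > 0L) abort(paste("unknown class:", paste(bad, collapse = ", ")))
  if (length(classes) == 0L) abort("empty class set")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)

  read_lengths <- c(28L, 30L)
  offsets <- c(`28` = 12L, `30` = 13L)
  init_boost <- 3

  st <- new_world_state(c(chr1 = 100000L, chr2 = 100000L))

  has <- function(cl) any(cl %in% classes)
  st <- embed_transcript(st, "tx_plain", "g_plain", "protein_coding", "+",
                         "chr1", cassette_plain(), c(250L, 363L))
  if (has(c("nuORF", "ndORF"))) {
    st <- embed_transcript(st, "tx_uorf", "g_uorf", "protein_coding", "+",
                           "chr1", cassette_uorf(), c(300L, 373L))
  }
  if (has(c("ouORF", "odORF"))) {
    st <- embed_transcript(st, "tx_ouorf", "g_ouorf", "protein_coding", "+",
                           "chr1", cassette_ouorf(), c(350L, 363L))
  }
  if (has("canonical_extended")) {
    st <- embed_transcript(st, "tx_ext", "g_ext", "protein_coding", "-",
                           "chr1", cassette_extended(), c(120L, 133L))
  }
  if (has("canonical")) {
    st <- embed_transcript(st, "tx_canon", "g_canon", "protein_coding", "+",
                           "chr2", cassette_canonical(), c(100L, 193L))
  }
  if (has("canonical_truncated")) {
    st <- embed_transcript(st, "tx_trunc", "g_trunc", "protein_coding", "+",
                           "chr2", cassette_truncated(), c(253L))
  }
  if (has("ncORF")) {
    st <- embed_transcript(st, "lnc_nc", "g_lnc", "lncRNA", "-", "chr2",
                           cassette_ncorf(70L, 33L, 100L), c(120L, 152L),
                           te_mult = 1.5)
    st <- embed_transcript(st, "pseudo_nc", "g_pseudo", "pseudogene", "+",
                           "chr2", cassette_ncorf(60L, 25L, 80L), c(218L))

    # isoform pair sharing one ORF on a common exon
    iso_shared <- cassette_ncorf(40L, 28L, 73L)       # 200-nt shared exon
    stopifnot(nchar(iso_shared$seq) == 200L)
    base <- st$cursor[["chr1"]]
    exB0 <- block_mat(base, base + 100L)
    exA1 <- block_mat(base + 250L, base + 400L)
    exS <- block_mat(base + 550L, base + 750L)
    casA <- list(seq = paste0(rand_dna(150), iso_shared$seq),
                 keep = 150L + iso_shared$keep, cds_tx = NULL,
                 plants = dplyr::mutate(iso_shared$plants,
                                        tx_start = .data$tx_start + 150L,
                                        tx_end = .data$tx_end + 150L),
                 regions = dplyr::mutate(iso_shared$regions,
                                         tx_start = .data$tx_start + 150L,
                                         tx_end = .data$tx_end + 150L))
    st <- embed_transcript(st, "iso_a", "g_iso", "lncRNA", "+", "chr1", casA,
                          c(150L, 200L), te_mult = 0.75,
                          exons_override = rbind(exA1, exS))
    sA <- st$tx[["iso_a"]]$spliced
    casB <- list(seq = paste0(rand_dna(100), substring(sA, 151L, 350L)),
                 keep = 100L + iso_shared$keep, cds_tx = NULL,
                 plants = dplyr::mutate(iso_shared$plants,
                                        tx_start = .data$tx_start + 100L,
                                        tx_end = .data$tx_end + 100L),
                 regions = NULL)  # shared reads are simulated once, on iso_a
    st <- embed_transcript(st, "iso_b", "g_iso", "lncRNA", "+", "chr1", casB,
                          c(100L, 200L), te_mult = 0.75,
                          exons_override = rbind(exB0, exS))
    st$cursor[["chr1"]] <- base + 750L + sample(500:1500, 1L)

    # nested trap: a short isoform starting inside a longer ORF exposes the
    # inner in-frame ATG as its own ORF, nested in the long one
    nest <- cassette_ncorf(100L, 60L, 117L)           # ORF [100,283), len 400
    nest$seq <- paste0(substring(nest$seq, 1L, 100L),
                       orf_nt(60L, inner_atg_at = 60L),
                       substring(nest$seq, 284L, 400L))
    nest$keep <- c(100L, 160L)
    gN <- st$cursor[["chr2"]]
    st <- embed_transcript(st, "nest_long", "g_nest", "lncRNA", "+", "chr2",
                           nest, 400L,
                           exons_override = block_mat(gN, gN + 400L))
    sN <- st$tx[["nest_long"]]$spliced
    casNB <- list(seq = substring(sN, 131L, 400L), keep = 30L, cds_tx = NULL,
                  plants = tibble(tx_start = 30L, tx_end = 153L,
                                  orf_class = "ncORF", translated = TRUE),
                  regions = NULL)
    st <- embed_transcript(st, "nest_short", "g_nest", "lncRNA", "+", "chr2",
                           casNB, 270L,
                           exons_override = block_mat(gN + 130L, gN + 400L))
    st$cursor[["chr2"]] <- gN + 400L + sample(500:1500, 1L)
  }

  # untranslated decoys (lncRNA, one ORF each); three carry the abundance
  # ladder used for FPKM rank checks
  decoy_ids <- character(0)
  if (n_decoys > 0L) {
    ab <- rep(1, n_decoys)
    ab[seq_len(min(3L, n_decoys))] <- c(1, 2, 4)[seq_len(min(3L, n_decoys))]
    for (k in seq_len(n_decoys)) {
      id <- sprintf("decoy_%02d", k)
      decoy_ids <- c(decoy_ids, id)
      chrom <- if (k %% 2L == 0L) "chr1" else "chr2"
      strand <- if (k %% 3L == 0L) "-" else "+"
      st <- embed_transcript(st, id, paste0("g_", id), "lncRNA", strand, chrom,
                             cassette_ncorf(80L, 30L, 127L, translated = FALSE),
                             300L, abundance = ab[k])
    }
  }

  # consistency: the genome must return exactly the designed spliced sequence
  genome <- vapply(st$chroms, identity, character(1))
  for (id in names(st$tx)) {
    t <- st$tx[[id]]
    got <- spliced_sequence(list(transcript_id = id, chrom = t$chrom,
                                 strand = t$strand, exons = t$exons[[1]]),
                            genome)
    if (!identical(got, t$spliced)) {
      abort(sprintf("internal generator error: spliced sequence mismatch for %s", id))
    }
  }

  # simulate reads
  rpf <- list(); rna <- list()
  for (id in names(st$tx)) {
    t <- st$tx[[id]]
    lam <- depth * t$te_mult * t$abundance
    if (!is.null(t$regions)) {
      for (i in seq_len(nrow(t$regions))) {
        rpf[[length(rpf) + 1L]] <- sim_rpf_region(
          t, t$regions$tx_start[i], t$regions$tx_end[i], lam, fidelity,
          read_lengths, offsets, init_boost, t$regions$boost[i])
      }
    }
    if (id %in% decoy_ids && decoy_mode == "readthrough") {
      p <- t$plants
      rpf[[length(rpf) + 1L]] <- sim_rpf_readthrough(
        t, p$tx_start[1], p$tx_end[1], lam / 3, read_lengths, offsets)
    }
    rna[[length(rna) + 1L]] <- sim_rna(t, t$abundance, rna_cov)
  }
  rpf <- bind_rows(rpf); rna <- bind_rows(rna)

  # write outputs
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    gtf = file.path(out_dir, "annot.gtf"),
    ribo_sam = file.path(out_dir, "ribo.sam"),
    rna_sam = file.path(out_dir, "rna.sam"),
    ribo_bam = file.path(out_dir, "ribo.bam"),
    rna_bam = file.path(out_dir, "rna.bam"),
    manifest = file.path(out_dir, "manifest.json")
  )
  dna <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dna, paths$genome, width = 70L)
  writeLines(world_gtf_lines(st), paths$gtf)
  write_sam(rpf, paths$ribo_sam, genome, "rpf")
  write_sam(rna, paths$rna_sam, genome, "rna")
  for (what in c("ribo", "rna")) {
    bam <- Rsamtools::asBam(paths[[paste0(what, "_sam")]],
                            sub("\\.bam$", "", paths[[paste0(what, "_bam")]]),
                            overwrite = TRUE, indexDestination = TRUE)
  }

  # manifest
  orf_rows <- list()
  for (id in names(st$tx)) {
    t <- st$tx[[id]]
    if (is.null(t$plants)) next
    for (i in seq_len(nrow(t$plants))) {
      p <- t$plants[i, ]
      bl <- project_to_genome(list(exons = t$exons[[1]], strand = t$strand),
                              c(p$tx_start, p$tx_end))
      orf_rows[[length(orf_rows) + 1L]] <- tibble(
        transcript_id = id, orf_class = p$orf_class,
        translated = p$translated,
        tx_start = p$tx_start, tx_end = p$tx_end,
        chrom = t$chrom, strand = t$strand, blocks = list(bl),
        orf_id = sprintf("%s:%d-%d:%s", t$chrom, bl[1, "start"],
                         bl[nrow(bl), "end"], t$strand),
        peptide = translate_orf(substring(t$spliced, p$tx_start + 1L, p$tx_end)),
        te_mult = t$te_mult, abundance = t$abundance,
        is_decoy = id %in% decoy_ids,
        nested_in_longer = id == "nest_short"
      )
    }
  }
  orfs <- bind_rows(orf_rows)
  orfs$expected_detected <- orfs$translated & !orfs$nested_in_longer
  tx_tbl <- bind_rows(lapply(names(st$tx), function(id) {
    t <- st$tx[[id]]
    tibble(transcript_id = id, gene_id = t$gene_id, chrom = t$chrom,
           strand = t$strand, biotype = t$biotype,
           exons = list(t$exons[[1]]),
           spliced = t$spliced, abundance = t$abundance, te_mult = t$te_mult)
  }))
  manifest <- list(
    params = list(seed = seed, depth = depth, fidelity = fidelity,
                  read_lengths = read_lengths, offsets = offsets,
                  init_boost = init_boost, rna_cov = rna_cov,
                  n_decoys = n_decoys, decoy_mode = decoy_mode),
    paths = paths,
    transcripts = tx_tbl,
    orfs = orfs,
    expected_unique_detected = sum(!duplicated(
      orfs$orf_id[orfs$expected_detected]))
  )
  json <- manifest
  json$transcripts$exons <- lapply(json$transcripts$exons, function(m)
    as.data.frame(m))
  json$orfs$blocks <- lapply(json$orfs$blocks, as.data.frame)
  jsonlite::write_json(json, paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate translation signal for a single ORF
#'
#' A lightweight component-level simulator used to study metric behaviour:
#' returns frame counts and region counts for one ORF plus its downstream
#' window, either with genuinely terminating periodic footprints
#' (`translated = TRUE`) or with uniform read-through signal.
#'
#' @param n_codons ORF length in codons (stop excluded).
#' @param downstream_nt downstream window length in nt.
#' @param depth mean P-sites per codon.
#' @param fidelity frame-0 fidelity.
#' @param translated logical; `FALSE` gives uniform read-through signal at the
#'   same total density, extending through the downstream window.
#' @param rna_per_nt mean RNA 5'-end count per nt (both regions).
#' @return list with `frame_counts`, `rpf_orf`, `rpf_down`, `rna_orf`,
#'   `rna_down`, `len_orf`, `len_down`.
#' @export
simulate_orf_signal <- function(n_codons, downstream_nt = 150L, depth = 4,
                                fidelity = 0.85, translated = TRUE,
                                rna_per_nt = 0.2) {
  len_orf <- (n_codons + 1L) * 3L
  if (translated) {
    cod <- seq.int(0L, len_orf - 3L, by = 3L)
    counts <- rpois(length(cod), depth)
    p <- rep(cod, counts)
    eps <- sample(c(0L, -1L, 1L), length(p), replace = TRUE,
                  prob = c(fidelity, (1 - fidelity) / 2, (1 - fidelity) / 2))
    p <- pmax(0L, p + eps)
    down <- integer(0)
  } else {
    n <- rpois(1L, depth / 3 * (len_orf + downstream_nt))
    pos <- sample(seq_len(len_orf + downstream_nt) - 1L, n, replace = TRUE)
    p <- pos[pos < len_orf]
    down <- pos[pos >= len_orf]
  }
  interior <- p >= 3L & p < (len_orf - 3L)
  fc <- vapply(0:2, function(f) sum(p[interior] %% 3L == f), numeric(1))
  list(frame_counts = fc,
       rpf_orf = length(p), rpf_down = length(down),
       rna_orf = rpois(1L, rna_per_nt * len_orf),
       rna_down = rpois(1L, rna_per_nt * downstream_nt),
       len_orf = len_orf, len_down = downstream_nt)
}
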