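# Shared fixtures: synthetic worlds and pipeline runs are expensive enough to
# build once per session and reuse across test files.

.fixture_env <- new.env(parent = emptyenv())

get_world <- function(seed = 1L) {
  key <- sprintf("world_%d", seed)
  if (is.null(.fixture_env[[key]])) {
    dir <- file.path(tempdir(), sprintf("smorfkit-world-%d", seed))
    .fixture_env[[key]] <- suppressMessages(make_world(dir, seed = seed))
  }
  .fixture_env[[key]]
}

get_run <- function(seed = 1L) {
  key <- sprintf("run_%d", seed)
  if (is.null(.fixture_env[[key]])) {
    w <- get_world(seed)
    .fixture_env[[key]] <- suppressMessages(run_smorf_pipeline(
      w$paths$genome, w$paths$gtf, w$paths$ribo_bam, w$paths$rna_bam))
  }
  .fixture_env[[key]]
}

get_world_transcripts <- function(seed = 1L) {
  key <- sprintf("txs_%d", seed)
  if (is.null(.fixture_env[[key]])) {
    w <- get_world(seed)
    genome <- read_genome(w$paths$genome)
    .fixture_env[[key]] <- list(
      genome = genome,
      txs = read_gtf(w$paths$gtf, genome = genome))
  }
  .fixture_env[[key]]
}

# Write SAM lines to a temp file and convert to an indexed BAM; returns the
# BAM path. `lines` are full alignment lines (tab-separated); the header is
# built from `chrom_sizes` (named integer vector).
sam_to_bam <- function(lines, chrom_sizes) {
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes), chrom_sizes))
  writeLines(c(hdr, lines), sam)
  Rsamtools::asBam(sam, sub("\\.sam$", "", sam),
                   overwrite = TRUE, indexDestination = TRUE)
}
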