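test_that("scan_orfs_in_sequence applies the first-start rule and records alternative starts", {
  # frame 0: ATG at 0, second ATG at 6, stop TAA at 21
  s <- paste0("ATGAAA", "ATG", "GCTGCTGCTGCT", "TAA")
  got <- scan_orfs_in_sequence(s)
  expect_identical(nrow(got), 1L)
  expect_identical(got$tx_start, 0L)
  expect_identical(got$tx_end, 24L)
  expect_identical(got$length_codons, 7L)
  expect_identical(got$alt_starts[[1]], 6L)
})

test_that("scan_orfs_in_sequence emits one ORF per (frame, stop) and resets after a stop", {
  # two consecutive ORFs in frame 0 separated by their stops
  s <- paste0("ATG", strrep("GCT", 5), "TAA",
              "ATG", strrep("GCA", 6), "TAG", "CC")
  got <- scan_orfs_in_sequence(s)
  expect_identical(got$tx_start, c(0L, 21L))
  expect_identical(got$tx_end, c(21L, 45L))
  expect_identical(got$length_codons, c(6L, 7L))
})

test_that("scan_orfs_in_sequence honours length bounds and requires an in-frame stop", {
  short <- paste0("ATG", strrep("GCT", 4), "TAA")   # 5 codons incl. start
  expect_identical(nrow(scan_orfs_in_sequence(short, min_codons = 6L)), 0L)
  expect_identical(nrow(scan_orfs_in_sequence(short, min_codons = 5L)), 1L)
  long <- paste0("ATG", strrep("GCT", 120), "TAA")
  expect_identical(nrow(scan_orfs_in_sequence(long)), 0L)     # > 100 codons
  expect_identical(nrow(scan_orfs_in_sequence(long, max_codons = 200L)), 1L)
  no_stop <- paste0("ATG", strrep("GCT", 10))
  expect_identical(nrow(scan_orfs_in_sequence(no_stop)), 0L)
})

test_that("scan_orfs_in_sequence supports alternative start codon sets", {
  s <- paste0("CTG", strrep("GCT", 8), "TAA")
  expect_identical(nrow(scan_orfs_in_sequence(s)), 0L)
  got <- scan_orfs_in_sequence(s, start_codons = c("ATG", "CTG"))
  expect_identical(got$tx_start, 0L)
})

test_that("project_to_genome matches a per-base oracle on random spliced structures", {
  set.seed(42)
  for (rep in 1:60) {
    n_ex <- sample(1:4, 1)
    widths <- sample(5:40, n_ex, replace = TRUE)
    gaps <- sample(10:50, n_ex, replace = TRUE)
    starts <- cumsum(gaps + c(0L, widths[-n_ex]))
    exons <- cbind(start = as.integer(starts),
                   end = as.integer(starts + widths))
    strand <- sample(c("+", "-"), 1)
    L <- sum(widths)
    a <- sample(0:(L - 2L), 1)
    b <- sample((a + 1L):L, 1)
    blocks <- project_to_genome(list(exons = exons, strand = strand), c(a, b))
    got <- unlist(lapply(seq_len(nrow(blocks)), function(i)
      seq.int(blocks[i, "start"], blocks[i, "end"] - 1L)))
    base_pos <- oracle_tx_base_positions(exons, strand)
    expect_identical(got, sort(base_pos[(a + 1L):b]))
  }
})

test_that("project_to_genome rejects out-of-range intervals", {
  tx <- list(exons = cbind(start = 0L, end = 10L), strand = "+")
  expect_error(project_to_genome(tx, c(-1L, 5L)), "out of range")
  expect_error(project_to_genome(tx, c(0L, 11L)), "out of range")
  expect_error(project_to_genome(tx, c(5L, 5L)), "out of range")
})

test_that("translate_orf uses the standard code, drops the trailing stop and flags errors", {
  expect_identical(translate_orf("ATGGCTTAA"), "MA")
  expect_identical(translate_orf("atggct"), "MA")
  expect_identical(translate_orf("ATGNNNTAA"), "MX")
  expect_error(translate_orf("ATGTAAGCTTAA"), "internal stop")
  expect_error(translate_orf("ATGG"), "divisible by 3")
})

test_that("scan_transcripts recovers exactly the planted ORFs of the synthetic world", {
  w <- get_world(1)
  wt <- get_world_transcripts(1)
  sc <- scan_transcripts(wt$txs, wt$genome)
  # every transcript yields exactly its planted ORFs: the ATG-scrubbed
  # backgrounds guarantee no incidental ORFs anywhere
  for (id in w$transcripts$transcript_id) {
    got <- sc[sc$transcript_id == id, ]
    exp <- w$orfs[w$orfs$transcript_id == id, ]
    got <- got[order(got$tx_start), ]
    exp <- exp[order(exp$tx_start), ]
    expect_identical(got$tx_start, exp$tx_start)
    expect_identical(got$tx_end, exp$tx_end)
    expect_identical(got$orf_id, exp$orf_id)
    expect_identical(got$peptide, exp$peptide)
  }
  expect_identical(nrow(sc), nrow(w$orfs))
})

test_that("scan_transcripts skips ambiguous transcripts with a warning and formats orf_id", {
  genome <- c(zz = strrep("N", 200),
              ok = paste0(strrep("C", 50), "ATG", strrep("GCT", 10), "TAA",
                          strrep("C", 50)))
  txs <- tibble::tibble(
    transcript_id = c("tN", "tOK"), gene_id = c("gN", "gOK"),
    chrom = c("zz", "ok"), strand = c("+", "+"),
    biotype = c("lncRNA", "lncRNA"),
    exons = list(cbind(start = 0L, end = 150L),
                 cbind(start = 0L, end = 136L)),
    cds = list(NULL, NULL))
  expect_warning(sc <- scan_transcripts(txs, genome), "ambiguous")
  expect_identical(sc$transcript_id, "tOK")
  expect_identical(sc$orf_id, "ok:50-86:+")
  expect_identical(sc$peptide, paste0("M", strrep("A", 10)))
})
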