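make_test_gtf <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

gtf_lines_basic <- c(
  "# a comment line",
  paste0("chrA\tsrc\ttranscript\t101\t200\t.\t+\t.\t",
         'gene_id "g1"; transcript_id "t1"; transcript_biotype "protein_coding";'),
  paste0("chrA\tsrc\texon\t101\t150\t.\t+\t.\t",
         'gene_id "g1"; transcript_id "t1"; transcript_biotype "protein_coding";'),
  paste0("chrA\tsrc\texon\t171\t200\t.\t+\t.\t",
         'gene_id "g1"; transcript_id "t1"; transcript_biotype "protein_coding";'),
  paste0("chrA\tsrc\tCDS\t111\t150\t.\t+\t.\t",
         'gene_id "g1"; transcript_id "t1"; transcript_biotype "protein_coding";'),
  paste0("chrA\tsrc\tCDS\t171\t185\t.\t+\t.\t",
         'gene_id "g1"; transcript_id "t1"; transcript_biotype "protein_coding";'),
  paste0("chrA\tsrc\tstop_codon\t186\t188\t.\t+\t.\t",
         'gene_id "g1"; transcript_id "t1"; transcript_biotype "protein_coding";'),
  # GFF-ish attribute dialect with gene_biotype fallback, minus strand
  "chrB\tsrc\texon\t51\t130\t.\t-\t.\tgene_id=g2;transcript_id=t2;gene_biotype=lncRNA"
)

test_that("read_genome loads multi-record FASTA, uppercased, names trimmed", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "acgtACGT", "tt",
               ">chr2", "GGGG"), fa)
  g <- read_genome(fa)
  expect_identical(g, c(chr1 = "ACGTACGTTT", chr2 = "GGGG"))
})

test_that("read_gtf converts coordinates, merges stop codon into the CDS and handles both attribute dialects", {
  txs <- read_gtf(make_test_gtf(gtf_lines_basic))
  expect_identical(nrow(txs), 2L)
  t1 <- txs[txs$transcript_id == "t1", ]
  expect_identical(t1$gene_id, "g1")
  expect_identical(t1$biotype, "protein_coding")
  expect_identical(t1$strand, "+")
  expect_identical(unname(t1$exons[[1]]),
                   unname(cbind(c(100L, 170L), c(150L, 200L))))
  # CDS [110,150)+[170,185) with stop_codon [185,188) merged into one block
  expect_identical(unname(t1$cds[[1]]),
                   unname(cbind(c(110L, 170L), c(150L, 188L))))
  t2 <- txs[txs$transcript_id == "t2", ]
  expect_identical(t2$biotype, "lncRNA")
  expect_identical(t2$strand, "-")
  expect_identical(unname(t2$exons[[1]]), unname(cbind(50L, 130L)))
  expect_null(t2$cds[[1]])
})

test_that("read_gtf reports malformed lines with their line number", {
  bad <- c(gtf_lines_basic[2:3], "chrA\tsrc\texon\t1\t10")
  expect_error(read_gtf(make_test_gtf(bad)), "line 3")
  noid <- c(gtf_lines_basic[2], 'chrA\tsrc\texon\t1\t10\t.\t+\t.\tgene_id "g";')
  expect_error(read_gtf(make_test_gtf(noid)), "transcript_id")
  nonnum <- 'chrA\tsrc\texon\tone\t10\t.\t+\t.\ttranscript_id "t";'
  expect_error(read_gtf(make_test_gtf(nonnum)), "line 1")
})

test_that("read_gtf warns on unknown strand, exon-less transcripts and missing chromosomes", {
  lines <- c(
    gtf_lines_basic[3],
    'chrA\tsrc\texon\t10\t20\t.\t.\t.\tgene_id "gx"; transcript_id "tx_dot";',
    'chrC\tsrc\tCDS\t10\t30\t.\t+\t.\tgene_id "gy"; transcript_id "tx_noex";',
    'chrZ\tsrc\texon\t10\t30\t.\t+\t.\tgene_id "gz"; transcript_id "tz";'
  )
  path <- make_test_gtf(lines)
  expect_warning(expect_warning(read_gtf(path),
                                "unknown strand"), "no exon records")
  genome <- c(chrA = strrep("A", 300))
  warns <- capture_warnings(txs <- read_gtf(path, genome = genome))
  expect_identical(txs$transcript_id, "t1")
  expect_true(any(grepl("absent from the genome", warns)))
})

test_that("read_gtf biotype filter selects transcripts", {
  txs <- read_gtf(make_test_gtf(gtf_lines_basic), biotypes = "lncRNA")
  expect_identical(txs$transcript_id, "t2")
})

test_that("spliced_sequence concatenates exons and reverse-complements on the minus strand", {
  genome <- c(c1 = "AACCGGTTACGTACGT")
  plus <- list(transcript_id = "p", chrom = "c1", strand = "+",
               exons = cbind(start = c(0L, 8L), end = c(4L, 12L)))
  expect_identical(spliced_sequence(plus, genome), "AACCACGT")
  minus <- list(transcript_id = "m", chrom = "c1", strand = "-",
                exons = cbind(start = c(0L, 8L), end = c(4L, 12L)))
  # revcomp("AACCACGT") = "ACGTGGTT"
  expect_identical(spliced_sequence(minus, genome), "ACGTGGTT")
  out_of_bounds <- list(transcript_id = "x", chrom = "c1", strand = "+",
                        exons = cbind(start = 0L, end = 99L))
  expect_error(spliced_sequence(out_of_bounds, genome), "bounds")
})

test_that("BED12+ output round-trips through read_bed12_plus", {
  res <- get_run(1)
  path <- tempfile(fileext = ".bed")
  write_bed12_plus(res$records, path)
  back <- read_bed12_plus(path)
  expect_identical(back$orf_id, res$records$orf_id)
  expect_identical(back$orf_class, res$records$orf_class)
  expect_identical(back$peptide, res$records$peptide)
  expect_identical(back$length_codons, res$records$length_codons)
  expect_identical(back$blocks, unname(res$records$blocks))
  expect_equal(back$orf_score, res$records$orf_score, tolerance = 1e-5)
  expect_equal(back$rrs, res$records$rrs, tolerance = 1e-5)
  expect_equal(back$te, res$records$te, tolerance = 1e-5)
  # header present and 25 columns per data line
  lines <- readLines(path)
  expect_match(lines[1], "^#chrom\t")
  expect_true(all(lengths(strsplit(lines[-1], "\t")) == 25L))
})

test_that("BED12+ of an empty record set is just the header", {
  res <- get_run(1)
  empty <- res$records[0, , drop = FALSE]
  path <- tempfile(fileext = ".bed")
  write_bed12_plus(empty, path)
  expect_identical(length(readLines(path)), 1L)
  expect_identical(nrow(read_bed12_plus(path)), 0L)
})
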