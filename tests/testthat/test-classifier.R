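test_that("classify_orf assigns every positional class correctly on known cases", {
  # CDS [100, 160)
  expect_identical(classify_orf(100L, 160L, 100L, 160L), "canonical")
  expect_identical(classify_orf(88L, 160L, 100L, 160L), "canonical_extended")
  expect_identical(classify_orf(112L, 160L, 100L, 160L), "canonical_truncated")
  expect_identical(classify_orf(10L, 70L, 100L, 160L), "nuORF")
  expect_identical(classify_orf(10L, 100L, 100L, 160L), "nuORF")   # abuts start
  expect_identical(classify_orf(80L, 131L, 100L, 160L), "ouORF")
  expect_identical(classify_orf(80L, 200L, 100L, 160L), "ouORF")   # spans CDS
  expect_identical(classify_orf(160L, 220L, 100L, 160L), "ndORF")  # abuts end
  expect_identical(classify_orf(200L, 260L, 100L, 160L), "ndORF")
  expect_identical(classify_orf(140L, 200L, 100L, 160L), "odORF")
  expect_identical(classify_orf(112L, 151L, 100L, 160L), "internal")
  expect_identical(classify_orf(10L, 70L), "ncORF")
  expect_identical(classify_orf(10L, 70L, NA, NA), "ncORF")
})

test_that("cds_tx_span maps spliced CDS blocks into transcript coordinates on both strands", {
  plus <- list(strand = "+",
               exons = cbind(start = c(0L, 20L), end = c(10L, 30L)),
               cds = cbind(start = c(4L, 20L), end = c(10L, 26L)))
  expect_identical(smorfkit:::cds_tx_span(plus), c(4L, 16L))
  minus <- list(strand = "-",
                exons = cbind(start = c(0L, 20L), end = c(10L, 30L)),
                cds = cbind(start = 22L, end = 28L))
  # tx length 20; genomic 22..27 -> plus offsets 12..17 -> minus 7..2
  expect_identical(smorfkit:::cds_tx_span(minus), c(2L, 8L))
  none <- list(strand = "+", exons = cbind(start = 0L, end = 30L), cds = NULL)
  expect_null(smorfkit:::cds_tx_span(none))
})

test_that("classify_orfs warns when a non-coding biotype carries a CDS", {
  txs <- tibble::tibble(
    transcript_id = "t", gene_id = "g", chrom = "c", strand = "+",
    biotype = "lncRNA",
    exons = list(cbind(start = 0L, end = 300L)),
    cds = list(cbind(start = 60L, end = 120L)))
  orfs <- tibble::tibble(transcript_id = "t", tx_start = 0L, tx_end = 30L)
  expect_warning(got <- classify_orfs(orfs, txs), "non-coding biotype")
  expect_identical(got$orf_class, "nuORF")
})

test_that("collapse_unique merges isoform duplicates by class precedence and drops internal ORFs", {
  b1 <- cbind(start = 100L, end = 160L)
  b2 <- cbind(start = 300L, end = 345L)
  orfs <- tibble::tibble(
    transcript_id = c("tA", "tB", "tC", "tD"),
    gene_id = c("gA", "gB", "gC", "gD"),
    chrom = "c", strand = "+",
    blocks = list(b1, b1, b2, b2),
    orf_class = c("nuORF", "ouORF", "internal", "ncORF"),
    score = c(1, 2, 3, 4))
  out <- collapse_unique(orfs)
  expect_identical(nrow(out), 2L)
  expect_identical(attr(out, "n_internal"), 1L)
  expect_identical(attr(out, "n_merged"), 1L)
  expect_identical(attr(out, "n_nested"), 0L)
  merged <- out[out$blocks |> vapply(function(b) b[1, "start"], integer(1)) == 100L, ]
  expect_identical(merged$orf_class, "ouORF")       # higher precedence wins
  expect_identical(merged$score, 2)                 # metrics follow the winner
  expect_identical(merged$host_transcripts[[1]], c("tA", "tB"))
  expect_identical(merged$gene_ids[[1]], c("gA", "gB"))
})

test_that("collapse_unique removes in-frame nested ORFs but keeps out-of-frame overlaps", {
  big <- cbind(start = 0L, end = 30L)
  in_frame <- cbind(start = 9L, end = 21L)       # codon starts subset of big's
  out_frame <- cbind(start = 10L, end = 22L)     # shifted by 1: different frame
  orfs <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3"),
    gene_id = "g", chrom = "c", strand = "+",
    blocks = list(big, in_frame, out_frame),
    orf_class = "ncORF")
  out <- collapse_unique(orfs)
  expect_identical(attr(out, "n_nested"), 1L)
  starts <- vapply(out$blocks, function(b) b[1, "start"], integer(1))
  expect_setequal(starts, c(0L, 10L))
})

test_that("collapse_unique on an empty set returns an empty table with zero counters", {
  orfs <- tibble::tibble(
    transcript_id = character(0), gene_id = character(0),
    chrom = character(0), strand = character(0),
    blocks = list(), orf_class = character(0))
  out <- collapse_unique(orfs)
  expect_identical(nrow(out), 0L)
  expect_identical(attr(out, "n_internal"), 0L)
  expect_identical(attr(out, "n_merged"), 0L)
  expect_identical(attr(out, "n_nested"), 0L)
})

test_that("class_composition counts and fractions are consistent", {
  rec <- tibble::tibble(orf_class = c("ncORF", "ncORF", "nuORF"))
  comp <- class_composition(rec)
  expect_identical(comp$orf_class, c("ncORF", "nuORF"))
  expect_identical(comp$count, c(2L, 1L))
  expect_equal(sum(comp$fraction), 1)
  empty <- class_composition(rec[0, , drop = FALSE])
  expect_identical(nrow(empty), 0L)
})
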