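# A deterministic P-site track putting `count` P-sites at given positions.
manual_track <- function(pos, count, strand = "+", chrom = "c",
                         library_size = 1000L) {
  smorfkit:::make_track(rep(chrom, sum(count)), rep(strand, sum(count)),
                        rep(pos, count), library_size)
}

test_that("orf_score follows the chi-square form and its sign convention", {
  f <- c(17, 3, 2)
  fbar <- mean(f)
  expect_equal(orf_score(f), log2(1 + sum((f - fbar)^2 / fbar)))
  expect_equal(orf_score(c(3, 17, 2)), -log2(1 + sum((f - fbar)^2 / fbar)))
  expect_equal(orf_score(c(2, 3, 17)), -log2(1 + sum((f - fbar)^2 / fbar)))
  expect_identical(orf_score(c(0, 0, 0)), 0)
  expect_equal(orf_score(c(5, 5, 5)), 0)
  expect_error(orf_score(c(-1, 0, 0)), "negative")
  expect_error(orf_score(c(1, 2)))
})

test_that("orf_frame_counts sums interior codons only and caps per-codon pile-ups", {
  # 12-codon ORF at [30, 66): frame-0 P-sites, 2 per codon
  blocks <- cbind(start = 30L, end = 66L)
  tr <- manual_track(seq(30L, 63L, by = 3L), rep(2L, 12))
  fc <- orf_frame_counts(blocks, "+", "c", tr)
  expect_identical(unname(fc), c(20, 0, 0))     # 10 interior codons x 2
  # one interior codon with a 1000-count pile-up is scaled to the 97.5th
  # percentile of per-codon totals
  tr2 <- manual_track(seq(30L, 63L, by = 3L), c(2L, rep(2L, 5), 1000L, rep(2L, 5)))
  fc2 <- orf_frame_counts(blocks, "+", "c", tr2)
  cap <- stats::quantile(c(rep(2, 9), 1000), 0.975, names = FALSE)
  expect_equal(unname(fc2), c(9 * 2 + cap, 0, 0))
  # off-frame signal lands in the right frame bin, also on the minus strand
  blocks3 <- cbind(start = 0L, end = 30L)
  tr3 <- manual_track(c(25L, 24L, 23L), c(1L, 1L, 1L), strand = "-")
  # minus-strand tx positions: 29..0; genomic 25,24,23 = offsets 4,5,6, so
  # interior codon 2 holds (0,1,1) and codon 3 holds (1,0,0); the percentile
  # cap rescales codon 2 (the per-codon maximum)
  fc3 <- orf_frame_counts(blocks3, "-", "c", tr3)
  cap3 <- stats::quantile(c(2, 1, rep(0, 6)), 0.975, names = FALSE)
  expect_equal(unname(fc3), c(1, cap3 / 2, cap3 / 2))
})

test_that("codon_coverage is the fraction of interior codons with frame-0 signal", {
  blocks <- cbind(start = 0L, end = 30L)   # 10 codons, 8 interior
  tr <- manual_track(c(3L, 6L, 9L, 12L), rep(1L, 4))
  expect_equal(codon_coverage(blocks, "+", "c", tr), 4 / 8)
  # frame-1 signal does not count
  tr2 <- manual_track(c(4L, 7L), c(1L, 1L))
  expect_equal(codon_coverage(blocks, "+", "c", tr2), 0)
  tiny <- cbind(start = 0L, end = 6L)
  expect_equal(codon_coverage(tiny, "+", "c", tr), 0)
})

test_that("rrs applies pseudocounts and is missing for empty downstream regions", {
  expect_equal(rrs(60, 0, 90, 150, 90, 150),
               ((60 + 1) / 90) / ((0 + 1) / 150) /
                 (((90 + 1) / 90) / ((150 + 1) / 150)))
  expect_identical(rrs(60, 0, 90, 150, 90, 0), NA_real_)
  expect_identical(rrs(60, 0, 90, 150, 90, NA), NA_real_)
  # equal densities on both sides give a score near 1
  expect_equal(rrs(100, 100, 200, 200, 300, 300), 1)
})

test_that("fpkm and translation efficiency have their closed forms", {
  expect_equal(fpkm(60, 90, 1e6), 60 * 1e9 / (90 * 1e6))
  expect_error(fpkm(1, 0, 1e6), "zero-length")
  expect_error(fpkm(1, 10, 0), "library")
  expect_equal(translation_efficiency(10, 5), 2)
  expect_identical(translation_efficiency(10, 0), NA_real_)
})

test_that("score_orfs computes metrics against deterministic tracks", {
  txs <- tibble::tibble(
    transcript_id = "t", gene_id = "g", chrom = "c", strand = "+",
    biotype = "lncRNA",
    exons = list(cbind(start = 0L, end = 300L)),
    cds = list(NULL))
  orfs <- tibble::tibble(
    transcript_id = "t", chrom = "c", strand = "+",
    tx_start = 30L, tx_end = 120L,
    blocks = list(cbind(start = 30L, end = 120L)))
  # 2 P-sites on every codon start of the ORF (30 codons)
  rpf <- manual_track(seq(30L, 117L, by = 3L), rep(2L, 30),
                      library_size = 1000L)
  # RNA: one 5' end per transcript base
  rna <- manual_track(0:299, rep(1L, 300), library_size = 2000L)
  got <- score_orfs(orfs, txs, rpf, rna, rna)
  expect_identical(unname(got$frame_counts[[1]]), c(56, 0, 0))
  expect_equal(got$orf_score, log2(1 + 2 * 56))
  expect_equal(got$coverage, 1)
  expect_identical(got$rpf_count, 60L)
  expect_identical(got$rna_count, 90L)
  expect_equal(got$rpf_fpkm, 60 * 1e9 / (90 * 1000))
  expect_equal(got$rna_fpkm, 90 * 1e9 / (90 * 2000))
  expect_equal(got$te, got$rpf_fpkm / got$rna_fpkm)
  # downstream window [120, 270): no RPF there
  expect_equal(got$rrs,
               ((60 + 1) / 90) / ((0 + 1) / 150) /
                 (((90 + 1) / 90) / ((150 + 1) / 150)))
})

test_that("score_orfs caps the downstream region at the CDS start for upstream ORFs", {
  txs <- tibble::tibble(
    transcript_id = "t", gene_id = "g", chrom = "c", strand = "+",
    biotype = "protein_coding",
    exons = list(cbind(start = 0L, end = 300L)),
    cds = list(cbind(start = 60L, end = 183L)))
  rpf <- manual_track(0L, 1L, library_size = 100L)
  rna <- manual_track(0:299, rep(1L, 300), library_size = 100L)
  mk <- function(s, e) tibble::tibble(
    transcript_id = "t", chrom = "c", strand = "+",
    tx_start = s, tx_end = e, blocks = list(cbind(start = s, end = e)))
  # overlapping upstream ORF: region [123, min(273, 60)) is empty -> NA
  ou <- score_orfs(mk(30L, 123L), txs, rpf, rna, rna)
  expect_identical(ou$rrs, NA_real_)
  # fully upstream ORF: region [45, 60) survives, 15 nt long
  nu <- score_orfs(mk(0L, 45L), txs, rpf, rna, rna)
  expect_equal(nu$rrs,
               ((1 + 1) / 45) / ((0 + 1) / 15) /
                 (((45 + 1) / 45) / ((15 + 1) / 15)))
  # an ORF sharing the CDS stop is not "upstream-type": full window applies
  ext <- score_orfs(mk(30L, 183L), txs, rpf, rna, rna)
  expect_false(is.na(ext$rrs))
})
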