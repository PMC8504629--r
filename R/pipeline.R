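#' Pipeline configuration
#'
#' Assembles the filter thresholds and scanning/calibration parameters used by
#' [run_smorf_pipeline()], optionally overlaid from a YAML file. Every
#' effective value is echoed in the run report.
#'
#' @param ... named overrides of the defaults.
#' @param yaml optional path to a YAML file of overrides (applied before
#'   `...`).
#' @return named list of parameters:
#' \describe{
#'   \item{min_codons, max_codons}{ORF length bounds in codons (5, 100).}
#'   \item{start_codons}{permitted start codons (`"ATG"`).}
#'   \item{min_rna_fpkm}{host-transcript expression gate (1).}
#'   \item{min_coverage}{minimum interior codon coverage (0.5).}
#'   \item{min_orf_score}{minimum ORFScore (6).}
#'   \item{min_rrs}{minimum ribosome release score (5; skipped when the
#'     downstream region is empty).}
#'   \item{downstream_window}{RRS downstream window in nt (150).}
#'   \item{read_lengths}{candidate RPF read lengths (25:34).}
#'   \item{min_mapq}{mapping-quality threshold for unique mapping (10).}
#'   \item{min_reads_per_length, min_frame0_frac}{calibration quality gates
#'     (100 reads, 0.5).}
#' }
#' @export
smorf_config <- function(..., yaml = NULL) {
  cfg <- list(
    min_codons = 5L, max_codons = 100L, start_codons = "ATG",
    min_rna_fpkm = 1, min_coverage = 0.5, min_orf_score = 6, min_rrs = 5,
    downstream_window = 150L, read_lengths = 25:34, min_mapq = 10L,
    min_reads_per_length = 100L, min_frame0_frac = 0.5
  )
  if (!is.null(yaml)) {
    over <- yaml::read_yaml(yaml)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0L) abort(paste("unknown config field:", paste(bad, collapse = ", ")))
  cfg[names(dots)] <- dots
  cfg
}

#' Run the full smORF discovery pipeline
#'
#' Orchestrates scan -> calibrate -> score -> filter -> classify -> collapse:
#' putative smORFs are enumerated on every transcript, P-site offsets are
#' calibrated from a metagene at annotated start codons, each ORF is scored
#' (ORFScore, coverage, RRS, FPKM, TE), and the filter cascade
#' (host RNA FPKM, coverage, ORFScore, RRS) is applied before isoform
#' duplicates are merged and nested ORFs removed.
#'
#' @param genome_fa genome FASTA path.
#' @param gtf transcript annotation GTF path.
#' @param ribo_bam aligned ribosome-profiling reads (indexed BAM).
#' @param rna_bam aligned RNA-Seq reads (indexed BAM).
#' @param config parameter list from [smorf_config()].
#' @param out_dir optional output directory; when given, the BED12+ table
#'   (`smorfs.bed`), per-ORF metrics TSV (`metrics.tsv`), class composition
#'   TSV (`class_composition.tsv`), offset table (`psite_offsets.tsv`) and
#'   run report (`run_report.json`) are written there.
#' @return an object of class `smorf_result`: list with `records` (tibble of
#'   surviving unique smORFs), `report` (stage counts and effective
#'   parameters), `offsets` (calibration table) and `composition`.
#' @export
run_smorf_pipeline <- function(genome_fa, gtf, ribo_bam, rna_bam,
                               config = smorf_config(), out_dir = NULL) {
  stage <- function(msg, ...) message(sprintf(paste0("[smorfkit] ", msg), ...))

  stage("reading genome and annotation")
  genome <- read_genome(genome_fa)
  txs <- read_gtf(gtf, genome = genome)
  stage("%d transcripts", nrow(txs))

  stage("reading alignments")
  rna_reads <- read_alignments(rna_bam, config$min_mapq)
  ribo_reads <- read_alignments(ribo_bam, config$min_mapq)
  rna_track <- build_end_track(rna_reads)
  rna_cov <- build_coverage_track(rna_reads)

  stage("host transcript expression")
  rna_lib <- attr(rna_track, "library_size")
  tx_rna_fpkm <- vapply(seq_len(nrow(txs)), function(i) {
    ex <- txs$exons[[i]]
    cnt <- blocks_track_count(ex, txs$strand[i], txs$chrom[i], rna_track)
    fpkm(cnt, block_width(ex), rna_lib)
  }, numeric(1))
  names(tx_rna_fpkm) <- txs$transcript_id

  stage("scanning transcripts for putative smORFs")
  orfs <- scan_transcripts(txs, genome, config$min_codons, config$max_codons,
                           config$start_codons)
  n_scanned <- nrow(orfs)
  stage("%d putative ORFs on %d transcripts", n_scanned,
        length(unique(orfs$transcript_id)))

  stage("calibrating P-site offsets")
  offsets <- metagene_offsets(ribo_reads, txs, config$read_lengths,
                              config$min_mapq, config$min_reads_per_length,
                              config$min_frame0_frac)
  rpf_track <- build_psite_track(ribo_reads, offsets)

  stage("scoring ORFs")
  orfs$host_rna_fpkm <- unname(tx_rna_fpkm[orfs$transcript_id])
  orfs <- score_orfs(orfs, txs, rpf_track, rna_track, rna_cov,
                     config$downstream_window)

  # AND-cascade; each ORF is charged to the first stage it fails
  pass_expr <- orfs$host_rna_fpkm >= config$min_rna_fpkm
  pass_cov <- orfs$coverage >= config$min_coverage
  pass_score <- orfs$orf_score >= config$min_orf_score
  pass_rrs <- is.na(orfs$rrs) | orfs$rrs >= config$min_rrs
  keep <- pass_expr & pass_cov & pass_score & pass_rrs
  fail_stage <- dplyr::case_when(
    !pass_expr ~ "host_expression",
    !pass_cov ~ "coverage",
    !pass_score ~ "orf_score",
    !pass_rrs ~ "rrs",
    TRUE ~ "pass"
  )
  stage("filters: %d of %d ORF-transcript pairs pass", sum(keep), n_scanned)

  surv <- classify_orfs(orfs[keep, , drop = FALSE], txs)
  records <- collapse_unique(surv)
  records$conservation_score <- NA_real_
  composition <- class_composition(records)
  stage("%d unique smORFs after collapse", nrow(records))

  report <- list(
    parameters = config,
    inputs = list(genome = genome_fa, gtf = gtf, ribo_bam = ribo_bam,
                  rna_bam = rna_bam),
    library_sizes = list(rpf = attr(rpf_track, "library_size"),
                         rna = rna_lib),
    n_transcripts = nrow(txs),
    stage_counts = c(list(
      n_scanned = n_scanned,
      n_passed_filters = sum(keep)),
      as.list(table(fail_stage[fail_stage != "pass"])),
      list(n_internal = attr(records, "n_internal"),
           n_isoform_merged = attr(records, "n_merged"),
           n_nested_removed = attr(records, "n_nested"),
           n_final = nrow(records))),
    offsets = offsets
  )

  res <- structure(list(records = records, report = report,
                        offsets = offsets, composition = composition),
                   class = "smorf_result")
  if (!is.null(out_dir)) write_smorf_outputs(res, out_dir)
  res
}

#' Write the output files of a pipeline run
#'
#' @param result a `smorf_result` from [run_smorf_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_smorf_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_bed12_plus(result$records, file.path(out_dir, "smorfs.bed"))
  met <- tidy(result)
  write.table(met, file.path(out_dir, "metrics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(result$composition, file.path(out_dir, "class_composition.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$offsets, file.path(out_dir, "psite_offsets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  rep <- result$report
  rep$offsets <- NULL
  jsonlite::write_json(rep, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.smorf_result <- function(x, ...) {
  cat("smORF discovery result\n")
  cat(sprintf("  %d putative ORFs scanned, %d unique smORFs retained\n",
              x$report$stage_counts$n_scanned,
              x$report$stage_counts$n_final))
  acc <- x$offsets[x$offsets$accepted, , drop = FALSE]
  cat(sprintf("  P-site offsets: %s\n",
              paste(sprintf("%dnt->%d", acc$read_length, acc$offset),
                    collapse = ", ")))
  if (nrow(x$composition) > 0) {
    cat("  class composition:\n")
    for (i in seq_len(nrow(x$composition))) {
      cat(sprintf("    %-20s %4d (%.1f%%)\n", x$composition$orf_class[i],
                  x$composition$count[i], 100 * x$composition$fraction[i]))
    }
  }
  invisible(x)
}

#' Tidy the per-smORF table of a pipeline result
#'
#' @param x a `smorf_result`.
#' @param ... unused.
#' @return a tibble with one row per unique smORF and flat columns (genomic
#'   span, class, hosts, metrics, peptide).
#' @exportS3Method generics::tidy
#' @export
tidy.smorf_result <- function(x, ...) {
  r <- x$records
  if (nrow(r) == 0L) {
    return(tibble(orf_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0), strand = character(0),
                  orf_class = character(0), length_codons = integer(0)))
  }
  tibble(
    orf_id = r$orf_id, chrom = r$chrom,
    start = map_int(r$blocks, function(b) b[1, "start"]),
    end = map_int(r$blocks, function(b) b[nrow(b), "end"]),
    strand = r$strand, orf_class = r$orf_class,
    n_exons = map_int(r$blocks, nrow),
    length_codons = r$length_codons,
    host_transcripts = map_chr(r$host_transcripts, paste, collapse = ","),
    gene_ids = map_chr(r$gene_ids, paste, collapse = ","),
    orf_score = r$orf_score, coverage = r$coverage, rrs = r$rrs,
    rpf_fpkm = r$rpf_fpkm, rna_fpkm = r$rna_fpkm, te = r$te,
    peptide = r$peptide
  )
}

#' One-row summary of a pipeline result
#'
#' @param x a `smorf_result`.
#' @param ... unused.
#' @return a one-row tibble with scan/filter counts and library sizes.
#' @exportS3Method generics::glance
#' @export
glance.smorf_result <- function(x, ...) {
  sc <- x$report$stage_counts
  tibble(
    n_scanned = sc$n_scanned,
    n_passed_filters = sc$n_passed_filters,
    n_unique = sc$n_final,
    n_classes = nrow(x$composition),
    n_accepted_read_lengths = sum(x$offsets$accepted),
    rpf_library = x$report$library_sizes$rpf,
    rna_library = x$report$library_sizes$rna
  )
}
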