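test_that("FASTA reading normalizes to uppercase RNA and preserves order", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">b desc ignored", "acgu", ">c", "GGNN"), p)
  seqs <- read_fasta(p)
  expect_identical(names(seqs), c("a", "b", "c"))
  expect_identical(unname(seqs), c("ACGU", "ACGU", "GGNN"))

  writeLines(character(0), p)
  expect_length(read_fasta(p), 0L)

  writeLines(c(">a", "ACXT"), p)
  expect_error(read_fasta(p), "illegal character.*'a'")
  writeLines(c("ACGT"), p)
  expect_error(read_fasta(p), "malformed FASTA")
  writeLines(c(">a", "ACGT", ">a", "GG"), p)
  expect_error(read_fasta(p), "duplicated")
})

test_that("FASTA write/read round trip reproduces normalized content", {
  set.seed(5)
  seqs <- stats::setNames(random_rna(5, 73), paste0("s", 1:5))
  p <- tempfile(fileext = ".fa")
  write_fasta(seqs, p)
  expect_identical(read_fasta(p), seqs)
})

test_that("GTF transcript models derive strand-aware lengths and junctions", {
  ## exons [100,200)+[300,400), CDS [150,350): junction inside CDS
  p <- write_gtf_lines(c(
    gtf_line("chr1", "exon", 101, 200, "+", "g1", "t1"),
    gtf_line("chr1", "exon", 301, 400, "+", "g1", "t1"),
    gtf_line("chr1", "CDS", 151, 350, "+", "g1", "t1")))
  m <- read_transcript_models(p)
  expect_equal(m$utr5_len, 50L)
  expect_equal(m$cds_len, 100L)
  expect_equal(m$utr3_len, 50L)
  expect_identical(m$stop_rel_junctions[[1]], integer(0))

  ## same exons, CDS [120,180): junction 20 nt downstream of stop
  p <- write_gtf_lines(c(
    gtf_line("chr1", "exon", 101, 200, "+", "g1", "t1"),
    gtf_line("chr1", "exon", 301, 400, "+", "g1", "t1"),
    gtf_line("chr1", "CDS", 121, 180, "+", "g1", "t1")))
  m <- read_transcript_models(p)
  expect_equal(m$utr5_len, 20L)
  expect_equal(m$cds_len, 60L)
  expect_equal(m$utr3_len, 120L)
  expect_identical(m$stop_rel_junctions[[1]], 20L)

  ## minus-strand mirror of case 1: identical derived lengths
  p <- write_gtf_lines(c(
    gtf_line("chr1", "exon", 101, 200, "-", "g1", "t1"),
    gtf_line("chr1", "exon", 301, 400, "-", "g1", "t1"),
    gtf_line("chr1", "CDS", 151, 350, "-", "g1", "t1")))
  m <- read_transcript_models(p)
  expect_equal(m$utr5_len, 50L)
  expect_equal(m$cds_len, 100L)
  expect_equal(m$utr3_len, 50L)
  expect_identical(m$stop_rel_junctions[[1]], integer(0))

  ## transcript without CDS excluded with warning
  p <- write_gtf_lines(c(
    gtf_line("chr1", "exon", 101, 200, "+", "g1", "t1"),
    gtf_line("chr1", "exon", 101, 400, "+", "g2", "t2"),
    gtf_line("chr1", "CDS", 121, 380, "+", "g2", "t2")))
  expect_warning(m <- read_transcript_models(p), "no CDS")
  expect_identical(m$transcript_id, "t2")
})

test_that("3'UTR end updates truncate, extend, and skip invalid ends", {
  p <- write_gtf_lines(c(
    gtf_line("chr1", "exon", 1, 1000, "+", "g1", "t1"),
    gtf_line("chr1", "CDS", 101, 500, "+", "g1", "t1")))
  m <- read_transcript_models(p)
  expect_equal(m$utr3_len, 500L)

  ## truncation: terminal base 300 nt downstream of stop
  bed <- data.frame(chrom = "chr1", start = 799L, end = 800L,
                    name = "g1", strand = "+")
  expect_equal(update_utr3_ends(m, bed)$utr3_len, 300L)

  ## no record for the gene: unchanged
  bed2 <- data.frame(chrom = "chr1", start = 799L, end = 800L,
                     name = "other", strand = "+")
  expect_equal(update_utr3_ends(m, bed2)$utr3_len, 500L)

  ## end beyond the terminal exon: stop-to-end distance along the genome
  bed3 <- data.frame(chrom = "chr1", start = 1099L, end = 1100L,
                     name = "g1", strand = "+")
  expect_equal(update_utr3_ends(m, bed3)$utr3_len, 600L)

  ## end upstream of the stop codon: skipped with warning
  bed4 <- data.frame(chrom = "chr1", start = 250L, end = 251L,
                     name = "g1", strand = "+")
  expect_warning(m4 <- update_utr3_ends(m, bed4), "upstream")
  expect_equal(m4$utr3_len, 500L)
})

test_that("representative transcript is longest 3'UTR with id tie-break", {
  m <- data.frame(gene_id = c("g1", "g1", "g2", "g2"),
                  transcript_id = c("t2", "t1", "tB", "tA"),
                  utr3_len = c(100L, 300L, 200L, 200L),
                  stringsAsFactors = FALSE)
  r <- representative_transcripts(m)
  expect_identical(r$transcript_id[r$gene_id == "g1"], "t1")
  expect_identical(r$transcript_id[r$gene_id == "g2"], "tA")
})

test_that("run configuration validates fields and reads YAML overrides", {
  cfg <- run_config()
  expect_equal(cfg$derepression_threshold, 0.2)
  expect_equal(cfg$enrichment_alpha, 0.005)
  expect_equal(cfg$n_cohorts, 1000L)
  expect_equal(cfg$n_shuffle_cohorts_seed, 100L)
  expect_error(run_config(n_bins = 0), "n_bins")
  expect_error(run_config(derepression_threshold = -1), "thresholds")

  y <- tempfile(fileext = ".yaml")
  writeLines(c("n_bins: 6", "enrichment_alpha: 0.01"), y)
  cfg2 <- read_run_config(y)
  expect_equal(cfg2$n_bins, 6L)
  expect_equal(cfg2$enrichment_alpha, 0.01)
  expect_equal(cfg2$n_cohorts, 1000L)
  writeLines("not_a_field: 1", y)
  expect_error(read_run_config(y), "unknown config field")
})

test_that("expression tables are validated on read", {
  p <- tempfile(fileext = ".tsv")
  df <- data.frame(gene_id = c("g1", "g1"), condition = c("a", "b"),
                   fpkm = c(1, 2), fpm = c(3, 4))
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_expression_table(p)), 2L)
  df$condition <- "a"
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_table(p), "duplicated")
})
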