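## Shared synthetic fixtures, built once per test run.

.umd_test_cache <- new.env(parent = emptyenv())

## moderate dataset with all planted categories (fractions 0.1, seed 42)
shared_dataset <- function() {
  if (!exists("ds", envir = .umd_test_cache)) {
    assign("ds",
           generate_umd_dataset(synthetic_config(n_genes = 250,
                                                 rng_seed = 42L)),
           envir = .umd_test_cache)
  }
  get("ds", envir = .umd_test_cache)
}

## a tiny hand-written GTF fixture written to a temp file
write_gtf_lines <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

gtf_line <- function(chrom, type, start1, end1, strand, gene, tx) {
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
          chrom, type, start1, end1, strand, gene, tx)
}

## minimal family table for hand-constructed seeds
families_from_seeds <- function(seeds28) {
  mirnas <- stats::setNames(
    vapply(seeds28, function(s) {
      paste0("A", s, "ACGUACGUACGUA")
    }, character(1)),
    paste0("mir-test-", seq_along(seeds28)))
  build_families(mirnas,
                 data.frame(mirna_id = names(mirnas),
                            abundance = rev(seq_along(mirnas))))
}
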