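test_that("generation is deterministic for a fixed configuration", {
  cfg <- synthetic_config(n_genes = 40, rng_seed = 101)
  d1 <- generate_umd_dataset(cfg)
  d2 <- generate_umd_dataset(cfg)
  expect_identical(d1$utr3, d2$utr3)
  expect_identical(d1$mirnas, d2$mirnas)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$ground_truth, d2$ground_truth)
  d3 <- generate_umd_dataset(synthetic_config(n_genes = 40, rng_seed = 102))
  expect_false(identical(d1$utr3, d3$utr3))
})

test_that("miRNA generation hits the CAG-seed fraction exactly", {
  set.seed(1)
  m <- generate_mirnas(synthetic_config(n_mirnas = 10, frac_cag_seed = 0.5))
  seeds <- substr(m$seqs, 2, 8)
  expect_equal(sum(grepl("CAG", seeds, fixed = TRUE)), 5L)
  expect_true(all(nchar(m$seqs) %in% 21:22))
  expect_false(anyDuplicated(seeds) > 0)

  m0 <- generate_mirnas(synthetic_config(n_mirnas = 10, frac_cag_seed = 0))
  expect_equal(sum(grepl("CAG", substr(m0$seqs, 2, 8), fixed = TRUE)), 0L)
  expect_error(generate_mirnas(synthetic_config(n_mirnas = 1,
                                                frac_cag_seed = 0.2)),
               "unattainable")
})

test_that("planted categories appear at the configured counts", {
  ds <- shared_dataset()
  gt <- ds$ground_truth
  expect_equal(sum(gt$spurious), 25L)
  expect_equal(sum(gt$nmd_annotated), 25L)
  expect_equal(sum(gt$dej), 25L)
  expect_equal(sum(gt$cryptic), 25L)
  expect_equal(sum(gt$offtarget), 25L)
  expect_equal(sum(gt$category == "clean"), 125L)
  ## dEJ genes carry an evidence junction > 50 nt downstream of the stop
  ev <- map_junctions_to_transcripts(ds$models, ds$junctions)
  dej_t <- detect_dej(ds$models, ev)
  expect_setequal(unique(ds$models$gene_id[dej_t]), gt$gene_id[gt$dej])
})

test_that("expected fold changes encode the per-site effect model", {
  ds <- shared_dataset()
  gt <- ds$ground_truth
  cfg <- ds$config
  expect_equal(gt$exp_lfc_siUPF1,
               cfg$beta_site * gt$n_sites + cfg$beta_cug_bonus * gt$n_sites_cug)
  expect_true(all(gt$exp_lfc_siUPF1[gt$n_sites == 0] == 0))
  expect_true(all(gt$exp_lfc_siDicer1 == 0))
  expect_true(all(gt$exp_lfc_siUPF1_siDicer1 == 0))
  expect_equal(gt$exp_lfc_siSMG7, cfg$alpha_smg7 * gt$exp_lfc_siUPF1)
  ## spot-check the worked example: 5 effective sites, no CUG bonus
  expect_equal(unname(cfg$beta_site * 5), 0.4)
  expect_equal(unname(cfg$alpha_smg7 * cfg$beta_site * 5), 0.16)
})

test_that("planted site counts scale with length at the configured density", {
  cfg <- synthetic_config(n_genes = 400, utr3_len_range = c(1000, 1000),
                          site_density = 2, frac_spurious = 0,
                          frac_nmd_annotated = 0, frac_dej = 0,
                          frac_cryptic = 0, frac_offtarget = 0,
                          frac_low_expression = 0, rng_seed = 33)
  ds <- generate_umd_dataset(cfg)
  m <- mean(ds$ground_truth$n_sites)
  ## Poisson(2) mean over 400 genes: s.e. ~ sqrt(2/400)
  expect_lt(abs(m - 2), 4 * sqrt(2 / 400))
})

test_that("scanning the generated UTRs recovers the planted sites exactly", {
  ds <- shared_dataset()
  sites <- scan_sites(ds$utr3, ds$families)
  got <- effective_site_counts(sites, ds$ground_truth$gene_id)
  expect_identical(unname(got), ds$ground_truth$n_sites)
  ## genes without planted sites are exactly the 6mer-free nontargets
  all_sites <- scan_sites(ds$utr3, ds$families, types = SITE_TYPES)
  nont <- select_nontargets(ds$ground_truth$gene_id, all_sites)
  planted_carriers <- unique(
    ds$planted_sites$gene_id[ds$planted_sites$site_type != "offset6mer"])
  expect_setequal(nont,
                  setdiff(ds$ground_truth$gene_id, planted_carriers))
})

test_that("written files round-trip through the standard format readers", {
  ds <- shared_dataset()
  dir <- file.path(tempdir(), "umd_ds")
  paths <- write_umd_dataset(ds, dir)
  ## GTF -> models reproduces every derived quantity
  m <- read_transcript_models(paths["gtf"])
  m <- m[match(ds$models$transcript_id, m$transcript_id), ]
  expect_equal(m$utr5_len, ds$models$utr5_len)
  expect_equal(m$cds_len, ds$models$cds_len)
  expect_equal(m$utr3_len, ds$models$utr3_len)
  expect_identical(m$stop_rel_junctions, ds$models$stop_rel_junctions)
  ## FASTA round trip
  expect_identical(read_fasta(paths["utr3"]), ds$utr3)
  expect_identical(read_fasta(paths["mirnas"]), ds$mirnas)
  ## expression TSV round trip
  expr <- read_expression_table(paths["expression"])
  expect_equal(nrow(expr), nrow(ds$expression))
})

test_that("simulated expression keeps FPM proportional to FPKM by length", {
  ds <- shared_dataset()
  expr <- ds$expression
  kb <- ds$models$spliced_len[match(expr$gene_id,
                                    ds$models$gene_id)] / 1000
  expect_equal(expr$fpm, expr$fpkm * kb)
  ctrl <- expr[expr$condition == "control", ]
  gt <- ds$ground_truth
  expect_true(all(ctrl$fpkm[match(gt$gene_id[gt$zero_control],
                                  ctrl$gene_id)] == 0))
})
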