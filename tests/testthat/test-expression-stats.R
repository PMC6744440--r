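make_expr <- function(fpkm_ctrl, fpkm_kd, genes = paste0("g", seq_along(fpkm_ctrl))) {
  rbind(data.frame(gene_id = genes, condition = "control",
                   fpkm = fpkm_ctrl, fpm = fpkm_ctrl),
        data.frame(gene_id = genes, condition = "kd",
                   fpkm = fpkm_kd, fpm = fpkm_kd))
}

test_that("log2 fold changes are plain FPKM ratios without pseudocounts", {
  expr <- make_expr(c(2, 2, 8), c(2, 4, 2))
  fc <- compute_log2fc(expr, "kd", "control")
  expect_equal(fc$log2fc, c(0, 1, -2))
  expr0 <- make_expr(c(0, 1), c(1, 1))
  expect_error(compute_log2fc(expr0, "kd", "control"), "zero control")
})

test_that("equal-count binning splits remainders to the shortest bins", {
  rec <- data.frame(gene_id = sprintf("g%02d", 1:9),
                    utr3_len = c(5, 3, 9, 1, 7, 2, 8, 4, 6))
  b <- bin_equal_count(rec, 3)
  expect_equal(as.vector(table(b$bin_index)), c(3, 3, 3))
  expect_true(all(diff(b$utr3_len) >= 0 | diff(b$bin_index) > 0))

  rec10 <- data.frame(gene_id = sprintf("g%02d", 1:10), utr3_len = 1:10)
  b10 <- bin_equal_count(rec10, 3)
  expect_equal(as.vector(table(b10$bin_index)), c(4, 3, 3))

  ## all-equal lengths: deterministic assignment by gene id
  recT <- data.frame(gene_id = sprintf("g%02d", 10:1), utr3_len = 5)
  b1 <- bin_equal_count(recT, 2)
  b2 <- bin_equal_count(recT[sample(10), ], 2)
  expect_identical(b1$gene_id, b2$gene_id)
})

test_that("shortest-bin normalization zeroes the reference median", {
  rec <- data.frame(gene_id = paste0("g", 1:6),
                    log2fc = c(0.1, 0.3, 0.5, 1, 2, 3),
                    bin_index = c(1, 1, 1, 2, 2, 2))
  norm <- normalize_to_shortest_bin(rec)
  expect_equal(stats::median(norm$log2fc[norm$bin_index == 1]), 0)
  expect_equal(attr(norm, "normalization_shift"), 0.3)
  expect_equal(norm$log2fc[4:6], c(0.7, 1.7, 2.7))
  ## constant shifts cancel
  rec2 <- rec; rec2$log2fc <- rec$log2fc + 5
  expect_equal(normalize_to_shortest_bin(rec2)$log2fc, norm$log2fc)
  rec3 <- rec[rec$bin_index == 2, ]
  expect_error(normalize_to_shortest_bin(rec3), "empty")
})

test_that("K-S shift test is one-sided toward derepression", {
  set.seed(9)
  ref <- stats::rnorm(500)
  expect_gte(ks_shift_test(ref, ref), 0.5)
  expect_lt(ks_shift_test(ref + 1, ref), 1e-10)
  ## swapping arguments reverses significance
  expect_gt(ks_shift_test(ref, ref + 1), 0.5)
})

test_that("derepressed fractions use strict thresholds", {
  d <- derepressed_fraction(c(0.3, 0.1, -0.3), 0.2)
  expect_equal(d$frac_up, 1 / 3)
  expect_equal(d$frac_down, 1 / 3)
  expect_equal(derepressed_fraction(rep(0, 5), 0.2)$frac_up, 0)
  d2 <- derepressed_fraction(0.2, 0.2)
  expect_equal(d2$frac_up, 0)
  expect_error(derepressed_fraction(numeric(0)), "no fold changes")
})

test_that("nontarget selection excludes 6mer carriers but keeps offset-6mer-only", {
  ann <- data.frame(gene_id = c("g1", "g2"),
                    site_type = c("offset6mer", "6mer"),
                    stringsAsFactors = FALSE)
  genes <- c("g1", "g2", "g3")
  expect_setequal(select_nontargets(genes, ann), c("g1", "g3"))
  expect_setequal(select_nontargets(genes, ann, strict = TRUE), "g3")
  expect_setequal(select_nontargets(genes, ann[0, ]), genes)
})

test_that("random cohorts preserve composition and find control genes", {
  ds <- shared_dataset()
  fams <- top_families(ds$families, 20)
  mature <- ds$mirnas[fams$family_id]
  gt <- ds$ground_truth
  nont_genes <- gt$gene_id[gt$n_sites == 0 & gt$category == "clean"]
  pool <- ds$utr3[nont_genes]
  set.seed(17)
  coh <- build_random_cohorts(mature, pool, n_cohorts = 5)
  expect_length(coh, 5L)
  for (co in coh) {
    ## mononucleotide composition preserved by the shuffle
    for (k in seq_along(mature)) {
      expect_identical(sort(strsplit(co$mirnas[[k]], "")[[1]]),
                       sort(strsplit(mature[[k]], "")[[1]]))
    }
    expect_gt(length(co$control_genes), 0L)
    expect_true(all(co$control_genes %in% nont_genes))
  }
  ## reproducible under the same seed
  set.seed(17)
  coh2 <- build_random_cohorts(mature, pool, n_cohorts = 5)
  expect_identical(coh, coh2)
  expect_error(build_random_cohorts(mature, character(0), 2), "empty")
})

test_that("cohort t-test compares cohort means to the target mean one-sidedly", {
  rec <- data.frame(gene_id = paste0("g", 1:6),
                    log2fc = c(0.1, 0.3, -0.1, -0.3, 0.2, -0.2))
  cohorts <- list(list(control_genes = "g1"),             # mean  0.1
                  list(control_genes = "g3"),             # mean -0.1
                  list(control_genes = c("g5", "g6")))    # mean  0
  ## target mean slightly off zero but equal to the mean of cohort means
  res <- cohort_t_test(c(0.1, -0.1), cohorts, rec)
  expect_equal(res$p_value, 0.5)
  ## strongly derepressed targets
  res2 <- cohort_t_test(c(2, 2.1), cohorts, rec)
  expect_lt(res2$p_value, 0.05)
  ## repressed targets give p near 1
  res3 <- cohort_t_test(c(-2, -2.1), cohorts, rec)
  expect_gt(res3$p_value, 0.95)
})

test_that("mean fold change by site count recovers a linear effect", {
  set.seed(13)
  n <- 600
  sites <- stats::rpois(n, 2)
  rec <- data.frame(gene_id = paste0("g", 1:n),
                    log2fc = 0.1 * sites + stats::rnorm(n, 0, 0.05),
                    n_effective_sites = sites)
  tab <- mean_fc_by_site_count(rec)
  expect_true(all(diff(tab$mean_log2fc[tab$n_genes >= 10]) > 0))
  expect_equal(site_count_slope(rec), 0.1, tolerance = 0.05)
})

test_that("score bins are equal-count with a degenerate single-bin case", {
  rec <- data.frame(gene_id = paste0("g", 1:8),
                    log2fc = c(1, 2, 3, 4, 5, 6, 7, 8),
                    wcontext_sum = rep(0, 8))
  tab <- mean_fc_by_score_bin(rec)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$mean_log2fc, mean(rec$log2fc))

  rec2 <- data.frame(gene_id = sprintf("g%02d", 1:12),
                     log2fc = -(1:12) / 10,
                     wcontext_sum = -(1:12) / 5)
  tab2 <- mean_fc_by_score_bin(rec2, n_bins = 3)
  expect_equal(tab2$n_genes, c(4, 4, 4))
  ## more negative score bins show stronger repression
  expect_true(all(diff(tab2$mean_log2fc) > 0))
  expect_error(mean_fc_by_score_bin(rec2[0, ]), "no records")
})

test_that("CUG co-occurrence classes follow the priority cascade", {
  fams <- families_from_seeds("ACAGUAC")     # 7m8 GUACUGU embeds CUG
  fams2 <- families_from_seeds("ACGUACG")    # CUG-free site strings
  utrs <- c(
    gA = paste0(strrep("A", 10), fams$s7m8[1], strrep("A", 10)),
    gB = paste0("CUG", strrep("A", 20), fams2$s7m8[1], strrep("A", 5)),
    gC = paste0(strrep("A", 10), "CUG", strrep("A", 10)),
    gD = strrep("A", 30),
    gE = paste0(strrep("A", 8), "CUG", strrep("A", 4), fams2$s7m8[1],
                strrep("A", 8)))
  ann <- scan_sites(utrs, rbind(fams, fams2))
  rec <- data.frame(gene_id = names(utrs), stringsAsFactors = FALSE)
  cls <- classify_cug_groups(rec, ann, utrs, window = 15L)
  got <- stats::setNames(cls$cug_class, cls$gene_id)
  expect_identical(unname(got["gA"]), "cug_embedded")
  expect_identical(unname(got["gB"]), "both_nonoverlap")
  expect_identical(unname(got["gC"]), "cug_only")
  expect_identical(unname(got["gD"]), "none")
  ## site with a CUG inside the 15-nt window falls outside all CUG classes
  expect_identical(unname(got["gE"]), "none")
})
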