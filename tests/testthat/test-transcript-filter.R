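fake_models <- function(utr5, cds, utr3, junc = list(integer(0))) {
  data.frame(transcript_id = paste0("t", seq_along(utr5)),
             gene_id = paste0("g", seq_along(utr5)),
             utr5_len = utr5, cds_len = cds, utr3_len = utr3,
             stop_rel_junctions = I(junc), stringsAsFactors = FALSE)
}

test_that("spurious classification uses inclusive structural bounds", {
  m <- fake_models(utr5 = c(25, 24, 1000, 25, 25),
                   cds = c(200, 200, 3000, 199, 200),
                   utr3 = c(50, 50, 2000, 50, 49),
                   junc = rep(list(integer(0)), 5))
  expect_identical(classify_spurious(m), c(FALSE, TRUE, FALSE, TRUE, TRUE))
})

test_that("dEJ detection triggers strictly beyond 50 nt downstream of stop", {
  m <- fake_models(utr5 = rep(100, 3), cds = rep(300, 3),
                   utr3 = rep(200, 3),
                   junc = list(51L, 50L, integer(0)))
  expect_identical(detect_dej(m), c(TRUE, FALSE, FALSE))
  ## evidence-supported junction flips a transcript
  ev <- data.frame(transcript_id = "t2", rel_pos = 120L)
  expect_identical(detect_dej(m, ev), c(TRUE, TRUE, FALSE))
  ev50 <- data.frame(transcript_id = "t3", rel_pos = 50L)
  expect_identical(detect_dej(m, ev50), c(TRUE, FALSE, FALSE))
})

test_that("cryptic splice signals need GU..AG with inner distance > 60", {
  yes <- paste0("GU", strrep("C", 61), "AG")
  no <- paste0("GU", strrep("C", 60), "AG")
  expect_true(detect_cryptic_intron(yes))
  expect_false(detect_cryptic_intron(no))
  expect_false(detect_cryptic_intron(strrep("CA", 100)))
  ## earliest GU with latest AG spans the threshold
  multi <- paste0("CC", "GU", strrep("C", 30), "GU", strrep("C", 35), "AG")
  expect_true(detect_cryptic_intron(multi))
})

test_that("siRNA off-target calls require 7-mer-class sites", {
  guide <- "UACGUACGUACGUACGUACGU"     # positions 2-8: ACGUACG
  ss <- site_strings("ACGUACG")
  with_7m8 <- paste0("CCCC", ss[["7m8"]], "CCCC")
  expect_true(detect_sirna_offtarget(with_7m8, guide))
  ## a bare 6mer core (no match at position 8, no A1) is not an off-target
  only_6mer <- paste0("GGGG", ss[["6mer"]], "CCCC")
  expect_false(detect_sirna_offtarget(only_6mer, guide))
  expect_false(detect_sirna_offtarget(with_7m8, character(0)))
  expect_error(detect_sirna_offtarget(with_7m8, "ACGU"), "8 nt")
})

test_that("expression filter keeps FPM >= 3 and positive control FPKM", {
  expr <- rbind(
    data.frame(gene_id = c("g1", "g2", "g3"), condition = "kd",
               fpkm = 1, fpm = c(3.0, 2.9, 5)),
    data.frame(gene_id = c("g1", "g2", "g3"), condition = "control",
               fpkm = c(1, 1, 0), fpm = 1))
  expect_identical(filter_expression(c("g1", "g2", "g3"), expr,
                                     "kd", "control"), "g1")
  expect_warning(
    kept <- filter_expression(c("g1", "g4"), expr, "kd", "control"),
    "missing")
  expect_identical(kept, "g1")
})

test_that("the filtering cascade recovers planted categories exactly", {
  ds <- shared_dataset()
  ev <- map_junctions_to_transcripts(ds$models, ds$junctions)
  filt <- run_dej_pipeline(ds$models, ds$utr3, ev, ds$nmd_flags,
                           ds$sirnas, ds$expression, "siUPF1", "control")
  gt <- ds$ground_truth
  expect_setequal(filt$excluded$spurious, gt$gene_id[gt$spurious])
  expect_setequal(filt$excluded$annotated_nmd, gt$gene_id[gt$nmd_annotated])
  expect_setequal(filt$excluded$dej_or_cryptic,
                  gt$gene_id[gt$dej | gt$cryptic])
  expect_setequal(filt$excluded$expression, gt$gene_id[gt$low_expression])
  expect_setequal(filt$excluded$sirna_offtarget, gt$gene_id[gt$offtarget])
  expect_setequal(filt$genes,
                  gt$gene_id[gt$category == "clean" & !gt$low_expression])

  ## report accounting identity and chaining
  rep <- filt$report
  expect_equal(rep$n_out, rep$n_in - rep$n_excluded)
  expect_equal(rep$n_in[-1], rep$n_out[-nrow(rep)])
  expect_equal(rep$n_out[nrow(rep)], length(filt$genes))
})

test_that("the final gene set is invariant to filter order", {
  ds <- shared_dataset()
  ev <- map_junctions_to_transcripts(ds$models, ds$junctions)
  filt <- run_dej_pipeline(ds$models, ds$utr3, ev, ds$nmd_flags,
                           ds$sirnas, ds$expression, "siUPF1", "control")
  ## recompute each exclusion on the full universe and intersect
  universe <- unique(ds$models$gene_id)
  spur <- tapply(!classify_spurious(ds$models), ds$models$gene_id, any)
  s1 <- universe[spur[universe]]
  s2 <- setdiff(universe, ds$nmd_flags)
  dejg <- unique(ds$models$gene_id[detect_dej(ds$models, ev)])
  cryg <- names(ds$utr3)[detect_cryptic_intron(ds$utr3)]
  s3 <- setdiff(universe, union(dejg, cryg))
  s4 <- filter_expression(universe, ds$expression, "siUPF1", "control")
  s5 <- universe[!detect_sirna_offtarget(ds$utr3[universe], ds$sirnas)]
  ## intersect in a different order than the pipeline applies
  final <- Reduce(intersect, list(s5, s4, s3, s2, s1))
  expect_setequal(final, filt$genes)
})

test_that("an all-clean dataset passes structural filters untouched", {
  cfg <- synthetic_config(n_genes = 60, frac_spurious = 0,
                          frac_nmd_annotated = 0, frac_dej = 0,
                          frac_cryptic = 0, frac_offtarget = 0,
                          frac_low_expression = 0, rng_seed = 8)
  ds <- generate_umd_dataset(cfg)
  ev <- map_junctions_to_transcripts(ds$models, ds$junctions)
  filt <- run_dej_pipeline(ds$models, ds$utr3, ev, ds$nmd_flags,
                           ds$sirnas, ds$expression, "siUPF1", "control")
  expect_equal(sum(filt$report$n_excluded), 0L)
  expect_setequal(filt$genes, ds$ground_truth$gene_id)
})
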