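test_that("site-type strings follow the canonical seed-match definitions", {
  ss <- site_strings("ACGUACG")
  expect_identical(ss[["7m8"]], "CGUACGU")
  expect_identical(ss[["8mer"]], "CGUACGUA")
  expect_identical(ss[["6mer"]], "GUACGU")
  expect_identical(ss[["7A1"]], "GUACGUA")
  expect_identical(ss[["offset6mer"]], "CGUACG")
  ss2 <- site_strings("AAAAAAA")
  expect_identical(ss2[["7m8"]], "UUUUUUU")
  expect_identical(ss2[["8mer"]], "UUUUUUUA")
})

test_that("site-string structural invariants hold for random seeds", {
  set.seed(11)
  for (i in 1:50) {
    seed <- paste(sample(c("A", "C", "G", "U"), 7, TRUE), collapse = "")
    ss <- site_strings(seed)
    expect_identical(nchar(unname(ss)), c(8L, 7L, 7L, 6L, 6L))
    expect_identical(ss[["8mer"]], paste0(ss[["7m8"]], "A"))
    expect_identical(ss[["7A1"]], paste0(ss[["6mer"]], "A"))
    ## 6mer is a suffix of 7m8; offset6mer is its prefix
    expect_identical(substr(ss[["7m8"]], 2, 7), ss[["6mer"]])
    expect_identical(substr(ss[["7m8"]], 1, 6), ss[["offset6mer"]])
    ## reverse complement is an involution
    expect_identical(rna_revcomp(rna_revcomp(seed)), seed)
  }
})

test_that("family building collapses shared seeds and sums abundance", {
  mirnas <- c(mA = "UACGUACGUACGUACGUACGU",  # positions 2-8: ACGUACG
              mB = "GACGUACGAAAAAAAAAAAAA",  # same seed, different tail
              mC = "UGGGCCCAAAAAAAAAAAAAA")
  ab <- data.frame(mirna_id = c("mA", "mB", "mC"),
                   abundance = c(10, 5, 30))
  fams <- build_families(mirnas, ab)
  expect_equal(nrow(fams), 2L)
  shared <- fams[fams$seed28 == "ACGUACG", ]
  expect_equal(shared$abundance, 15)
  expect_identical(shared$family_id, "mA")
  expect_setequal(shared$members[[1]], c("mA", "mB"))
  ## sorted by abundance
  expect_identical(fams$family_id[1], "mC")
  expect_error(build_families(c(x = "ACGU"), ab), "shorter than 8")
})

test_that("scanner reports maximal site types at each locus", {
  fams <- families_from_seeds("ACGUACG")   # 7m8 = CGUACGU
  ##             0123456789...
  u1 <- c(g1 = "AAACGUACGUAAA")            # 7m8 at [3,10), followed by A
  s1 <- scan_sites(u1, fams)
  expect_equal(nrow(s1), 1L)
  expect_identical(s1$site_type, "8mer")
  expect_equal(c(s1$start, s1$end), c(3L, 11L))

  u2 <- c(g1 = "AAACGUACGUCCC")            # no A after the match
  s2 <- scan_sites(u2, fams)
  expect_identical(s2$site_type, "7m8")
  expect_equal(c(s2$start, s2$end), c(3L, 10L))

  u3 <- c(g1 = "CCCCCCCCCCCC")
  expect_equal(nrow(scan_sites(u3, fams)), 0L)

  ## terminal core match with no following base cannot be 7A1/8mer
  u4 <- c(g1 = "CCCGUACGU")                # core GUACGU at the 3' end
  s4 <- scan_sites(u4, fams, types = SITE_TYPES)
  expect_false(any(s4$site_type %in% c("8mer", "7A1")))
})

test_that("scanner matches the brute-force regex oracle on random inputs", {
  set.seed(77)
  for (rep in 1:60) {
    n_fam <- sample(1:3, 1)
    seeds <- unique(replicate(n_fam, paste(sample(c("A", "C", "G", "U"),
                                                  7, TRUE), collapse = "")))
    fams <- families_from_seeds(seeds)
    utrs <- stats::setNames(random_rna(2, sample(30:120, 1)), c("u1", "u2"))
    ## seed one UTR with a literal site to raise match density
    pat <- fams$s7m8[1]
    utrs[1] <- paste0(substr(utrs[1], 1, 5), pat,
                      substr(utrs[1], 6 + nchar(pat), nchar(utrs[1])))
    got <- scan_sites(utrs, fams, types = SITE_TYPES)
    want <- oracle_scan_sites(utrs, fams, types = SITE_TYPES)
    expect_identical(sort_sites(got[names(want)]), sort_sites(want))
  }
})

test_that("effective site counts are monotone under 3' extension", {
  set.seed(123)
  fams <- families_from_seeds(c("ACGUACG", "GGCACCA"))
  for (rep in 1:20) {
    u <- random_rna(1, 60)
    ext <- paste0(u, random_rna(1, 40))
    n1 <- count_effective_sites(scan_sites(c(g = u), fams))
    n2 <- count_effective_sites(scan_sites(c(g = ext), fams))
    expect_gte(n2, n1)
  }
})

test_that("effective sites are the 7-mer classes only", {
  ann <- data.frame(gene_id = "g",
                    site_type = c("8mer", "7m8", "6mer"),
                    stringsAsFactors = FALSE)
  expect_equal(count_effective_sites(ann), 2L)
  expect_equal(count_effective_sites(ann[0, ]), 0L)
  ann10 <- data.frame(gene_id = "g", site_type = rep("7A1", 10))
  expect_equal(count_effective_sites(ann10), 10L)
})

test_that("context++ score summation resolves overlaps by efficacy", {
  ann <- data.frame(gene_id = "g", family_id = c("f1", "f2"),
                    site_type = "7m8", start = c(0L, 20L),
                    end = c(7L, 27L), stringsAsFactors = FALSE)
  sc <- data.frame(gene_id = "g", family_id = c("f1", "f2"),
                   start = c(0L, 20L), score = c(-0.1, -0.2))
  expect_equal(unname(sum_wcontext(ann, sc)), -0.3)

  ## overlapping sites: only the more negative score contributes
  ann2 <- ann; ann2$start <- c(0L, 3L); ann2$end <- c(7L, 10L)
  sc2 <- sc; sc2$start <- c(0L, 3L); sc2$score <- c(-0.1, -0.3)
  expect_equal(unname(sum_wcontext(ann2, sc2)), -0.3)

  ## no scored sites
  expect_equal(unname(sum_wcontext(ann, sc[0, ])["g"]), 0)
  ## positive score warns
  sc3 <- sc; sc3$score[1] <- 0.2
  expect_warning(sum_wcontext(ann, sc3), "positive")
})
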