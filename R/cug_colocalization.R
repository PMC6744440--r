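## ---------------------------------------------------------------------------
## cug_colocalization: CUG counts in MRE flanks vs random-site controls,
## 3-mer signal-to-noise ratios, and CAG enrichment in miRNA seed regions
## against dinucleotide-shuffled cohorts.
## ---------------------------------------------------------------------------

## number of CUG occurrences overlapping the two flank windows of one site;
## a CUG counts when at least one of its 3 bases lies in the window
.cug_in_flanks_one <- function(cug0, start, end, window) {
  up <- cug0 + 3L > start - window & cug0 < start
  dn <- cug0 + 3L > end & cug0 < end + window
  sum(up | dn)
}

#' Count CUG motifs in the flanks of seed-match sites
#'
#' Counts CUG occurrences within the `window`-nt flank immediately 5' or 3'
#' of each site (a CUG overlapping the window by any of its bases counts;
#' CUGs inside the site itself do not). If more than `n_sample` sites are
#' given, `n_sample` are sampled without replacement under the current RNG
#' state. Windows truncated at UTR boundaries are counted as is.
#'
#' @param utrs named character vector of 3'UTR sequences.
#' @param sites site annotation data.frame from [scan_sites()].
#' @param window flank width in nt (default 5).
#' @param n_sample maximum number of sites used (default 1000).
#' @return list with `total` CUG count, `per_site` counts, `n_sites` used
#'   and `exposure` (number of distinct CUG start positions overlapping the
#'   flanks, `n_sites * 2 * (window + 2)`).
#' @export
count_cug_in_flanks <- function(utrs, sites, window = 5L, n_sample = 1000L) {
  stopifnot(window >= 3L)
  if (nrow(sites) > n_sample) {
    sites <- sites[sample.int(nrow(sites), n_sample), , drop = FALSE]
  }
  cug_pos <- lapply(utrs, function(u) fixed_matches0("CUG", u))
  per_site <- vapply(seq_len(nrow(sites)), function(i) {
    .cug_in_flanks_one(cug_pos[[sites$gene_id[i]]],
                       sites$start[i], sites$end[i], window)
  }, numeric(1))
  list(total = sum(per_site), per_site = per_site,
       n_sites = nrow(sites),
       exposure = nrow(sites) * 2L * (window + 2L))
}

#' CUG flank counts at random 7-mer positions
#'
#' Control for [count_cug_in_flanks()]: `n_sites` random 7-mer positions are
#' drawn uniformly (without replacement) over all valid positions pooled
#' across the UTRs, and CUG flank occurrences are counted identically.
#'
#' @param utrs named character vector of 3'UTR sequences.
#' @param n_sites number of random sites.
#' @param window flank width in nt.
#' @param site_len placed site length (default 7).
#' @return same structure as [count_cug_in_flanks()].
#' @export
random_flank_control <- function(utrs, n_sites, window = 5L, site_len = 7L) {
  lens <- nchar(utrs)
  valid <- pmax(0L, lens - site_len + 1L)
  if (sum(valid) == 0L) stop("no UTR long enough for a site", call. = FALSE)
  if (n_sites == 0L) {
    return(list(total = 0, per_site = numeric(0), n_sites = 0L,
                exposure = 0L))
  }
  pick <- sample.int(sum(valid), min(n_sites, sum(valid)))
  cum0 <- cumsum(c(0L, valid))
  ## map pooled index -> (gene, offset); rightmost-tie handling skips
  ## genes with no valid position
  gene_idx <- findInterval(pick - 0.5, cum0)
  offs <- pick - cum0[gene_idx]
  sites <- data.frame(gene_id = names(utrs)[gene_idx],
                      start = offs - 1L,
                      end = offs - 1L + site_len,
                      stringsAsFactors = FALSE)
  cug_pos <- lapply(utrs, function(u) fixed_matches0("CUG", u))
  per_site <- vapply(seq_len(nrow(sites)), function(i) {
    .cug_in_flanks_one(cug_pos[[sites$gene_id[i]]],
                       sites$start[i], sites$end[i], window)
  }, numeric(1))
  list(total = sum(per_site), per_site = per_site, n_sites = nrow(sites),
       exposure = nrow(sites) * 2L * (window + 2L))
}

#' Compare CUG flank occurrence rates
#'
#' One-sided Fisher exact test that rate a exceeds rate b, on occurrence vs
#' non-occurrence positions (exposure = possible CUG start positions).
#'
#' @param count_a,exposure_a observed count and exposure of group a.
#' @param count_b,exposure_b observed count and exposure of group b.
#' @return p-value.
#' @export
flank_enrichment_test <- function(count_a, exposure_a, count_b, exposure_b) {
  if (exposure_a <= 0 || exposure_b <= 0) {
    stop("flank_enrichment_test: zero exposure", call. = FALSE)
  }
  stats::fisher.test(
    matrix(c(count_a, exposure_a - count_a,
             count_b, exposure_b - count_b), nrow = 2, byrow = TRUE),
    alternative = "greater")$p.value
}

#' Signal-to-noise ratios of all 64 triplet nucleotides
#'
#' Observed 3-mer counts in the given sequences divided by the expected
#' counts, where the expectation is the mean count over `n_shuffles`
#' dinucleotide-preserving shuffles of the same sequences.
#'
#' @param seqs character vector of RNA sequences.
#' @param n_shuffles shuffles used for the expectation (default 10).
#' @param eps expected-count floor used when a triplet never occurs in the
#'   shuffles (flagged in the output).
#' @return data.frame with 64 rows: `triplet`, `obs_count`, `exp_count`,
#'   `snr`, `exp_zero` flag.
#' @export
snr_3mers <- function(seqs, n_shuffles = 10L, eps = 0.5) {
  stopifnot(n_shuffles >= 1L)
  obs <- count_kmers(seqs, 3L, drop_zero = FALSE)
  exp_sum <- numeric(length(obs))
  for (r in seq_len(n_shuffles)) {
    exp_sum <- exp_sum + count_kmers(dinuc_shuffle(seqs), 3L, drop_zero = FALSE)
  }
  exp_mean <- exp_sum / n_shuffles
  zero <- exp_mean == 0
  snr <- ifelse(zero, obs / eps, obs / exp_mean)
  data.frame(triplet = names(obs), obs_count = as.integer(obs),
             exp_count = exp_mean, snr = snr, exp_zero = zero,
             stringsAsFactors = FALSE)
}

#' Reverse complement a set of sequences
#'
#' @param seqs named character vector (RNA alphabet).
#' @return named character vector of reverse complements.
#' @export
revcomp_set <- function(seqs) {
  stats::setNames(rna_revcomp(seqs), names(seqs))
}

#' Correlate two signal-to-noise profiles
#'
#' Pearson correlation over the 64 aligned triplets.
#'
#' @param x,y data.frames from [snr_3mers()].
#' @return list with `r` and `p` (one-sided, positive association).
#' @export
correlate_snr <- function(x, y) {
  yy <- y$snr[match(x$triplet, y$triplet)]
  if (any(is.na(yy))) stop("triplet sets do not align", call. = FALSE)
  if (stats::sd(x$snr) == 0 || stats::sd(yy) == 0) {
    stop("correlate_snr: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x$snr, yy, method = "pearson",
                        alternative = "greater")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' CAG enrichment in miRNA seed regions vs shuffled cohorts
#'
#' The observed statistic is the fraction of families whose seed region
#' (miRNA positions 2-8) contains CAG. Each control cohort dinucleotide-
#' shuffles every family's representative mature sequence and re-scores the
#' shuffled position-2-8 windows identically. Enrichment is tested by a
#' one-sided Fisher exact test of the observed counts against the pooled
#' cohort counts.
#'
#' @param families family data.frame from [build_families()].
#' @param mirnas named character vector of mature miRNA sequences (the
#'   family representative is looked up by `family_id`).
#' @param n_cohorts number of shuffle cohorts (default 100).
#' @return list with `observed_count`, `observed_prop`, `cohort_props`,
#'   `cohort_mean_prop` and `p_value`.
#' @export
cag_seed_enrichment <- function(families, mirnas, n_cohorts = 100L) {
  stopifnot(n_cohorts >= 1L)
  has_cag <- grepl("CAG", families$seed28, fixed = TRUE)
  n <- nrow(families)
  reps <- mirnas[families$family_id]
  cohort_counts <- vapply(seq_len(n_cohorts), function(cc) {
    sh <- dinuc_shuffle(reps)
    sum(grepl("CAG", substr(sh, 2L, 8L), fixed = TRUE))
  }, numeric(1))
  p <- stats::fisher.test(
    matrix(c(sum(has_cag), n - sum(has_cag),
             sum(cohort_counts), n * n_cohorts - sum(cohort_counts)),
           nrow = 2, byrow = TRUE),
    alternative = "greater")$p.value
  list(observed_count = sum(has_cag),
       observed_prop = sum(has_cag) / n,
       cohort_props = cohort_counts / n,
       cohort_mean_prop = mean(cohort_counts) / n,
       p_value = p)
}
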