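## ---------------------------------------------------------------------------
## expression_stats: log2 fold changes, equal-count 3'UTR-length binning
## with shortest-bin median normalization, one-sided K-S shift tests,
## shuffled-miRNA cohort nulls with one-sample t-tests, site-count and
## score-bin response curves, and CUG/site co-occurrence classes.
## ---------------------------------------------------------------------------

#' Compute per-gene log2 fold changes
#'
#' `log2(FPKM_kd / FPKM_ctrl)` with no pseudocount; genes with zero
#' control FPKM must have been filtered upstream and are an error here.
#'
#' @param expr long-form expression table.
#' @param kd_condition,ctrl_condition condition labels.
#' @param genes optional gene subset (default: all genes in both
#'   conditions).
#' @param utr_lengths optional named vector of 3'UTR lengths to attach.
#' @return data.frame with `gene_id`, `log2fc` and (if given) `utr3_len`.
#' @export
compute_log2fc <- function(expr, kd_condition, ctrl_condition,
                           genes = NULL, utr_lengths = NULL) {
  kd <- expr[expr$condition == kd_condition, , drop = FALSE]
  ctrl <- expr[expr$condition == ctrl_condition, , drop = FALSE]
  if (is.null(genes)) genes <- intersect(kd$gene_id, ctrl$gene_id)
  num <- kd$fpkm[match(genes, kd$gene_id)]
  den <- ctrl$fpkm[match(genes, ctrl$gene_id)]
  if (any(is.na(num)) || any(is.na(den))) {
    stop("gene(s) missing a condition in compute_log2fc", call. = FALSE)
  }
  if (any(den == 0)) {
    stop("zero control FPKM encountered; genes must be filtered upstream",
         call. = FALSE)
  }
  out <- data.frame(gene_id = genes, log2fc = log2(num / den),
                    stringsAsFactors = FALSE)
  if (!is.null(utr_lengths)) out$utr3_len <- unname(utr_lengths[genes])
  out
}

#' Assign equal-count 3'UTR-length bins
#'
#' Records are sorted by `utr3_len` (ties by `gene_id`) and partitioned
#' into `n_bins` contiguous groups whose sizes differ by at most one;
#' remainder genes go to the lowest-index bins. Bin 1 holds the shortest
#' 3'UTRs. Bin boundaries are attached as `attr(, "bin_boundaries")`.
#'
#' @param records data.frame with `gene_id` and `utr3_len`.
#' @param n_bins number of bins (>= 2; `n_records >= n_bins`).
#' @return records with a `bin_index` column, in sorted order.
#' @export
bin_equal_count <- function(records, n_bins) {
  stopifnot(n_bins >= 2L, nrow(records) >= n_bins)
  ord <- order(records$utr3_len, records$gene_id)
  records <- records[ord, , drop = FALSE]
  n <- nrow(records)
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  records$bin_index <- rep(seq_len(n_bins), times = sizes)
  bb <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    v <- records$utr3_len[records$bin_index == b]
    data.frame(bin_index = b, n = length(v), min_len = min(v),
               max_len = max(v))
  }))
  attr(records, "bin_boundaries") <- bb
  rownames(records) <- NULL
  records
}

#' Normalize fold changes to the shortest 3'UTR bin
#'
#' Subtracts the median log2 fold change of bin 1 (the shortest-3'UTR
#' bin) from every record, so that bin's median becomes exactly 0.
#'
#' @param records data.frame with `log2fc` and `bin_index`.
#' @return records with shifted `log2fc`; the shift is attached as
#'   `attr(, "normalization_shift")`.
#' @export
normalize_to_shortest_bin <- function(records) {
  ref <- records$log2fc[records$bin_index == 1L]
  if (length(ref) == 0L) stop("shortest bin is empty", call. = FALSE)
  shift <- stats::median(ref)
  records$log2fc <- records$log2fc - shift
  attr(records, "normalization_shift") <- shift
  records
}

#' One-sided two-sample K-S shift test
#'
#' Tests the alternative that `values_bin` is stochastically greater than
#' `values_ref` (its CDF shifted right, i.e. lying below the reference
#' CDF).
#'
#' @param values_bin,values_ref numeric samples.
#' @return p-value.
#' @export
ks_shift_test <- function(values_bin, values_ref) {
  stopifnot(length(values_bin) > 0L, length(values_ref) > 0L)
  ## In stats::ks.test, alternative = "less" tests that the CDF of x lies
  ## below that of y, i.e. x stochastically greater.
  suppressWarnings(
    stats::ks.test(values_bin, values_ref, alternative = "less")$p.value)
}

#' Fractions of derepressed and downregulated genes
#'
#' @param log2fc numeric vector of fold changes.
#' @param threshold positive log2 threshold (default 0.2); inequalities
#'   are strict.
#' @return list with `frac_up` (log2fc > threshold) and `frac_down`
#'   (log2fc < -threshold).
#' @export
derepressed_fraction <- function(log2fc, threshold = 0.2) {
  stopifnot(threshold > 0)
  if (length(log2fc) == 0L) stop("no fold changes given", call. = FALSE)
  list(frac_up = mean(log2fc > threshold),
       frac_down = mean(log2fc < -threshold))
}

#' Select nontarget genes
#'
#' Genes lacking any 6mer-or-better site of the given families (a 6mer
#' core underlies every 8mer/7m8/7A1 locus, so zero annotated loci of
#' those four types means no seed match at all). Offset-6mer-only
#' carriers are included unless `strict = TRUE`.
#'
#' @param genes gene universe.
#' @param annotations site annotations scanned with 6mer (and, for
#'   `strict`, offset6mer) included.
#' @param strict also exclude offset-6mer carriers.
#' @return character vector of nontarget gene ids.
#' @export
select_nontargets <- function(genes, annotations, strict = FALSE) {
  types <- c(EFFECTIVE_TYPES, "6mer")
  if (strict) types <- c(types, "offset6mer")
  carriers <- unique(annotations$gene_id[annotations$site_type %in% types])
  setdiff(genes, carriers)
}

## effective-site patterns (7m8 + 7A1; 8mer matches are a subset of 7m8)
.cohort_patterns <- function(shuffled) {
  seeds <- substr(shuffled, 2L, 8L)
  unique(unlist(lapply(seeds, function(s) {
    ss <- site_strings(s)
    c(ss[["7m8"]], ss[["7A1"]])
  })))
}

#' Build shuffled-miRNA cohorts with matched control genes
#'
#' Each cohort dinucleotide-shuffles the mature sequences of the top
#' miRNA families and takes as its control genes the nontargets that
#' contain at least one effective 7-mer site of any shuffled miRNA.
#' Cohorts with no control gene are re-drawn (up to `max_retry`).
#' Optionally control genes are stratified to the 3'UTR-length deciles of
#' the real targets.
#'
#' @param mature named character vector of mature miRNA sequences of the
#'   top families (one per family).
#' @param nontarget_utrs named character vector of nontarget 3'UTRs.
#' @param n_cohorts number of cohorts.
#' @param length_match optional numeric vector of target 3'UTR lengths;
#'   when given, control genes are subsampled to match its deciles.
#' @param max_retry resampling cap for empty cohorts.
#' @return list of cohorts, each `list(mirnas=, control_genes=)`.
#' @export
build_random_cohorts <- function(mature, nontarget_utrs, n_cohorts,
                                 length_match = NULL, max_retry = 10L) {
  if (length(nontarget_utrs) == 0L) {
    stop("empty nontarget pool", call. = FALSE)
  }
  lens <- stats::setNames(nchar(nontarget_utrs), names(nontarget_utrs))
  out <- vector("list", n_cohorts)
  for (cc in seq_len(n_cohorts)) {
    ctrl <- character(0); sh <- NULL
    for (r in seq_len(max_retry)) {
      sh <- dinuc_shuffle(mature)
      names(sh) <- names(mature)
      pats <- .cohort_patterns(sh)
      hit <- rep(FALSE, length(nontarget_utrs))
      for (p in pats) hit <- hit | grepl(p, nontarget_utrs, fixed = TRUE)
      ctrl <- names(nontarget_utrs)[hit]
      if (length(ctrl) > 0L) break
    }
    if (length(ctrl) == 0L) {
      stop("cohort ", cc, " has no control genes after ", max_retry,
           " retries", call. = FALSE)
    }
    if (!is.null(length_match)) {
      q <- stats::quantile(length_match, probs = seq(0, 1, 0.1))
      strat <- cut(lens[ctrl], breaks = unique(c(-Inf, q, Inf)))
      want <- table(cut(length_match, breaks = unique(c(-Inf, q, Inf))))
      keep <- unlist(lapply(levels(strat), function(lv) {
        g <- ctrl[strat == lv]
        n_want <- ceiling(length(ctrl) * want[lv] / sum(want))
        if (length(g) <= n_want) g else g[sample.int(length(g), n_want)]
      }))
      if (length(keep) > 0L) ctrl <- keep
    }
    out[[cc]] <- list(mirnas = sh, control_genes = ctrl)
  }
  out
}

#' One-sample t-test of cohort means against the target mean
#'
#' The sample is the per-cohort mean log2 fold change of control genes;
#' it is compared to mu = mean target log2 fold change with a one-tailed
#' t-test for the alternative that cohort means lie below the target mean
#' (derepression of targets).
#'
#' @param target_log2fc fold changes of the target genes.
#' @param cohorts cohort list from [build_random_cohorts()].
#' @param records data.frame with `gene_id`, `log2fc` covering the
#'   control genes.
#' @return list with `target_mean`, `cohort_means`, `p_value`,
#'   `direction`.
#' @export
cohort_t_test <- function(target_log2fc, cohorts, records) {
  fc <- stats::setNames(records$log2fc, records$gene_id)
  cohort_means <- vapply(cohorts, function(co) {
    v <- fc[co$control_genes]
    mean(v[!is.na(v)])
  }, numeric(1))
  if (stats::sd(cohort_means) == 0) {
    stop("cohort means have zero variance", call. = FALSE)
  }
  tm <- mean(target_log2fc)
  tt <- stats::t.test(cohort_means, mu = tm, alternative = "less")
  list(target_mean = tm, cohort_means = cohort_means,
       p_value = tt$p.value, direction = "derepression")
}

#' Mean fold change by effective-site count
#'
#' Genes are grouped by their effective 7-mer site count; per group the
#' mean and s.e.m. of the log2 fold change are reported, with a one-sided
#' K-S test against count-matched random-site control genes when cohorts
#' are supplied (control genes grouped by their cohort-miRNA site
#' counts). Groups smaller than 3 get `p = NA`.
#'
#' @param records data.frame with `log2fc` and `n_effective_sites`.
#' @param cohorts optional cohort list; control site counts are computed
#'   on `control_utrs` for up to `max_control_cohorts` cohorts.
#' @param control_utrs named character vector of control 3'UTRs.
#' @param max_control_cohorts cohorts used for the control pool.
#' @return data.frame (`n_sites`, `n_genes`, `mean_log2fc`, `sem`, `p_ks`).
#' @export
mean_fc_by_site_count <- function(records, cohorts = NULL,
                                  control_utrs = NULL,
                                  max_control_cohorts = 50L) {
  ctrl_pool <- NULL
  if (!is.null(cohorts) && !is.null(control_utrs)) {
    fc <- stats::setNames(records$log2fc, records$gene_id)
    use <- cohorts[seq_len(min(length(cohorts), max_control_cohorts))]
    pool <- lapply(use, function(co) {
      genes <- intersect(co$control_genes, names(control_utrs))
      if (length(genes) == 0L) return(NULL)
      pats <- .cohort_patterns(co$mirnas)
      counts <- rep(0L, length(genes))
      for (p in pats) {
        m <- gregexpr(p, control_utrs[genes], fixed = TRUE)
        counts <- counts + vapply(m, function(x) {
          if (x[1] == -1L) 0L else length(x)
        }, integer(1))
      }
      data.frame(n_sites = counts, log2fc = unname(fc[genes]))
    })
    ctrl_pool <- do.call(rbind, pool[!vapply(pool, is.null, logical(1))])
    ctrl_pool <- ctrl_pool[!is.na(ctrl_pool$log2fc), , drop = FALSE]
  }
  counts <- sort(unique(records$n_effective_sites))
  rows <- lapply(counts, function(s) {
    v <- records$log2fc[records$n_effective_sites == s]
    p <- NA_real_
    if (length(v) >= 3L && !is.null(ctrl_pool)) {
      ref <- ctrl_pool$log2fc[ctrl_pool$n_sites == s]
      if (length(ref) >= 3L) p <- ks_shift_test(v, ref)
    }
    data.frame(n_sites = s, n_genes = length(v), mean_log2fc = mean(v),
               sem = stats::sd(v) / sqrt(length(v)), p_ks = p)
  })
  do.call(rbind, rows)
}

#' Regression slope of fold change on effective-site count
#'
#' @param records data.frame with `log2fc` and `n_effective_sites`.
#' @return slope (log2FC per site) of the gene-level least-squares fit.
#' @export
site_count_slope <- function(records) {
  unname(stats::coef(stats::lm(log2fc ~ n_effective_sites,
                               data = records))[2])
}

#' Mean fold change by summed site-score bin
#'
#' Equal-count bins over the per-gene summed wContext++ score (all-equal
#' scores collapse to a single bin).
#'
#' @param records data.frame with `log2fc` and `wcontext_sum`.
#' @param n_bins number of bins.
#' @return data.frame (`bin_index`, `n_genes`, `mean_score`,
#'   `mean_log2fc`, `sem`).
#' @export
mean_fc_by_score_bin <- function(records, n_bins = 4L) {
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  if (length(unique(records$wcontext_sum)) == 1L) {
    return(data.frame(bin_index = 1L, n_genes = nrow(records),
                      mean_score = records$wcontext_sum[1],
                      mean_log2fc = mean(records$log2fc),
                      sem = stats::sd(records$log2fc) / sqrt(nrow(records))))
  }
  n_bins <- min(n_bins, nrow(records))
  ord <- order(records$wcontext_sum, records$gene_id)
  records <- records[ord, , drop = FALSE]
  sizes <- rep(nrow(records) %/% n_bins, n_bins)
  extra <- nrow(records) %% n_bins
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bi <- rep(seq_len(n_bins), times = sizes)
  do.call(rbind, lapply(seq_len(n_bins), function(b) {
    v <- records$log2fc[bi == b]
    data.frame(bin_index = b, n_genes = length(v),
               mean_score = mean(records$wcontext_sum[bi == b]),
               mean_log2fc = mean(v),
               sem = stats::sd(v) / sqrt(length(v)))
  }))
}

#' Classify genes by CUG / 7-mer-site co-occurrence
#'
#' Four mutually exclusive classes, assigned in priority order:
#' `cug_embedded` (some effective site contains CUG within its site
#' string), `both_nonoverlap` (at least one site and at least one CUG,
#' none within the +/- `window` nt gap of any site), `cug_only` (CUG
#' present, no effective site), `none`. Gap is measured between nearest
#' edges.
#'
#' @param records data.frame with `gene_id`.
#' @param annotations effective-site annotations from [scan_sites()].
#' @param utr_seqs named character vector of 3'UTR sequences.
#' @param window co-occurrence window in nt (default 15).
#' @return records with a `cug_class` column.
#' @export
classify_cug_groups <- function(records, annotations, utr_seqs,
                                window = 15L) {
  eff <- annotations[annotations$site_type %in% EFFECTIVE_TYPES, ,
                     drop = FALSE]
  cls <- vapply(records$gene_id, function(g) {
    u <- utr_seqs[[g]]
    if (is.null(u)) return("none")
    cug0 <- fixed_matches0("CUG", u)
    sites <- eff[eff$gene_id == g, , drop = FALSE]
    if (nrow(sites) > 0L) {
      embedded <- any(vapply(seq_len(nrow(sites)), function(i) {
        grepl("CUG", substr(u, sites$start[i] + 1L, sites$end[i]),
              fixed = TRUE)
      }, logical(1)))
      if (embedded) return("cug_embedded")
      if (length(cug0) == 0L) return("none")
      near <- vapply(cug0, function(c0) {
        any(c0 + 3L > sites$start - window & c0 < sites$end + window)
      }, logical(1))
      if (!any(near)) return("both_nonoverlap")
      return("none")
    }
    if (length(cug0) > 0L) return("cug_only")
    "none"
  }, character(1), USE.NAMES = FALSE)
  records$cug_class <- cls
  records
}
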