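## ---------------------------------------------------------------------------
## kmer_enrichment: dinucleotide-preserving shuffles, k-mer counting,
## 7-mer enrichment against shuffled backgrounds, degenerate pattern
## expansion and MRE annotation.
## ---------------------------------------------------------------------------

## Altschul-Erickson Euler-path shuffle of one N-free character vector.
## Preserves the dinucleotide multiset and both terminal characters.
.dinuc_shuffle_chars <- function(ch) {
  L <- length(ch)
  if (L < 3L) return(ch)
  verts <- unique(ch)
  if (length(verts) == 1L) return(ch)
  from <- ch[-L]; to <- ch[-1L]
  last <- ch[L]
  targets <- split(to, factor(from, levels = verts))
  nonlast <- setdiff(verts[lengths(targets) > 0L], last)
  ## choose a random last exit per non-terminal vertex until the chosen
  ## edges form an arborescence directed toward the terminal vertex
  repeat {
    last_edge <- vapply(nonlast, function(v) {
      tv <- targets[[v]]
      tv[sample.int(length(tv), 1L)]
    }, character(1))
    ok <- TRUE
    for (v in nonlast) {
      cur <- v; steps <- 0L
      while (cur != last) {
        cur <- last_edge[[cur]]
        steps <- steps + 1L
        if (is.na(cur) || steps > length(verts)) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) break
  }
  order_list <- list()
  for (v in verts) {
    tv <- targets[[v]]
    if (length(tv) == 0L) next
    if (v %in% nonlast) {
      drop1 <- match(last_edge[[v]], tv)
      rest <- tv[-drop1]
      if (length(rest) > 1L) rest <- rest[sample.int(length(rest))]
      order_list[[v]] <- c(rest, last_edge[[v]])
    } else {
      order_list[[v]] <- if (length(tv) > 1L) tv[sample.int(length(tv))] else tv
    }
  }
  ptr <- stats::setNames(rep(1L, length(order_list)), names(order_list))
  out <- character(L)
  out[1] <- ch[1]
  cur <- ch[1]
  for (i in 2:L) {
    nxt <- order_list[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  out
}

#' Dinucleotide-preserving shuffle
#'
#' Random permutation of each sequence preserving its dinucleotide count
#' multiset and its first and last nucleotide (Euler-path construction).
#' Runs of N split the sequence into segments that are shuffled
#' independently. Deterministic under a fixed RNG seed.
#'
#' @param seqs character vector of sequences (length >= 2 each).
#' @return character vector of shuffled sequences.
#' @export
dinuc_shuffle <- function(seqs) {
  vapply(seqs, function(s) {
    if (nchar(s) < 2L) stop("dinuc_shuffle: sequence shorter than 2 nt",
                            call. = FALSE)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    if (!any(ch == "N")) {
      return(paste(.dinuc_shuffle_chars(ch), collapse = ""))
    }
    isn <- ch == "N"
    seg <- cumsum(c(TRUE, diff(isn) != 0L))
    parts <- split(ch, seg)
    parts <- lapply(parts, function(p) {
      if (p[1] == "N" || length(p) < 3L) p else .dinuc_shuffle_chars(p)
    })
    paste(unlist(parts, use.names = FALSE), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Count overlapping k-mers
#'
#' Overlapping occurrences are counted with step 1 and summed over all
#' sequences; windows containing N are skipped.
#'
#' @param seqs character vector of RNA sequences.
#' @param k word size (>= 1).
#' @param drop_zero drop k-mers with zero counts (default TRUE).
#' @return named integer vector of counts.
#' @export
count_kmers <- function(seqs, k, drop_zero = TRUE) {
  stopifnot(k >= 1L)
  seqs <- seqs[nchar(seqs) >= k]
  if (length(seqs) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  set <- Biostrings::RNAStringSet(seqs)
  mat <- Biostrings::oligonucleotideFrequency(set, width = k, step = 1L)
  counts <- as.integer(round(colSums(mat)))
  names(counts) <- colnames(mat)
  if (drop_zero) counts <- counts[counts > 0L]
  counts
}

#' One-sided Fisher enrichment p-value for 2x2 tables
#'
#' P-value of the one-sided Fisher exact test for enrichment of occurrences
#' in the first sample, i.e. the upper hypergeometric tail of `a` in the
#' table \[\[a, b\], \[c, d\]\]. Vectorized over tables.
#'
#' @param a,b,c,d table cells (a = target occurrences, b = target
#'   non-occurrences, c = background occurrences, d = background
#'   non-occurrences).
#' @return numeric vector of p-values.
#' @export
fisher_enrichment_p <- function(a, b, c, d) {
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' 7-mer enrichment in target 3'UTRs against shuffled backgrounds
#'
#' The background is one dinucleotide-preserving shuffle per target UTR
#' (a number-matched shuffled set); with `n_shuffles > 1` the background
#' pools counts over several shuffles per UTR (totals grow accordingly).
#' For every possible k-mer a one-sided Fisher exact test compares target
#' occurrence counts to background counts; significance is called at the
#' nominal `alpha` (no multiple-testing correction by default, matching
#' nominal reporting; set `adjust = "BH"` for Benjamini-Hochberg).
#'
#' @param target_utrs named character vector of target 3'UTR sequences.
#' @param alpha nominal significance threshold (default 0.005).
#' @param k word size (default 7).
#' @param n_shuffles background shuffles per UTR (default 1).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with one row per k-mer: counts, totals, `p_value`,
#'   `significant`, `gc_fraction`, `is_ccug_pattern`, and `is_mre`/
#'   `mre_families` placeholders filled by [annotate_mres()].
#' @export
enrich_7mers <- function(target_utrs, alpha = 0.005, k = 7L,
                         n_shuffles = 1L, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (length(target_utrs) == 0L) {
    stop("enrich_7mers: no target UTRs", call. = FALSE)
  }
  obs <- count_kmers(target_utrs, k, drop_zero = FALSE)
  kmers <- names(obs)
  bg <- numeric(length(obs))
  for (r in seq_len(n_shuffles)) {
    bg <- bg + count_kmers(dinuc_shuffle(target_utrs), k, drop_zero = FALSE)
  }
  obs_total <- sum(obs); bg_total <- sum(bg)
  p <- fisher_enrichment_p(obs, obs_total - obs, bg, bg_total - bg)
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  ccug <- kmers %in% expand_degenerate("CCUG[AG][AG][AG]")
  data.frame(kmer = kmers,
             obs_count = as.integer(obs), bg_count = as.integer(bg),
             obs_total = obs_total, bg_total = bg_total,
             p_value = p, significant = p < alpha,
             gc_fraction = gc_fraction(kmers),
             is_mre = NA, mre_families = NA_character_,
             is_ccug_pattern = ccug,
             stringsAsFactors = FALSE)
}

#' Expand a degenerate RNA pattern
#'
#' Bracketed choice groups are expanded to all concrete k-mers, e.g.
#' `"CCUG[AG][AG][AG]"` yields the eight CCUG-purine motifs.
#'
#' @param pattern RNA letters with `[..]` choice groups.
#' @return character vector of expansions, lexicographic order, unique.
#' @export
expand_degenerate <- function(pattern) {
  toks <- regmatches(pattern,
                     gregexpr("\\[[ACGUN]+\\]|[ACGUN]", pattern))[[1]]
  if (paste(toks, collapse = "") != pattern) {
    stop("malformed degenerate pattern: ", pattern, call. = FALSE)
  }
  sets <- lapply(toks, function(t) {
    if (startsWith(t, "[")) {
      strsplit(substr(t, 2L, nchar(t) - 1L), "", fixed = TRUE)[[1]]
    } else t
  })
  grid <- do.call(expand.grid,
                  c(rev(sets), list(stringsAsFactors = FALSE)))
  out <- do.call(paste0, rev(grid))
  sort(unique(out))
}

#' Annotate enrichment rows with miRNA recognition elements
#'
#' A k-mer is an MRE when it equals some family's 7m8 or 7A1 site string.
#' The summary compares the MRE fraction among significant k-mers to the
#' chance baseline (the MRE fraction among all 4^k possible k-mers) with a
#' one-sided Fisher exact test; the fraction among non-significant k-mers
#' is also reported as an alternative baseline.
#'
#' @param rows data.frame from [enrich_7mers()].
#' @param families_all family data.frame defining the MRE universe.
#' @param families_topN optional family subset for `mre_families` labels
#'   (defaults to `families_all`).
#' @return list with `rows` (annotated) and `summary` (fractions and p).
#' @export
annotate_mres <- function(rows, families_all, families_topN = NULL) {
  if (is.null(families_topN)) families_topN <- families_all
  mre_map <- c(stats::setNames(families_all$family_id, families_all$s7m8),
               stats::setNames(families_all$family_id, families_all$s7A1))
  rows$is_mre <- rows$kmer %in% names(mre_map)
  lab <- vapply(rows$kmer, function(km) {
    fams <- unique(c(families_topN$family_id[families_topN$s7m8 == km],
                     families_topN$family_id[families_topN$s7A1 == km]))
    paste(fams, collapse = ",")
  }, character(1))
  rows$mre_families <- lab
  ## MRE universe within the supplied k-mer rows (the full 4^k table in
  ## ordinary use, so this equals the number of distinct MRE k-mers)
  n_mre_all <- sum(rows$is_mre)
  n_all <- nrow(rows)
  sig <- rows$significant
  n_sig_mre <- sum(rows$is_mre & sig)
  n_sig <- sum(sig)
  p <- stats::fisher.test(
    matrix(c(n_sig_mre, n_sig - n_sig_mre,
             n_mre_all - n_sig_mre, (n_all - n_mre_all) - (n_sig - n_sig_mre)),
           nrow = 2, byrow = TRUE),
    alternative = "greater")$p.value
  summary <- list(
    frac_mre_significant = if (n_sig > 0L) n_sig_mre / n_sig else NA_real_,
    frac_mre_chance = n_mre_all / n_all,
    frac_mre_nonsignificant =
      if (n_sig < n_all) sum(rows$is_mre & !sig) / (n_all - n_sig) else NA_real_,
    p_value = p)
  list(rows = rows, summary = summary)
}

#' GC content split at a significance pivot
#'
#' Mean GC fraction (with s.e.m.) of significant k-mers stronger than a
#' user-supplied p-value pivot versus the rest, mirroring inset summaries
#' that split at the strongest MRE.
#'
#' @param rows data.frame from [enrich_7mers()].
#' @param pivot_p p-value pivot.
#' @return data.frame with one row per group.
#' @export
gc_split_summary <- function(rows, pivot_p) {
  grp <- ifelse(rows$p_value < pivot_p, "stronger", "weaker_or_ns")
  agg <- lapply(split(rows$gc_fraction, grp), function(v) {
    c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v))
  })
  out <- do.call(rbind, agg)
  data.frame(group = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}
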