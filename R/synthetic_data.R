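## ---------------------------------------------------------------------------
## synthetic_data: a generator for complete synthetic inputs (annotation,
## 3'UTR sequences, miRNAs, siRNAs, junction evidence, five-condition
## expression) with exact planted ground truth.
##
## Design: background 3'UTR sequence is drawn from a constrained alphabet
## in which the forbidden patterns -- GU/AG dinucleotides (cryptic splice
## half-sites), the 6-nt seed cores of every generated miRNA family and of
## every siRNA -- never occur outside deliberately planted intervals. This
## makes planted category labels and planted site counts exactly
## recoverable by the analysis code, so filter precision/recall and
## effect-size recovery can be asserted without slack from chance hits.
## ---------------------------------------------------------------------------

RNA_BASES <- c("A", "C", "G", "U")
UMD_CONDITIONS <- c("control", "siUPF1", "siDicer1", "siUPF1_siDicer1",
                    "siSMG7")

#' Synthetic dataset configuration
#'
#' Defaults encode the study conditions the generator emulates: 3'UTR
#' lengths log-uniform over 50 nt-10 kb, one planted effective site per kb
#' of 3'UTR, 24% of miRNA families with CAG embedded in the seed (12 of
#' 50), a per-site derepression of 0.08 log2 units under UPF1 knockdown
#' with a 0.04 bonus per CUG-embedded site, siSMG7 effects attenuated to
#' 40% of the siUPF1 effect, no miRNA-dependent effect in Dicer1-depleted
#' backgrounds, and gene-wise Gaussian noise of 0.25 log2 units.
#'
#' @param n_genes number of genes.
#' @param utr3_len_range 3'UTR length range in nt (log-uniform; lower
#'   bound must be >= 7).
#' @param frac_spurious,frac_nmd_annotated,frac_dej,frac_cryptic,frac_offtarget
#'   planted category fractions (must sum to <= 1; the remainder is clean).
#' @param frac_low_expression fraction of clean genes pushed below the
#'   expression filter (includes a quarter with zero control FPKM).
#' @param n_mirnas number of miRNAs (one seed family each by default).
#' @param frac_cag_seed fraction of miRNAs with CAG inside positions 2-8.
#' @param site_density planted effective sites per kb of 3'UTR.
#' @param frac_cug_embedded_sites fraction of planted sites drawn from
#'   CAG-seed families (their site strings embed CUG).
#' @param frac_cug_flank fraction of the remaining planted sites that
#'   receive a CUG planted in the 5-nt flank.
#' @param beta_site log2FC per effective site under siUPF1.
#' @param beta_cug_bonus extra log2FC per CUG-embedded site.
#' @param alpha_smg7 multiplicative attenuation of the siSMG7 effect.
#' @param sigma_noise s.d. of gene-wise log2FC noise.
#' @param baseline_fpkm_logmean,baseline_fpkm_logsd log-normal baseline
#'   expression parameters.
#' @param rng_seed integer seed.
#' @return validated list of class `umd_synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 3000L,
                             utr3_len_range = c(50L, 10000L),
                             frac_spurious = 0.1,
                             frac_nmd_annotated = 0.1,
                             frac_dej = 0.1,
                             frac_cryptic = 0.1,
                             frac_offtarget = 0.1,
                             frac_low_expression = 0.02,
                             n_mirnas = 50L,
                             frac_cag_seed = 0.24,
                             site_density = 1.0,
                             frac_cug_embedded_sites = 0.2,
                             frac_cug_flank = 0.3,
                             beta_site = 0.08,
                             beta_cug_bonus = 0.04,
                             alpha_smg7 = 0.4,
                             sigma_noise = 0.25,
                             baseline_fpkm_logmean = 3,
                             baseline_fpkm_logsd = 1.2,
                             rng_seed = 1L) {
  cfg <- as.list(environment())
  fracs <- c(cfg$frac_spurious, cfg$frac_nmd_annotated, cfg$frac_dej,
             cfg$frac_cryptic, cfg$frac_offtarget)
  if (any(fracs < 0 | fracs > 1) || sum(fracs) > 1) {
    stop("category fractions must lie in [0,1] and sum to <= 1",
         call. = FALSE)
  }
  if (cfg$frac_cag_seed < 0 || cfg$frac_cag_seed > 1 ||
      cfg$frac_cug_embedded_sites < 0 || cfg$frac_cug_embedded_sites > 1 ||
      cfg$frac_cug_flank < 0 || cfg$frac_cug_flank > 1 ||
      cfg$frac_low_expression < 0 || cfg$frac_low_expression > 1) {
    stop("fractions must lie in [0,1]", call. = FALSE)
  }
  if (cfg$utr3_len_range[1] < 7L) {
    stop("utr3_len_range lower bound must be >= 7 nt", call. = FALSE)
  }
  if (cfg$beta_site < 0) stop("beta_site must be >= 0", call. = FALSE)
  if (cfg$sigma_noise <= 0) stop("sigma_noise must be > 0", call. = FALSE)
  if (cfg$n_genes < 1L || cfg$n_mirnas < 1L) {
    stop("n_genes and n_mirnas must be >= 1", call. = FALSE)
  }
  cfg$n_genes <- as.integer(cfg$n_genes)
  cfg$n_mirnas <- as.integer(cfg$n_mirnas)
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  class(cfg) <- "umd_synthetic_config"
  cfg
}

.has_forbidden_dinuc <- function(x) {
  grepl("GU", x, fixed = TRUE) | grepl("AG", x, fixed = TRUE)
}

## sample one 7-nt seed (miRNA positions 2-8) whose 8mer site string is free
## of GU/AG and which contains CAG iff want_cag; compatibility: its 6mer
## core must not occur inside any previously accepted 8mer string and no
## previous core may occur inside its own 8mer string
.sample_seed <- function(want_cag, prev_cores, prev_8mers, max_try = 5000L) {
  for (i in seq_len(max_try)) {
    s <- paste(sample(RNA_BASES, 7L, replace = TRUE), collapse = "")
    if (want_cag != grepl("CAG", s, fixed = TRUE)) next
    ss <- site_strings(s)
    if (.has_forbidden_dinuc(ss[["8mer"]])) next
    core <- ss[["6mer"]]
    if (core %in% prev_cores) next
    if (length(prev_8mers) > 0L &&
        (any(vapply(prev_8mers, function(e) grepl(core, e, fixed = TRUE),
                    logical(1))) ||
         any(vapply(prev_cores, function(c0) grepl(c0, ss[["8mer"]],
                                                   fixed = TRUE),
                    logical(1))))) next
    return(s)
  }
  stop("could not sample a compatible seed; relax the configuration",
       call. = FALSE)
}

#' Generate synthetic miRNAs with abundances
#'
#' Mature sequences are 21-22 nt; a configured fraction carries CAG within
#' seed positions 2-8; seeds are pairwise distinct (one family per miRNA)
#' and mutually compatible for exact site-count ground truth. Abundances
#' are drawn from a heavy-tailed log-normal.
#'
#' @param cfg [synthetic_config()] list.
#' @return list with `seqs` (named character vector) and `abundance`
#'   (data.frame `mirna_id`, `abundance`).
#' @export
generate_mirnas <- function(cfg) {
  n <- cfg$n_mirnas
  n_cag <- round(cfg$frac_cag_seed * n)
  if (cfg$frac_cag_seed > 0 && n_cag == 0L) {
    stop("frac_cag_seed unattainable with n_mirnas = ", n, call. = FALSE)
  }
  want <- c(rep(TRUE, n_cag), rep(FALSE, n - n_cag))
  cores <- character(0); e8 <- character(0)
  seqs <- character(n)
  for (i in seq_len(n)) {
    seed <- .sample_seed(want[i], cores, e8)
    ss <- site_strings(seed)
    cores <- c(cores, ss[["6mer"]]); e8 <- c(e8, ss[["8mer"]])
    len <- sample(21:22, 1L)
    tail_len <- len - 8L
    seqs[i] <- paste0(sample(RNA_BASES, 1L), seed,
                      paste(sample(RNA_BASES, tail_len, replace = TRUE),
                            collapse = ""))
  }
  ids <- sprintf("mir-syn-%02d", seq_len(n))
  names(seqs) <- ids
  abundance <- data.frame(
    mirna_id = ids,
    abundance = round(stats::rlnorm(n, meanlog = 4, sdlog = 1.5), 2),
    stringsAsFactors = FALSE)
  list(seqs = seqs, abundance = abundance)
}

## background sequence free of GU/AG dinucleotides, length n (vectorized
## rejection repair)
.background_chars <- function(n) {
  x <- sample(RNA_BASES, n, replace = TRUE)
  repeat {
    bad <- which((x[-n] == "G" & x[-1] == "U") |
                   (x[-n] == "A" & x[-1] == "G"))
    if (length(bad) == 0L) break
    ## rewrite the second character of each forbidden pair; skip adjacent
    ## pairs in the same pass (they are re-checked on the next round)
    bad <- bad[c(TRUE, diff(bad) > 1L)]
    pos <- bad + 1L
    cand <- sample(RNA_BASES, length(pos), replace = TRUE)
    prev <- x[bad]
    nxt <- c(x, "")[pos + 1L]
    ok <- !(prev == "G" & cand == "U") & !(prev == "A" & cand == "G") &
      !(cand == "G" & nxt == "U") & !(cand == "A" & nxt == "G")
    x[pos[ok]] <- cand[ok]
  }
  x
}

## non-overlapping interval sampler: k intervals of width w in [0, L),
## keeping a gap of at least `gap` nt to previously placed intervals
## (matrix with columns start, end); returns as many as fit
.place_intervals <- function(k, w, L, gap, taken, max_try = 200L) {
  placed <- matrix(integer(0), ncol = 2)
  for (j in seq_len(k)) {
    ok <- FALSE
    for (t in seq_len(max_try)) {
      s <- sample.int(L - w + 1L, 1L) - 1L
      e <- s + w
      all_tk <- rbind(taken, placed)
      if (nrow(all_tk) == 0L ||
          all(e + gap <= all_tk[, 1] | s >= all_tk[, 2] + gap)) {
        ok <- TRUE; break
      }
    }
    if (!ok) break
    placed <- rbind(placed, c(s, e))
  }
  placed
}

## TRUE where [s,e) has at least one position outside all protected
## intervals of this gene; returns a vector of unprotected 0-based offsets
.unprotected_offsets <- function(s, e, prot) {
  pos <- s:(e - 1L)
  if (nrow(prot) == 0L) return(pos)
  keep <- vapply(pos, function(p) {
    !any(p >= prot[, 1] & p < prot[, 2])
  }, logical(1))
  pos[keep]
}

## remove every occurrence of `patterns` outside protected intervals by
## point mutations. A mutation is accepted only if, in the local window,
## it creates no new occurrence of any pattern, so the global occurrence
## count decreases strictly and the loop converges. A final forced phase
## (plain repair) covers the rare corner where no safe mutation exists.
.suppress_patterns <- function(seqs, patterns, protected, max_iter = 60L,
                               forced = FALSE) {
  maxw <- max(nchar(patterns))
  count_window <- function(u, p) {
    lo <- max(1L, p + 1L - (maxw - 1L))
    hi <- min(nchar(u), p + 1L + (maxw - 1L))
    win <- substr(u, lo, hi)
    sum(vapply(patterns, function(q) {
      m <- gregexpr(q, win, fixed = TRUE)[[1]]
      if (m[1] == -1L) 0L else length(m)
    }, integer(1)))
  }
  stuck <- 0L
  for (iter in seq_len(max_iter)) {
    n_mut <- 0L; n_open <- 0L
    for (pat in patterns) {
      hits <- gregexpr(pat, seqs, fixed = TRUE)
      w <- nchar(pat)
      for (g in seq_along(seqs)) {
        m <- hits[[g]]
        if (m[1] == -1L) next
        prot <- protected[[g]]
        for (p0 in as.integer(m) - 1L) {
          u <- seqs[g]
          ## re-check: earlier mutations may have removed this occurrence
          if (substr(u, p0 + 1L, p0 + w) != pat) next
          cand <- .unprotected_offsets(p0, p0 + w, prot)
          if (length(cand) == 0L) next   # a planted occurrence; keep
          cand <- cand[order(abs(cand - (p0 + w / 2)))]
          done <- FALSE
          for (p in cand) {
            old <- substr(u, p + 1L, p + 1L)
            prev <- if (p >= 1L) substr(u, p, p) else ""
            nxt <- substr(u, p + 2L, p + 2L)
            allowed <- setdiff(RNA_BASES, old)
            if (prev == "G") allowed <- setdiff(allowed, "U")
            if (prev == "A") allowed <- setdiff(allowed, "G")
            if (nxt == "U") allowed <- setdiff(allowed, "G")
            if (nxt == "G") allowed <- setdiff(allowed, "A")
            if (length(allowed) == 0L) next
            allowed <- allowed[sample.int(length(allowed))]
            before <- if (forced) 0L else count_window(u, p)
            for (b in allowed) {
              u2 <- u
              substr(u2, p + 1L, p + 1L) <- b
              if (forced || count_window(u2, p) < before) {
                seqs[g] <- u2
                n_mut <- n_mut + 1L
                done <- TRUE
                break
              }
            }
            if (done) break
          }
          if (!done) n_open <- n_open + 1L
        }
      }
    }
    if (n_open == 0L && n_mut == 0L) break
    if (n_mut == 0L && n_open > 0L) {
      ## no safe mutation found for the remaining occurrences: repair
      ## them plainly once, then resume safe iterations
      stuck <- stuck + 1L
      if (stuck > 3L) break
      seqs <- .suppress_patterns(seqs, patterns, protected, max_iter = 1L,
                                 forced = TRUE)
    }
  }
  seqs
}

## Core-based effective/6mer occurrence finder used for ground-truth
## reconciliation (same locus conventions as scan_sites, minimal columns).
.core_occurrences <- function(seqs, fams) {
  out <- list()
  for (f in seq_len(nrow(fams))) {
    core <- fams$s6mer[f]
    m8char <- substr(fams$s7m8[f], 1L, 1L)
    hits <- gregexpr(core, seqs, fixed = TRUE)
    for (g in seq_along(seqs)) {
      m <- hits[[g]]
      if (m[1] == -1L) next
      u <- seqs[[g]]
      p0 <- as.integer(m) - 1L
      prev <- substr(rep(u, length(p0)), p0, p0)
      nxt <- substr(rep(u, length(p0)), p0 + 7L, p0 + 7L)
      is_m8 <- prev == m8char
      is_a1 <- nxt == "A"
      out[[length(out) + 1L]] <- data.frame(
        gene_id = names(seqs)[g], family_id = fams$family_id[f],
        site_type = .site_type_at(is_m8, is_a1),
        start = ifelse(is_m8, p0 - 1L, p0),
        end = ifelse(is_a1, p0 + 7L, p0 + 6L),
        core_pos = p0, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

## fold residual chance occurrences (rare: wedged between protected
## intervals where no safe repair exists) into the planted-site table
.reconcile_residual_sites <- function(seqs, fams, planted) {
  occ <- .core_occurrences(seqs, fams)
  if (is.null(occ)) return(planted)
  planted_core <- ifelse(planted$site_type %in% c("8mer", "7m8"),
                         planted$start + 1L, planted$start)
  key_p <- paste(planted$gene_id, planted$family_id, planted_core)
  key_o <- paste(occ$gene_id, occ$family_id, occ$core_pos)
  extra <- occ[!key_o %in% key_p, , drop = FALSE]
  extra <- extra[!duplicated(paste(extra$gene_id, extra$start, extra$end)), ,
                 drop = FALSE]
  if (nrow(extra) == 0L) return(planted)
  cag <- stats::setNames(grepl("CAG", fams$seed28, fixed = TRUE),
                         fams$family_id)
  rbind(planted,
        data.frame(gene_id = extra$gene_id, family_id = extra$family_id,
                   site_type = extra$site_type, start = extra$start,
                   end = extra$end,
                   cag_family = unname(cag[extra$family_id]),
                   flank_cug = FALSE, stringsAsFactors = FALSE))
}

## genomic exon/CDS intervals for one transcript given segment boundaries
.gene_geometry <- function(utr5, cds, utr3, junc_tcs, strand, base,
                           intron = 150L) {
  total <- utr5 + cds + utr3
  bnd <- sort(unique(junc_tcs))
  bnd <- bnd[bnd > 0L & bnd < total]
  seg_lo <- c(0L, bnd); seg_hi <- c(bnd, total)
  k <- length(seg_lo)
  G <- total + intron * (k - 1L)
  map_iv <- function(a, b) {
    ## map transcript interval [a,b) to genomic intervals per segment
    out <- matrix(integer(0), ncol = 2)
    for (i in seq_len(k)) {
      lo <- max(a, seg_lo[i]); hi <- min(b, seg_hi[i])
      if (lo >= hi) next
      if (strand == "+") {
        out <- rbind(out, c(base + lo + intron * (i - 1L),
                            base + hi + intron * (i - 1L)))
      } else {
        out <- rbind(out, c(base + G - (hi + intron * (i - 1L)),
                            base + G - (lo + intron * (i - 1L))))
      }
    }
    out[order(out[, 1]), , drop = FALSE]
  }
  exons <- map_iv(0L, total)
  cds_iv <- map_iv(utr5, utr5 + cds)
  ## intron intervals in genomic coordinates (for junction BED evidence)
  introns <- if (k > 1L) {
    cbind(exons[-k, 2], exons[-1, 1])
  } else matrix(integer(0), ncol = 2)
  list(exons = exons, cds = cds_iv, introns = introns, span = G)
}

#' Generate a synthetic transcriptome with planted ground truth
#'
#' Builds transcript models (one transcript per gene), 3'UTR sequences,
#' junction evidence and a ground-truth table. Planted categories:
#' `spurious` genes violate exactly one structural rule (5'UTR >= 25 /
#' CDS >= 200 / 3'UTR >= 50); `dej` genes carry an annotated and
#' evidence-supported junction > 50 nt downstream of the stop codon;
#' `cryptic` genes carry a GU...AG signal with inner distance > 60 nt;
#' `offtarget` genes carry a planted siRNA 7-mer site; `nmd_annotated`
#' genes appear in the returned flag list. Planted miRNA sites never
#' overlap; their count is Poisson with mean `site_density` per kb, and
#' outside planted intervals the sequence contains no seed core of any
#' generated family or siRNA and no GU/AG dinucleotide, so planted counts
#' and labels are exact.
#'
#' @param cfg [synthetic_config()] list.
#' @param mirnas output of [generate_mirnas()].
#' @param sirnas optional named character vector of siRNA guides; two are
#'   generated when NULL.
#' @return list with `models`, `utr3` (sequences), `junctions` (BED-style
#'   data.frame of supported introns), `ground_truth`, `planted_sites`,
#'   `families`, `sirnas`, `nmd_flags`.
#' @export
generate_transcriptome <- function(cfg, mirnas, sirnas = NULL) {
  n <- cfg$n_genes
  fams <- build_families(mirnas$seqs, mirnas$abundance)
  fam_cag <- grepl("CAG", fams$seed28, fixed = TRUE)
  if (is.null(sirnas)) {
    cores <- fams$s6mer; e8 <- fams$s8mer
    s_seqs <- character(2)
    for (i in 1:2) {
      seed <- .sample_seed(FALSE, cores, e8)
      ss <- site_strings(seed)
      cores <- c(cores, ss[["6mer"]]); e8 <- c(e8, ss[["8mer"]])
      s_seqs[i] <- paste0(sample(RNA_BASES, 1L), seed,
                          paste(sample(RNA_BASES, 13L, replace = TRUE),
                                collapse = ""))
    }
    sirnas <- stats::setNames(s_seqs, c("siRNA-guide-1", "siRNA-scramble"))
  }
  sirna_fams <- build_families(
    sirnas, data.frame(mirna_id = names(sirnas),
                       abundance = rep(1, length(sirnas))))

  ## ---- category assignment -------------------------------------------
  counts <- vapply(
    c(cfg$frac_spurious, cfg$frac_nmd_annotated, cfg$frac_dej,
      cfg$frac_cryptic, cfg$frac_offtarget),
    function(f) as.integer(round(f * n)), integer(1))
  cat_lab <- rep("clean", n)
  idx <- 1L
  for (ci in seq_along(counts)) {
    lab <- c("spurious", "nmd_annotated", "dej", "cryptic", "offtarget")[ci]
    if (counts[ci] > 0L) {
      cat_lab[idx:(idx + counts[ci] - 1L)] <- lab
      idx <- idx + counts[ci]
    }
  }
  gene_ids <- sprintf("gene%05d", seq_len(n))

  ## ---- structural lengths --------------------------------------------
  lo <- cfg$utr3_len_range[1]; hi <- cfg$utr3_len_range[2]
  utr3_len <- as.integer(round(exp(stats::runif(n, log(lo), log(hi)))))
  utr5_len <- sample(50:300, n, replace = TRUE)
  cds_len <- 3L * sample(100:500, n, replace = TRUE)
  spur_type <- integer(n)
  for (i in which(cat_lab == "spurious")) {
    spur_type[i] <- sample(1:3, 1L)
    if (spur_type[i] == 1L) utr5_len[i] <- sample(5:24, 1L)
    if (spur_type[i] == 2L) cds_len[i] <- 3L * sample(20:66, 1L)
    if (spur_type[i] == 3L) utr3_len[i] <- sample(10:49, 1L)
  }
  utr3_len[cat_lab == "dej"] <- pmax(utr3_len[cat_lab == "dej"], 150L)
  utr3_len[cat_lab == "cryptic"] <- pmax(utr3_len[cat_lab == "cryptic"], 250L)

  ## ---- 3'UTR background ----------------------------------------------
  all_bg <- .background_chars(sum(utr3_len))
  splits <- rep(seq_len(n), utr3_len)
  seqs <- vapply(split(all_bg, splits), paste, character(1), collapse = "")
  names(seqs) <- gene_ids

  ## ---- planting -------------------------------------------------------
  protected <- rep(list(matrix(integer(0), ncol = 2)), n)
  cryptic_plant <- vector("list", n)
  site_rows <- vector("list", n)
  n_sites <- integer(n); n_sites_cug <- integer(n)
  cag_pool <- which(fam_cag); nocag_pool <- which(!fam_cag)
  for (i in seq_len(n)) {
    L <- utr3_len[i]
    u <- seqs[[i]]
    prot <- matrix(integer(0), ncol = 2)
    ## cryptic splice signal: GU ... AG with inner distance > 60
    if (cat_lab[i] == "cryptic") {
      gap <- sample(61:120, 1L)
      a <- sample.int(L - (gap + 4L), 1L) - 1L
      substr(u, a + 1L, a + 2L) <- "GU"
      b <- a + 2L + gap
      substr(u, b + 1L, b + 2L) <- "AG"
      prot <- rbind(prot, c(a, a + 2L), c(b, b + 2L))
      cryptic_plant[[i]] <- c(a, b)
    }
    ## siRNA off-target site (7m8 of guide 1)
    if (cat_lab[i] == "offtarget" && L >= 9L) {
      pat <- sirna_fams$s7m8[sirna_fams$family_id == names(sirnas)[1]]
      iv <- .place_intervals(1L, nchar(pat), L, 2L, prot)
      if (nrow(iv) == 1L) {
        substr(u, iv[1, 1] + 1L, iv[1, 2]) <- pat
        prot <- rbind(prot, iv)
      }
    }
    ## miRNA sites: Poisson(site_density per kb)
    k <- stats::rpois(1L, cfg$site_density * L / 1000)
    rows <- NULL
    if (k > 0L && L >= 20L) {
      for (j in seq_len(k)) {
        use_cag <- length(cag_pool) > 0L &&
          stats::runif(1) < cfg$frac_cug_embedded_sites
        f <- if (use_cag) cag_pool[sample.int(length(cag_pool), 1L)]
             else nocag_pool[sample.int(length(nocag_pool), 1L)]
        ty <- sample(EFFECTIVE_TYPES, 1L, prob = c(0.25, 0.45, 0.30))
        pat <- switch(ty, "8mer" = fams$s8mer[f], "7m8" = fams$s7m8[f],
                      "7A1" = fams$s7A1[f])
        iv <- .place_intervals(1L, nchar(pat), L, 8L, prot)
        if (nrow(iv) == 0L) next
        substr(u, iv[1, 1] + 1L, iv[1, 2]) <- pat
        prot <- rbind(prot, iv)
        flank_cug <- FALSE
        if (!use_cag && stats::runif(1) < cfg$frac_cug_flank) {
          ## place CUG wholly inside the 5-nt flank, 1-2 nt off the edge
          d <- sample(1:2, 1L)
          cs <- if (stats::runif(1) < 0.5) iv[1, 1] - d - 3L
                else iv[1, 2] + d
          if (cs >= 0L && cs + 3L <= L &&
              length(.unprotected_offsets(cs, cs + 3L, prot)) == 3L) {
            substr(u, cs + 1L, cs + 3L) <- "CUG"
            prot <- rbind(prot, c(cs, cs + 3L))
            flank_cug <- TRUE
          }
        }
        rows <- rbind(rows, data.frame(
          gene_id = gene_ids[i], family_id = fams$family_id[f],
          site_type = ty, start = iv[1, 1], end = iv[1, 2],
          cag_family = use_cag, flank_cug = flank_cug,
          stringsAsFactors = FALSE))
      }
    }
    if (!is.null(rows)) {
      site_rows[[i]] <- rows
      n_sites[i] <- nrow(rows)
      n_sites_cug[i] <- sum(rows$cag_family)
    }
    seqs[i] <- u
    protected[[i]] <- prot
  }

  ## ---- suppression of chance hits ------------------------------------
  forb <- unique(c("GU", "AG", fams$s6mer, sirna_fams$s6mer))
  seqs <- .suppress_patterns(seqs, forb, protected)

  ## ---- ground-truth site table (planted + rare residuals) ------------
  planted_sites <- do.call(rbind, site_rows[!vapply(site_rows, is.null,
                                                    logical(1))])
  if (is.null(planted_sites)) {
    planted_sites <- data.frame(gene_id = character(0),
                                family_id = character(0),
                                site_type = character(0),
                                start = integer(0), end = integer(0),
                                cag_family = logical(0),
                                flank_cug = logical(0),
                                stringsAsFactors = FALSE)
  }
  planted_sites <- .reconcile_residual_sites(seqs, fams, planted_sites)
  eff <- planted_sites[planted_sites$site_type %in% EFFECTIVE_TYPES, ,
                       drop = FALSE]
  n_sites <- as.integer(table(factor(eff$gene_id, levels = gene_ids)))
  n_sites_cug <- as.integer(table(factor(eff$gene_id[eff$cag_family],
                                         levels = gene_ids)))

  ## ---- gene geometry, models, junction evidence ----------------------
  model_rows <- vector("list", n)
  junc_rows <- vector("list", n)
  base <- 0L
  strands <- rep(c("+", "-"), length.out = n)
  boundary_utr_junc <- cat_lab == "clean" & stats::runif(n) < 0.15 &
    utr3_len >= 80L
  for (i in seq_len(n)) {
    stop_tc <- utr5_len[i] + cds_len[i]
    junc_tcs <- utr5_len[i] + as.integer(floor(cds_len[i] / 2))
    if (cat_lab[i] == "dej") {
      j <- sample(51:min(500L, utr3_len[i] - 10L), 1L)
      junc_tcs <- c(junc_tcs, stop_tc + j)
    } else if (boundary_utr_junc[i]) {
      j <- sample(0:50, 1L)
      junc_tcs <- c(junc_tcs, stop_tc + j)
    }
    geo <- .gene_geometry(utr5_len[i], cds_len[i], utr3_len[i],
                          junc_tcs, strands[i], base)
    model_rows[[i]] <- .model_row(
      transcript_id = paste0(gene_ids[i], ".t1"), gene_id = gene_ids[i],
      chrom = "chrS", strand = strands[i],
      starts = geo$exons[, 1], ends = geo$exons[, 2],
      cds_lo = min(geo$cds[, 1]), cds_hi = max(geo$cds[, 2]))
    if (nrow(geo$introns) > 0L) {
      junc_rows[[i]] <- data.frame(
        chrom = "chrS", start = geo$introns[, 1], end = geo$introns[, 2],
        name = gene_ids[i], score = 1L, strand = strands[i],
        stringsAsFactors = FALSE)
    }
    base <- base + geo$span + 500L
  }
  models <- do.call(rbind, model_rows)
  junctions <- do.call(rbind, junc_rows[!vapply(junc_rows, is.null,
                                                logical(1))])

  ## ---- low-expression flags ------------------------------------------
  clean_idx <- which(cat_lab == "clean")
  n_low <- round(cfg$frac_low_expression * n)
  low_idx <- if (n_low > 0L && length(clean_idx) > 0L) {
    clean_idx[sample.int(length(clean_idx), min(n_low, length(clean_idx)))]
  } else integer(0)
  zero_ctrl_idx <- if (length(low_idx) >= 4L) {
    low_idx[seq_len(floor(length(low_idx) / 4))]
  } else integer(0)

  ground_truth <- data.frame(
    gene_id = gene_ids, category = cat_lab,
    spurious = cat_lab == "spurious",
    nmd_annotated = cat_lab == "nmd_annotated",
    dej = cat_lab == "dej",
    cryptic = cat_lab == "cryptic",
    offtarget = cat_lab == "offtarget",
    low_expression = seq_len(n) %in% low_idx,
    zero_control = seq_len(n) %in% zero_ctrl_idx,
    utr3_len = utr3_len,
    n_sites = n_sites,
    n_sites_cug = n_sites_cug,
    stringsAsFactors = FALSE)
  ## expected per-condition log2 fold-changes (miRNA-effect model)
  e_upf1 <- cfg$beta_site * n_sites + cfg$beta_cug_bonus * n_sites_cug
  ground_truth$exp_lfc_siUPF1 <- e_upf1
  ground_truth$exp_lfc_siDicer1 <- 0
  ground_truth$exp_lfc_siUPF1_siDicer1 <- 0
  ground_truth$exp_lfc_siSMG7 <- cfg$alpha_smg7 * e_upf1

  list(models = models, utr3 = seqs, junctions = junctions,
       ground_truth = ground_truth, planted_sites = planted_sites,
       families = fams, sirnas = sirnas,
       nmd_flags = gene_ids[cat_lab == "nmd_annotated"])
}

#' Simulate five-condition expression from ground truth
#'
#' Per-condition log2 fold-change versus control is the ground-truth
#' expected effect plus independent Gaussian noise; FPKM in a knockdown is
#' the control FPKM scaled by 2^log2FC; FPM is FPKM times the spliced
#' transcript length in kb. Genes flagged `low_expression` are scaled so
#' their siUPF1 FPM falls below 3 (exercising the expression filter);
#' `zero_control` genes get zero control expression.
#'
#' @param models transcript model data.frame (spliced lengths).
#' @param ground_truth ground-truth data.frame from
#'   [generate_transcriptome()].
#' @param cfg [synthetic_config()] list.
#' @return long-form expression data.frame (`gene_id`, `condition`,
#'   `fpkm`, `fpm`).
#' @export
simulate_expression <- function(models, ground_truth, cfg) {
  gt <- ground_truth
  n <- nrow(gt)
  kb <- models$spliced_len[match(gt$gene_id, models$gene_id)] / 1000
  fpkm0 <- stats::rlnorm(n, cfg$baseline_fpkm_logmean, cfg$baseline_fpkm_logsd)
  low <- gt$low_expression & !gt$zero_control
  ## noise is truncated at +/- 6 s.d. (statistically invisible) so the
  ## expression-filter labels below are guaranteed, not just likely
  trunc6 <- function(z) pmin(pmax(z, -6 * cfg$sigma_noise),
                             6 * cfg$sigma_noise)
  expected <- cbind(control = 0,
                    siUPF1 = gt$exp_lfc_siUPF1,
                    siDicer1 = gt$exp_lfc_siDicer1,
                    siUPF1_siDicer1 = gt$exp_lfc_siUPF1_siDicer1,
                    siSMG7 = gt$exp_lfc_siSMG7)
  lfc <- matrix(0, n, length(UMD_CONDITIONS),
                dimnames = list(NULL, UMD_CONDITIONS))
  for (cond in setdiff(UMD_CONDITIONS, "control")) {
    lfc[, cond] <- expected[, cond] + trunc6(stats::rnorm(n, 0, cfg$sigma_noise))
  }
  ## unflagged genes stay comfortably above 3 FPM in every knockdown
  ## (noise bound 2^(6 sigma)); flagged low-expression genes are scaled so
  ## their siUPF1 FPM falls strictly below 3
  floor_fpkm <- 3.05 * 2^(6 * cfg$sigma_noise) / kb
  fpkm0[!low & !gt$zero_control] <- pmax(fpkm0[!low & !gt$zero_control],
                                         floor_fpkm[!low & !gt$zero_control])
  if (any(low)) {
    target_fpm <- stats::runif(sum(low), 0.3, 2.5)
    fpkm0[low] <- target_fpm / kb[low] / 2^lfc[low, "siUPF1"]
  }
  fpkm0[gt$zero_control] <- 0
  out <- vector("list", length(UMD_CONDITIONS))
  for (ci in seq_along(UMD_CONDITIONS)) {
    cond <- UMD_CONDITIONS[ci]
    fpkm <- fpkm0 * 2^lfc[, cond]
    out[[ci]] <- data.frame(gene_id = gt$gene_id, condition = cond,
                            fpkm = fpkm, fpm = fpkm * kb,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a complete synthetic dataset
#'
#' Seeds the RNG from `cfg$rng_seed` and runs [generate_mirnas()],
#' [generate_transcriptome()] and [simulate_expression()] in order, so a
#' given configuration yields byte-identical outputs.
#'
#' @param cfg [synthetic_config()] list.
#' @return list combining all generator outputs plus `expression` and
#'   `abundance`.
#' @export
generate_umd_dataset <- function(cfg = synthetic_config()) {
  set.seed(cfg$rng_seed)
  mir <- generate_mirnas(cfg)
  tr <- generate_transcriptome(cfg, mir)
  expr <- simulate_expression(tr$models, tr$ground_truth, cfg)
  c(tr, list(mirnas = mir$seqs, abundance = mir$abundance,
             expression = expr, config = cfg))
}

#' Write a synthetic dataset to standard-format files
#'
#' Writes GTF (annotation), FASTA (3'UTRs, miRNAs), plain-text siRNA
#' guides, BED6 (junction evidence), and TSVs (expression, miRNA
#' abundance, NMD flags, ground truth).
#'
#' @param ds dataset list from [generate_umd_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
write_umd_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(gtf = file.path(dir, "annotation.gtf"),
             utr3 = file.path(dir, "utr3.fa"),
             mirnas = file.path(dir, "mirnas.fa"),
             sirnas = file.path(dir, "sirnas.txt"),
             junctions = file.path(dir, "junctions.bed"),
             expression = file.path(dir, "expression.tsv"),
             abundance = file.path(dir, "mirna_abundance.tsv"),
             nmd_flags = file.path(dir, "nmd_flags.tsv"),
             ground_truth = file.path(dir, "ground_truth.tsv"))
  .write_models_gtf(ds$models, paths["gtf"])
  write_fasta(ds$utr3, paths["utr3"])
  write_fasta(ds$mirnas, paths["mirnas"])
  writeLines(paste(names(ds$sirnas), ds$sirnas, sep = "\t"),
             paths["sirnas"])
  utils::write.table(ds$junctions, paths["junctions"], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tsv_file(ds$expression, paths["expression"])
  write_tsv_file(ds$abundance, paths["abundance"])
  write_tsv_file(data.frame(gene_id = ds$nmd_flags), paths["nmd_flags"])
  write_tsv_file(ds$ground_truth, paths["ground_truth"])
  paths
}

.write_models_gtf <- function(models, path) {
  lines <- character(0)
  for (i in seq_len(nrow(models))) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     models$gene_id[i], models$transcript_id[i])
    es <- models$exon_starts[[i]]; ee <- models$exon_ends[[i]]
    lines <- c(lines, sprintf("%s\tumdecay\texon\t%d\t%d\t.\t%s\t.\t%s",
                              models$chrom[i], es + 1L, ee,
                              models$strand[i], attrs))
    ## CDS features: intersect CDS genomic span with each exon
    lo <- models$cds_start[i]; hi <- models$cds_end[i]
    cl <- pmax(es, lo); ch <- pmin(ee, hi)
    keep <- cl < ch
    lines <- c(lines, sprintf("%s\tumdecay\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                              models$chrom[i], cl[keep] + 1L, ch[keep],
                              models$strand[i], attrs))
  }
  writeLines(lines, path)
  invisible(path)
}
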