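## ---------------------------------------------------------------------------
## mirna_sites: seed families, site-type strings, 3'UTR scanning, effective
## site counts and weighted context++ score summation.
##
## Site-type definitions (target strand, 5'->3'):
##   7m8  = reverse complement of miRNA positions 2-8
##   6mer = reverse complement of miRNA positions 2-7
##   8mer = 7m8 + "A"      (A opposite miRNA position 1)
##   7A1  = 6mer + "A"
##   offset-6mer = reverse complement of miRNA positions 3-8
## ---------------------------------------------------------------------------

#' Seed-match site classes
#'
#' `SITE_TYPES` lists the five site classes, maximal first;
#' `EFFECTIVE_TYPES` the 7-mer classes counted as effective target sites.
#'
#' @export
SITE_TYPES <- c("8mer", "7m8", "7A1", "6mer", "offset6mer")

#' @rdname SITE_TYPES
#' @export
EFFECTIVE_TYPES <- c("8mer", "7m8", "7A1")

#' Derive the five site-type strings for a seed
#'
#' @param seed28 7-nt miRNA positions 2-8 (RNA alphabet).
#' @return named character vector with elements `8mer`, `7m8`, `7A1`,
#'   `6mer`, `offset6mer`.
#' @export
site_strings <- function(seed28) {
  stopifnot(nchar(seed28) == 7L)
  s7m8 <- rna_revcomp(seed28)
  s6 <- rna_revcomp(substr(seed28, 1L, 6L))
  soff <- rna_revcomp(substr(seed28, 2L, 7L))
  c("8mer" = paste0(s7m8, "A"),
    "7m8" = s7m8,
    "7A1" = paste0(s6, "A"),
    "6mer" = s6,
    "offset6mer" = soff)
}

#' Collapse miRNAs into seed families
#'
#' miRNAs sharing positions 2-8 form one family (the TargetScan family
#' convention; set `seed_span = c(2, 7)` for 6-nt families). Family
#' abundance is the sum of member abundances; the family is named after its
#' most abundant member. Families are returned sorted by decreasing
#' abundance.
#'
#' @param mirnas named character vector of mature miRNA sequences (>= 8 nt).
#' @param abundance data.frame with columns `mirna_id`, `abundance`.
#' @param seed_span positions defining the family key (default 2-8).
#' @return data.frame with columns `family_id`, `seed27`, `seed28`,
#'   `abundance`, list-column `members`, and the five site-string columns.
#' @export
build_families <- function(mirnas, abundance, seed_span = c(2L, 8L)) {
  short <- nchar(mirnas) < 8L
  if (any(short)) {
    stop("miRNA shorter than 8 nt: ", names(mirnas)[short][1], call. = FALSE)
  }
  ab <- stats::setNames(abundance$abundance, abundance$mirna_id)[names(mirnas)]
  ab[is.na(ab)] <- 0
  key <- substr(mirnas, seed_span[1], seed_span[2])
  fams <- lapply(split(seq_along(mirnas), key), function(i) {
    i <- i[order(-ab[i], names(mirnas)[i])]
    m1 <- mirnas[[i[1]]]
    seed28 <- substr(m1, 2L, 8L)
    ss <- site_strings(seed28)
    data.frame(family_id = names(mirnas)[i[1]],
               seed27 = substr(m1, 2L, 7L),
               seed28 = seed28,
               abundance = sum(ab[i]),
               members = I(list(names(mirnas)[i])),
               s8mer = ss[["8mer"]], s7m8 = ss[["7m8"]], s7A1 = ss[["7A1"]],
               s6mer = ss[["6mer"]], soffset6mer = ss[["offset6mer"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, unname(fams))
  out <- out[order(-out$abundance, out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the N most abundant families
#'
#' @param families output of [build_families()].
#' @param n number of families to keep.
#' @return the top `n` rows by abundance.
#' @export
top_families <- function(families, n) {
  utils::head(families, n)
}

## type resolution for a 6mer-core match given its boundary characters
.site_type_at <- function(prev_is_m8, next_is_a) {
  ifelse(prev_is_m8 & next_is_a, "8mer",
         ifelse(prev_is_m8, "7m8",
                ifelse(next_is_a, "7A1", "6mer")))
}

#' Scan 3'UTRs for miRNA seed-match sites
#'
#' Reports every occurrence (overlapping occurrences allowed) of the
#' requested site types for each family. At a single locus matching several
#' types of the same family only the maximal type is reported
#' (8mer over 7m8/7A1 over 6mer); an offset-6mer is reported only where it
#' cannot be extended into a 7m8 match. Sites of different families are all
#' reported even when they overlap. A terminal core match with no following
#' nucleotide cannot be 8mer/7A1 (there is no opposite-position base).
#' Matching is literal over A/C/G/U, so windows containing N never match.
#'
#' @param utrs named character vector of 3'UTR sequences keyed by gene id.
#' @param families data.frame from [build_families()].
#' @param types site types to report (subset of
#'   `c("8mer","7m8","7A1","6mer","offset6mer")`).
#' @param flank_window nt of flank used to call `cug_relation = "nearby"`.
#' @return data.frame with columns `gene_id`, `family_id`, `site_type`,
#'   `start`, `end` (0-based half-open in the 3'UTR) and `cug_relation`
#'   (`embedded`, `nearby`, `none`).
#' @export
scan_sites <- function(utrs, families, types = EFFECTIVE_TYPES,
                       flank_window = 5L) {
  stopifnot(all(types %in% SITE_TYPES))
  genes <- names(utrs)
  res <- list()
  for (f in seq_len(nrow(families))) {
    core <- families$s6mer[f]
    m8char <- substr(families$s7m8[f], 1L, 1L)
    ext7m8 <- substr(families$s7m8[f], 7L, 7L)
    hits <- gregexpr(core, utrs, fixed = TRUE)
    offhits <- if ("offset6mer" %in% types) {
      gregexpr(families$soffset6mer[f], utrs, fixed = TRUE)
    } else NULL
    for (g in seq_along(utrs)) {
      u <- utrs[[g]]
      pos <- hits[[g]]
      starts0 <- integer(0); ends0 <- integer(0); type <- character(0)
      if (pos[1] != -1L) {
        p0 <- as.integer(pos) - 1L             # 0-based core starts
        prev <- substr(rep(u, length(p0)), p0, p0)        # char at p0-1 (1-based p0)
        nxt <- substr(rep(u, length(p0)), p0 + 7L, p0 + 7L)
        is_m8 <- prev == m8char
        is_a1 <- nxt == "A"
        ty <- .site_type_at(is_m8, is_a1)
        s0 <- ifelse(is_m8, p0 - 1L, p0)
        e0 <- ifelse(is_a1, p0 + 7L, p0 + 6L)
        starts0 <- c(starts0, s0); ends0 <- c(ends0, e0); type <- c(type, ty)
      }
      if (!is.null(offhits)) {
        pos2 <- offhits[[g]]
        if (pos2[1] != -1L) {
          q0 <- as.integer(pos2) - 1L
          nxt2 <- substr(rep(u, length(q0)), q0 + 7L, q0 + 7L)
          keep <- nxt2 != ext7m8   # extendable to 7m8 -> covered above
          if (any(keep)) {
            starts0 <- c(starts0, q0[keep])
            ends0 <- c(ends0, q0[keep] + 6L)
            type <- c(type, rep("offset6mer", sum(keep)))
          }
        }
      }
      if (length(starts0) == 0L) next
      df <- data.frame(gene_id = genes[g], family_id = families$family_id[f],
                       site_type = type, start = starts0, end = ends0,
                       stringsAsFactors = FALSE)
      ## drop duplicate loci (possible for repetitive seeds), keep maximal type
      pr <- match(df$site_type, SITE_TYPES)
      df <- df[order(df$start, pr), , drop = FALSE]
      df <- df[!duplicated(df[c("start", "end")]), , drop = FALSE]
      res[[length(res) + 1L]] <- df
    }
  }
  ann <- if (length(res) > 0L) do.call(rbind, res) else
    data.frame(gene_id = character(0), family_id = character(0),
               site_type = character(0), start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
  ann <- ann[ann$site_type %in% types, , drop = FALSE]
  ann$cug_relation <- .cug_relation(utrs, ann, flank_window)
  rownames(ann) <- NULL
  ann
}

## embedded / nearby / none classification of each site w.r.t. CUG motifs;
## a CUG is "nearby" if any of its bases falls in the flank window on either
## side of the site
.cug_relation <- function(utrs, ann, window) {
  if (nrow(ann) == 0L) return(character(0))
  cug_pos <- lapply(utrs, function(u) fixed_matches0("CUG", u))
  rel <- character(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    u <- utrs[[ann$gene_id[i]]]
    s <- ann$start[i]; e <- ann$end[i]
    if (grepl("CUG", substr(u, s + 1L, e), fixed = TRUE)) {
      rel[i] <- "embedded"
      next
    }
    c0 <- cug_pos[[ann$gene_id[i]]]
    up <- any(c0 + 3L > s - window & c0 < s)
    dn <- any(c0 + 3L > e & c0 < e + window)
    rel[i] <- if (up || dn) "nearby" else "none"
  }
  rel
}

#' Count effective 7-mer sites
#'
#' Effective sites are the 8mer, 7m8 and 7A1 site classes.
#'
#' @param annotations site annotation data.frame from [scan_sites()]
#'   (typically for one gene).
#' @return integer count.
#' @export
count_effective_sites <- function(annotations) {
  sum(annotations$site_type %in% EFFECTIVE_TYPES)
}

#' Effective 7-mer site counts per gene
#'
#' @param annotations site annotation data.frame from [scan_sites()].
#' @param genes gene universe (genes without sites get 0).
#' @return named integer vector over `genes`.
#' @export
effective_site_counts <- function(annotations, genes) {
  eff <- annotations[annotations$site_type %in% EFFECTIVE_TYPES, , drop = FALSE]
  tab <- table(factor(eff$gene_id, levels = genes))
  stats::setNames(as.integer(tab), genes)
}

#' Sum weighted context++ scores with overlap resolution
#'
#' Site efficacy scores (more negative = stronger predicted repression) are
#' summed per gene over non-overlapping sites. Where sites of different
#' miRNAs overlap, the site with greater efficacy (more negative score) is
#' kept: a greedy sweep accepts sites in ascending score order and discards
#' any site overlapping an accepted one.
#'
#' @param annotations site annotation data.frame (effective sites).
#' @param score_table data.frame with columns `gene_id`, `family_id`,
#'   `start`, `score` (scores <= 0 by convention; positive scores trigger a
#'   warning but are still summed).
#' @return named numeric vector of per-gene score sums (0 for genes with no
#'   scored sites).
#' @export
sum_wcontext <- function(annotations, score_table) {
  if (any(score_table$score > 0)) {
    warning("positive wContext++ score(s) in score table; summed as given",
            call. = FALSE)
  }
  key_ann <- paste(annotations$gene_id, annotations$family_id,
                   annotations$start)
  key_sc <- paste(score_table$gene_id, score_table$family_id,
                  score_table$start)
  score <- score_table$score[match(key_ann, key_sc)]
  ann <- annotations[!is.na(score), , drop = FALSE]
  score <- score[!is.na(score)]
  genes <- unique(annotations$gene_id)
  out <- stats::setNames(numeric(length(genes)), genes)
  for (g in unique(ann$gene_id)) {
    i <- which(ann$gene_id == g)
    i <- i[order(score[i])]
    taken_s <- integer(0); taken_e <- integer(0); total <- 0
    for (k in i) {
      s <- ann$start[k]; e <- ann$end[k]
      if (length(taken_s) == 0L || all(e <= taken_s | s >= taken_e)) {
        total <- total + score[k]
        taken_s <- c(taken_s, s); taken_e <- c(taken_e, e)
      }
    }
    out[g] <- total
  }
  out
}
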