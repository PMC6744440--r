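## ---------------------------------------------------------------------------
## transcript_filter: the dEJ-free filtering cascade with per-step
## exclusion accounting.
##
## Steps, in order: spurious structure -> annotated NMD -> dEJ / cryptic
## splice signal -> expression -> siRNA off-target.
## ---------------------------------------------------------------------------

#' Classify spurious transcript structures
#'
#' A transcript is spurious unless 5'UTR >= 25 nt, CDS >= 200 nt and
#' 3'UTR >= 50 nt (boundaries inclusive: a transcript meeting all three
#' exactly is not spurious).
#'
#' @param models transcript model data.frame.
#' @return logical vector (TRUE = spurious).
#' @export
classify_spurious <- function(models) {
  models$utr5_len < 25L | models$cds_len < 200L | models$utr3_len < 50L
}

#' Detect downstream exon junctions (dEJ)
#'
#' A transcript carries a dEJ when any annotated or evidence-supported
#' exon-exon junction lies strictly more than `threshold` nt downstream of
#' the stop codon (a junction at exactly 50 nt does not trigger, matching
#' the lower bound of the canonical 50-55 nt rule).
#'
#' @param models transcript model data.frame.
#' @param evidence optional data.frame from
#'   [map_junctions_to_transcripts()] (`transcript_id`, `rel_pos`).
#' @param threshold nt downstream of the stop codon (default 50).
#' @return logical vector over transcripts (TRUE = has dEJ).
#' @export
detect_dej <- function(models, evidence = NULL, threshold = 50L) {
  ann <- vapply(models$stop_rel_junctions,
                function(r) any(r > threshold), logical(1))
  if (is.null(evidence) || nrow(evidence) == 0L) return(ann)
  ev_hit <- evidence$transcript_id[evidence$rel_pos > threshold]
  ann | models$transcript_id %in% ev_hit
}

#' Detect cryptic splicing signals in a 3'UTR
#'
#' TRUE when the sequence contains a GU dinucleotide followed by an AG
#' dinucleotide with strictly more than `min_inner` nt strictly between
#' them (the putative intron's inner distance).
#'
#' @param seqs character vector of 3'UTR sequences.
#' @param min_inner minimum inner distance in nt (default 60; > 60
#'   triggers, consistent with a minimum intron length of 61).
#' @return logical vector.
#' @export
detect_cryptic_intron <- function(seqs, min_inner = 60L) {
  vapply(seqs, function(s) {
    gu <- fixed_matches0("GU", s)
    if (length(gu) == 0L) return(FALSE)
    ag <- fixed_matches0("AG", s)
    if (length(ag) == 0L) return(FALSE)
    ## earliest donor and latest acceptor maximize the inner distance
    max(ag) - (min(gu) + 2L) > min_inner
  }, logical(1), USE.NAMES = FALSE)
}

#' Detect putative siRNA off-targets
#'
#' A 3'UTR is a putative off-target when it contains at least one 8mer,
#' 7m8 or 7A1 site of any siRNA guide (site strings computed exactly as for
#' a miRNA, from guide positions 2-8).
#'
#' @param seqs character vector of 3'UTR sequences.
#' @param sirna_guides character vector of guide-strand sequences
#'   (>= 8 nt each); an empty set flags nothing.
#' @return logical vector.
#' @export
detect_sirna_offtarget <- function(seqs, sirna_guides) {
  if (length(sirna_guides) == 0L) return(rep(FALSE, length(seqs)))
  if (any(nchar(sirna_guides) < 8L)) {
    stop("siRNA guide shorter than 8 nt", call. = FALSE)
  }
  hit <- rep(FALSE, length(seqs))
  for (g in sirna_guides) {
    ss <- site_strings(substr(g, 2L, 8L))
    ## 8mer matches are a subset of 7m8 matches
    for (pat in unique(ss[c("7m8", "7A1")])) {
      hit <- hit | grepl(pat, seqs, fixed = TRUE)
    }
  }
  hit
}

#' Expression-level gene filter
#'
#' Keeps genes with at least `min_fpm` fragments per million in the
#' knockdown condition and non-zero FPKM in the control (avoiding
#' divide-by-zero fold changes). Genes missing either condition are
#' excluded with a warning.
#'
#' @param genes gene ids to screen.
#' @param expr expression table (long form).
#' @param kd_condition,ctrl_condition condition labels.
#' @param min_fpm FPM threshold (default 3; exactly 3 is kept).
#' @return character vector of kept gene ids.
#' @export
filter_expression <- function(genes, expr, kd_condition, ctrl_condition,
                              min_fpm = 3) {
  kd <- expr[expr$condition == kd_condition, , drop = FALSE]
  ctrl <- expr[expr$condition == ctrl_condition, , drop = FALSE]
  fpm_kd <- kd$fpm[match(genes, kd$gene_id)]
  fpkm_ctrl <- ctrl$fpkm[match(genes, ctrl$gene_id)]
  missing <- is.na(fpm_kd) | is.na(fpkm_ctrl)
  if (any(missing)) {
    warning(sum(missing), " gene(s) missing a condition; excluded",
            call. = FALSE)
  }
  keep <- !missing & fpm_kd >= min_fpm & fpkm_ctrl > 0
  genes[keep]
}

.report_step <- function(report, step, universe, excluded_ids) {
  rbind(report, data.frame(
    step = step,
    n_in = length(universe),
    n_excluded = length(excluded_ids),
    n_out = length(universe) - length(excluded_ids),
    excluded = I(list(sort(excluded_ids))),
    stringsAsFactors = FALSE))
}

#' Run the dEJ-free gene filtering cascade
#'
#' Applies, in order: (1) spurious structure (a gene survives if at least
#' one transcript is non-spurious), (2) annotated NMD flags (a gene is
#' removed if any transcript is flagged; the flag list also carries
#' classifier-derived NMD calls supplied as input), (3) dEJ or cryptic
#' splice signal in any transcript / the representative 3'UTR, (4)
#' expression level, (5) siRNA off-target sites. Returns the surviving
#' gene set and a per-step report whose accounting satisfies
#' `n_out = n_in - n_excluded` with chained steps.
#'
#' @param models transcript model data.frame.
#' @param seqs named character vector of representative 3'UTR sequences
#'   keyed by gene id.
#' @param junctions evidence junction data.frame from
#'   [map_junctions_to_transcripts()], or NULL.
#' @param nmd_flags character vector of annotated-NMD gene ids.
#' @param sirnas character vector of siRNA guide sequences.
#' @param expr expression table.
#' @param kd_condition,ctrl_condition condition labels for the expression
#'   step.
#' @param dej_threshold nt threshold for the dEJ rule (default 50).
#' @param min_inner cryptic-intron inner distance threshold (default 60).
#' @param min_fpm expression threshold (default 3).
#' @return list with `genes` (kept), `report` (data.frame) and
#'   `excluded` (named list of per-step gene id vectors).
#' @export
run_dej_pipeline <- function(models, seqs, junctions = NULL,
                             nmd_flags = character(0),
                             sirnas = character(0),
                             expr, kd_condition, ctrl_condition,
                             dej_threshold = 50L, min_inner = 60L,
                             min_fpm = 3) {
  universe <- unique(models$gene_id)
  orphans <- setdiff(universe, names(seqs))
  if (length(orphans) > 0L) {
    stop("gene(s) without 3'UTR sequence: ",
         paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
  }
  orphans <- setdiff(universe, unique(expr$gene_id))
  if (length(orphans) > 0L) {
    stop("gene(s) without expression rows: ",
         paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
  }
  report <- NULL
  excluded <- list()

  ## 1. spurious: gene survives if any transcript is non-spurious
  spur_t <- classify_spurious(models)
  gene_ok <- tapply(!spur_t, models$gene_id, any)
  ex <- universe[!gene_ok[universe]]
  report <- .report_step(report, "spurious", universe, ex)
  excluded$spurious <- ex
  kept <- setdiff(universe, ex)

  ## 2. annotated NMD target genes (input flag list)
  ex <- intersect(kept, nmd_flags)
  report <- .report_step(report, "annotated_nmd", kept, ex)
  excluded$annotated_nmd <- ex
  kept <- setdiff(kept, ex)

  ## 3. dEJ (annotated or evidence-supported) or cryptic splice signal
  dej_t <- detect_dej(models, junctions, threshold = dej_threshold)
  dej_gene <- unique(models$gene_id[dej_t])
  cryptic_gene <- names(seqs)[detect_cryptic_intron(seqs,
                                                    min_inner = min_inner)]
  ex <- intersect(kept, union(dej_gene, cryptic_gene))
  report <- .report_step(report, "dej_or_cryptic", kept, ex)
  excluded$dej_or_cryptic <- ex
  kept <- setdiff(kept, ex)

  ## 4. expression filter
  keep_expr <- filter_expression(kept, expr, kd_condition, ctrl_condition,
                                 min_fpm = min_fpm)
  ex <- setdiff(kept, keep_expr)
  report <- .report_step(report, "expression", kept, ex)
  excluded$expression <- ex
  kept <- keep_expr

  ## 5. siRNA off-targets
  off <- detect_sirna_offtarget(seqs[kept], sirnas)
  ex <- kept[off]
  report <- .report_step(report, "sirna_offtarget", kept, ex)
  excluded$sirna_offtarget <- ex
  kept <- setdiff(kept, ex)

  list(genes = kept, report = report, excluded = excluded)
}
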