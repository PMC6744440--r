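## ---------------------------------------------------------------------------
## formats_io: FASTA / GTF / BED / TSV input-output and run configuration.
##
## Coordinate conventions used throughout the package:
##   * internal coordinates are 0-based half-open;
##   * GTF input is 1-based inclusive (converted on read);
##   * BED input is 0-based half-open.
## ---------------------------------------------------------------------------

#' Read a FASTA file of RNA (or DNA) sequences
#'
#' Sequences are normalized to the uppercase RNA alphabet on read
#' (lowercase folded, T rewritten to U); `N` is tolerated. Record ids are
#' the header tokens up to the first whitespace and must be unique.
#'
#' @param path path to a FASTA file.
#' @return named character vector of normalized sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 1L && nzchar(first) && !startsWith(first, ">")) {
    stop("malformed FASTA (line 1 does not start with '>'): ", path,
         call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(stats::setNames(character(0), character(0)))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicated sequence id in ", path, ": ",
         ids[duplicated(ids)][1], call. = FALSE)
  }
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record '", ids[!nzchar(seqs)][1], "'",
         call. = FALSE)
  }
  stats::setNames(rna_normalize(seqs, ids), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' @noRd
read_tsv_file <- function(path, ...) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' @noRd
write_tsv_file <- function(x, path) {
  ## list-columns are collapsed to comma-separated strings for TSV output
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (j in seq_along(x)) {
    if (is.list(x[[j]])) {
      x[[j]] <- vapply(x[[j]], function(v) paste(v, collapse = ","),
                       character(1))
    }
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## exonic bases strictly before genomic boundary b (plus strand reading)
.tc_plus <- function(b, starts, ends) {
  sum(pmax(0L, pmin(ends, b) - starts))
}

## exonic bases at or after genomic boundary b (minus strand reading)
.tc_minus <- function(b, starts, ends) {
  sum(pmax(0L, ends - pmax(starts, b)))
}

.model_row <- function(transcript_id, gene_id, chrom, strand,
                       starts, ends, cds_lo, cds_hi) {
  ord <- order(starts)
  starts <- as.integer(starts[ord]); ends <- as.integer(ends[ord])
  if (any(starts[-1] < ends[-length(ends)])) {
    stop("overlapping exons in transcript ", transcript_id, call. = FALSE)
  }
  widths <- ends - starts
  spliced <- sum(widths)
  in_exon <- function(p) any(starts <= p & p <= ends)
  if (!in_exon(cds_lo) || !in_exon(cds_hi)) {
    stop("CDS outside exons in transcript ", transcript_id, call. = FALSE)
  }
  if (strand == "+") {
    utr5 <- .tc_plus(cds_lo, starts, ends)
    cds_end_tc <- .tc_plus(cds_hi, starts, ends)
    junc_tc <- cumsum(widths)[-length(widths)]
  } else {
    utr5 <- .tc_minus(cds_hi, starts, ends)
    cds_end_tc <- .tc_minus(cds_lo, starts, ends)
    junc_tc <- cumsum(rev(widths))[-length(widths)]
  }
  cds_len <- cds_end_tc - utr5
  utr3 <- spliced - cds_end_tc
  if (cds_len <= 0L) {
    stop("inconsistent CDS/exon structure in transcript ", transcript_id,
         call. = FALSE)
  }
  rel <- junc_tc - cds_end_tc
  data.frame(
    transcript_id = transcript_id, gene_id = gene_id,
    chrom = chrom, strand = strand,
    exon_starts = I(list(starts)), exon_ends = I(list(ends)),
    cds_start = as.integer(cds_lo), cds_end = as.integer(cds_hi),
    utr5_len = as.integer(utr5), cds_len = as.integer(cds_len),
    utr3_len = as.integer(utr3), spliced_len = as.integer(spliced),
    stop_rel_junctions = I(list(as.integer(rel[rel >= 0L]))),
    nmd_annotated = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Read transcript models from a GTF file
#'
#' Builds one record per transcript from `exon` and `CDS` features, with
#' strand-aware 5'UTR/CDS/3'UTR lengths and the transcript-coordinate
#' positions of exon-exon junctions downstream of the stop codon
#' (`stop_rel_junctions`, in nt; a junction at the stop codon is 0). The CDS
#' feature is taken to end at the stop codon. Transcripts lacking a CDS are
#' excluded with a warning; exon/CDS inconsistencies are errors naming the
#' transcript.
#'
#' @param gtf path to a GTF file (1-based inclusive coordinates).
#' @return data.frame of transcript models (one row per transcript) with
#'   list-columns `exon_starts`/`exon_ends` (0-based half-open) and
#'   `stop_rel_junctions`.
#' @export
read_transcript_models <- function(gtf) {
  gr <- rtracklayer::import(gtf, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  tid <- as.character(meta$transcript_id)
  gid <- as.character(meta$gene_id)
  keep <- type %in% c("exon", "CDS")
  gr <- gr[keep]; type <- type[keep]; tid <- tid[keep]; gid <- gid[keep]
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))

  out <- list()
  for (t in unique(tid)) {
    i <- which(tid == t)
    ie <- i[type[i] == "exon"]
    ic <- i[type[i] == "CDS"]
    if (length(ie) == 0L) {
      stop("transcript ", t, " has no exon features", call. = FALSE)
    }
    if (length(ic) == 0L) {
      warning("transcript ", t, " has no CDS; excluded", call. = FALSE)
      next
    }
    out[[t]] <- .model_row(
      transcript_id = t, gene_id = gid[ie][1],
      chrom = chrom[ie][1], strand = strand[ie][1],
      starts = start0[ie], ends = end0[ie],
      cds_lo = min(start0[ic]), cds_hi = max(end0[ic])
    )
  }
  if (length(out) == 0L) {
    stop("no transcripts with CDS found in ", gtf, call. = FALSE)
  }
  do.call(rbind, unname(out))
}

#' Select the representative transcript per gene
#'
#' One transcript represents each gene in all 3'UTR analyses: the transcript
#' with the longest 3'UTR, ties broken by the lexicographically smallest
#' transcript id.
#'
#' @param models transcript model data.frame.
#' @return data.frame with one row per gene.
#' @export
representative_transcripts <- function(models) {
  ord <- order(models$gene_id, -models$utr3_len, models$transcript_id)
  m <- models[ord, , drop = FALSE]
  m[!duplicated(m$gene_id), , drop = FALSE]
}

.as_bed_df <- function(bed) {
  if (is.character(bed)) bed <- rtracklayer::import(bed, format = "bed")
  if (inherits(bed, "GRanges")) {
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(bed)),
      start = GenomicRanges::start(bed) - 1L,
      end = GenomicRanges::end(bed),
      name = if (!is.null(bed$name)) as.character(bed$name) else NA_character_,
      strand = as.character(GenomicRanges::strand(bed)),
      stringsAsFactors = FALSE
    )
    return(df)
  }
  as.data.frame(bed, stringsAsFactors = FALSE)
}

#' Update 3'UTR ends with major poly(A) positions
#'
#' Emulates updating annotated 3'UTR ends with the major 3' end profiled by
#' 3P-seq. Each BED record names a gene (`name` column) and its `start`
#' column gives the 0-based genomic position of the new terminal 3'UTR base.
#' The matched transcript's 3'UTR is truncated or extended to the stop-to-end
#' distance (extensions beyond the terminal exon are measured along the
#' genome). When a gene has several records the one nearest the current 3'UTR
#' length is used; ends at or upstream of the stop codon are skipped with a
#' warning; unmatched transcripts are unchanged.
#'
#' @param models transcript model data.frame.
#' @param ends BED path, GRanges, or data.frame with columns
#'   chrom/start/end/name/strand.
#' @return updated models (utr3_len and spliced_len recomputed).
#' @export
update_utr3_ends <- function(models, ends) {
  bed <- .as_bed_df(ends)
  for (i in seq_len(nrow(models))) {
    hit <- which(bed$name == models$gene_id[i] &
                   bed$chrom == models$chrom[i] &
                   (bed$strand == models$strand[i] | bed$strand == "*"))
    if (length(hit) == 0L) next
    starts <- models$exon_starts[[i]]; ends_i <- models$exon_ends[[i]]
    cds_end_tc <- models$utr5_len[i] + models$cds_len[i]
    new_lens <- vapply(hit, function(h) {
      pos <- bed$start[h]
      if (models$strand[i] == "+") {
        b <- pos + 1L
        inside <- .tc_plus(min(b, max(ends_i)), starts, ends_i) - cds_end_tc
        ext <- max(0L, b - max(ends_i))
      } else {
        b <- pos
        inside <- .tc_minus(max(b, min(starts)), starts, ends_i) - cds_end_tc
        ext <- max(0L, min(starts) - b)
      }
      as.integer(inside + ext)
    }, integer(1))
    valid <- new_lens > 0L
    if (!any(valid)) {
      warning("3'UTR end for gene ", models$gene_id[i],
              " lies upstream of the stop codon; skipped", call. = FALSE)
      next
    }
    new_lens <- new_lens[valid]
    best <- new_lens[which.min(abs(new_lens - models$utr3_len[i]))]
    models$utr3_len[i] <- best
    models$spliced_len[i] <- models$utr5_len[i] + models$cds_len[i] + best
  }
  models
}

#' Truncate 3'UTR sequences to model lengths
#'
#' After [update_utr3_ends()], trims sequences longer than the recorded
#' 3'UTR length; sequences shorter than the model length (extensions past
#' the annotated exon, for which no sequence is available) are left as is
#' with a warning.
#'
#' @param seqs named character vector of 3'UTR sequences keyed by gene id.
#' @param models representative transcript models.
#' @return truncated sequences.
#' @export
truncate_utr_sequences <- function(seqs, models) {
  idx <- match(names(seqs), models$gene_id)
  for (k in which(!is.na(idx))) {
    len <- models$utr3_len[idx[k]]
    if (nchar(seqs[k]) > len) {
      seqs[k] <- substr(seqs[k], 1L, len)
    } else if (nchar(seqs[k]) < len) {
      warning("3'UTR sequence for ", names(seqs)[k],
              " is shorter than the model length; left unchanged",
              call. = FALSE)
    }
  }
  seqs
}

#' Map evidence junctions into stop-relative transcript coordinates
#'
#' Converts RNA-seq-supported exon-exon junctions (BED intervals spanning
#' the intron) to distances downstream of each transcript's stop codon.
#' Junctions outside a transcript's genomic span are ignored with a warning.
#'
#' @param models transcript model data.frame.
#' @param junctions BED path, GRanges, or data.frame (0-based half-open
#'   intron intervals with strand).
#' @return data.frame with columns `transcript_id`, `rel_pos` (nt downstream
#'   of the stop codon; may be negative for junctions upstream of the stop).
#' @export
map_junctions_to_transcripts <- function(models, junctions) {
  bed <- .as_bed_df(junctions)
  span_lo <- vapply(models$exon_starts, min, integer(1))
  span_hi <- vapply(models$exon_ends, max, integer(1))
  cds_end_tc <- models$utr5_len + models$cds_len
  tid <- character(0); rel <- integer(0)
  matched <- rep(FALSE, nrow(bed))
  for (key in unique(paste(models$chrom, models$strand))) {
    ks <- strsplit(key, " ", fixed = TRUE)[[1]]
    mi <- which(models$chrom == ks[1] & models$strand == ks[2])
    bi <- which(bed$chrom == ks[1] & (bed$strand == ks[2] |
                                        bed$strand == "*"))
    if (length(mi) == 0L || length(bi) == 0L) next
    o <- mi[order(span_lo[mi])]
    lo <- span_lo[o]; hi_run <- cummax(span_hi[o])
    donor <- if (ks[2] == "+") bed$start[bi] else bed$end[bi]
    for (j in seq_along(bi)) {
      p <- findInterval(donor[j], lo)
      while (p >= 1L && hi_run[p] >= donor[j]) {
        i <- o[p]
        if (span_hi[i] >= donor[j]) {
          matched[bi[j]] <- TRUE
          tc <- if (ks[2] == "+") {
            .tc_plus(donor[j], models$exon_starts[[i]],
                     models$exon_ends[[i]])
          } else {
            .tc_minus(donor[j], models$exon_starts[[i]],
                      models$exon_ends[[i]])
          }
          tid <- c(tid, models$transcript_id[i])
          rel <- c(rel, as.integer(tc - cds_end_tc[i]))
        }
        p <- p - 1L
      }
    }
  }
  if (any(!matched)) {
    warning(sum(!matched),
            " junction record(s) outside all transcript spans ignored",
            call. = FALSE)
  }
  data.frame(transcript_id = tid, rel_pos = rel, stringsAsFactors = FALSE)
}

#' Read a gene-level expression table
#'
#' Expects a TSV with header columns `gene_id`, `condition`, `fpkm`, `fpm`
#' (one row per gene and condition).
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_expression_table <- function(path) {
  x <- read_tsv_file(path)
  need <- c("gene_id", "condition", "fpkm", "fpm")
  if (!all(need %in% names(x))) {
    stop("expression table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(x[c("gene_id", "condition")])) {
    stop("duplicated (gene_id, condition) rows in expression table",
         call. = FALSE)
  }
  if (any(!is.finite(x$fpkm)) || any(!is.finite(x$fpm)) ||
      any(x$fpkm < 0) || any(x$fpm < 0)) {
    stop("fpkm/fpm must be finite and non-negative", call. = FALSE)
  }
  x
}

#' Analysis run configuration
#'
#' Central tunable parameters with the study defaults: four equal-count
#' 3'UTR-length bins, derepression called at |log2FC| > 0.2, 7-mer
#' enrichment at nominal P < 0.005, CUG flank window of 5 nt, CUG/site
#' co-occurrence window of 15 nt, 1000 shuffled-miRNA cohorts of 50 miRNAs,
#' 100 shuffle cohorts for seed-region CAG statistics, and the 50 most
#' abundant miRNA families.
#'
#' @param n_bins number of equal-count 3'UTR-length bins.
#' @param derepression_threshold log2 fold-change calling threshold (> 0).
#' @param enrichment_alpha nominal significance level for 7-mer enrichment.
#' @param flank_window nt of flank on each side of a site for CUG counting.
#' @param cug_window nt window for CUG/site co-occurrence classes.
#' @param n_cohorts number of shuffled-miRNA cohorts for the expression null.
#' @param cohort_size miRNAs per cohort.
#' @param n_shuffle_cohorts_seed shuffle cohorts for seed-region CAG counts.
#' @param rng_seed integer seed.
#' @param top_n_families number of most-abundant miRNA families analyzed.
#' @return validated list of class `umd_run_config`.
#' @export
run_config <- function(n_bins = 4L,
                       derepression_threshold = 0.2,
                       enrichment_alpha = 0.005,
                       flank_window = 5L,
                       cug_window = 15L,
                       n_cohorts = 1000L,
                       cohort_size = 50L,
                       n_shuffle_cohorts_seed = 100L,
                       rng_seed = 1L,
                       top_n_families = 50L) {
  cfg <- list(n_bins = as.integer(n_bins),
              derepression_threshold = derepression_threshold,
              enrichment_alpha = enrichment_alpha,
              flank_window = as.integer(flank_window),
              cug_window = as.integer(cug_window),
              n_cohorts = as.integer(n_cohorts),
              cohort_size = as.integer(cohort_size),
              n_shuffle_cohorts_seed = as.integer(n_shuffle_cohorts_seed),
              rng_seed = as.integer(rng_seed),
              top_n_families = as.integer(top_n_families))
  counts <- c("n_bins", "flank_window", "cug_window", "n_cohorts",
              "cohort_size", "n_shuffle_cohorts_seed", "top_n_families")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      stop("run_config: ", f, " must be >= 1", call. = FALSE)
    }
  }
  if (cfg$derepression_threshold <= 0 || cfg$enrichment_alpha <= 0) {
    stop("run_config: thresholds must be > 0", call. = FALSE)
  }
  class(cfg) <- "umd_run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Fields present in the YAML override the [run_config()] defaults.
#'
#' @param path YAML file path.
#' @return `umd_run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, raw)
}
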