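#' Normalize sequences to the uppercase RNA alphabet
#'
#' All sequence handling in this package is done in the RNA alphabet
#' (A, C, G, U): the motifs under study (CUG, CAG, CCUG\[AG\]\[AG\]\[AG\]) are
#' RNA motifs, so DNA input is converted on read. Lowercase letters are
#' uppercased and T is rewritten to U. `N` is tolerated (ambiguity); any
#' other character is an error naming the offending record.
#'
#' @param x character vector of sequences.
#' @param ids optional character vector of record ids used in error messages.
#' @return character vector over \{A, C, G, U, N\}.
#' @export
rna_normalize <- function(x, ids = names(x)) {
  out <- chartr("acgtun", "ACGUUN", toupper(x))
  out <- chartr("T", "U", out)
  bad <- grepl("[^ACGUN]", out)
  if (any(bad)) {
    lab <- if (!is.null(ids)) ids[bad][1] else which(bad)[1]
    stop("illegal character in sequence record '", lab,
         "' (only A, C, G, T, U, N are accepted)", call. = FALSE)
  }
  out
}

#' Reverse-complement RNA sequences
#'
#' @param x character vector in the RNA alphabet.
#' @return character vector of reverse complements (N maps to N).
#' @export
rna_revcomp <- function(x) {
  comp <- chartr("ACGUN", "UGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

## fraction of G/C among the first `k` characters of each k-mer
gc_fraction <- function(kmers) {
  n <- nchar(kmers)
  (n - nchar(gsub("[GC]", "", kmers))) / n
}

## 0-based start positions of fixed-string matches of `pattern` in one string
fixed_matches0 <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

umd_verbose <- function() isTRUE(getOption("umdecay.verbose", FALSE))

umd_log <- function(...) {
  if (umd_verbose()) message("[umdecay] ", ...)
  invisible(NULL)
}
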