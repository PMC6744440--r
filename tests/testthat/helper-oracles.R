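## Independent oracles used across the suite. These deliberately avoid the
## package's implementation paths: the site oracle matches full site-type
## strings with regexes and collapses types post hoc; the Fisher oracle
## sums hypergeometric point masses directly.

## brute-force seed-site scanner: regex over the five full site strings,
## post-hoc maximal-type collapse within each family
oracle_scan_sites <- function(utrs, families,
                              types = c("8mer", "7m8", "7A1")) {
  all_rows <- list()
  for (f in seq_len(nrow(families))) {
    ss <- c("8mer" = families$s8mer[f], "7m8" = families$s7m8[f],
            "7A1" = families$s7A1[f], "6mer" = families$s6mer[f],
            "offset6mer" = families$soffset6mer[f])
    for (g in seq_along(utrs)) {
      u <- utrs[[g]]
      pos <- lapply(ss, function(p) {
        m <- gregexpr(p, u, fixed = TRUE)[[1]]
        if (m[1] == -1L) integer(0) else as.integer(m) - 1L
      })
      rows <- list()
      for (s in pos[["8mer"]]) {
        rows[[length(rows) + 1L]] <- c("8mer", s, s + 8L)
      }
      for (s in setdiff(pos[["7m8"]], pos[["8mer"]])) {
        rows[[length(rows) + 1L]] <- c("7m8", s, s + 7L)
      }
      for (s in setdiff(pos[["7A1"]], pos[["8mer"]] + 1L)) {
        rows[[length(rows) + 1L]] <- c("7A1", s, s + 7L)
      }
      for (s in pos[["6mer"]]) {
        if ((s - 1L) %in% pos[["7m8"]]) next   # part of a 7m8/8mer locus
        if (s %in% pos[["7A1"]]) next          # part of a 7A1 locus
        rows[[length(rows) + 1L]] <- c("6mer", s, s + 6L)
      }
      for (s in pos[["offset6mer"]]) {
        if (s %in% pos[["7m8"]]) next          # extendable to 7m8
        rows[[length(rows) + 1L]] <- c("offset6mer", s, s + 6L)
      }
      if (length(rows) == 0L) next
      df <- data.frame(gene_id = names(utrs)[g],
                       family_id = families$family_id[f],
                       site_type = vapply(rows, `[`, character(1), 1),
                       start = as.integer(vapply(rows, `[`, character(1), 2)),
                       end = as.integer(vapply(rows, `[`, character(1), 3)),
                       stringsAsFactors = FALSE)
      pr <- match(df$site_type,
                  c("8mer", "7m8", "7A1", "6mer", "offset6mer"))
      df <- df[order(df$start, pr), , drop = FALSE]
      df <- df[!duplicated(df[c("start", "end")]), , drop = FALSE]
      all_rows[[length(all_rows) + 1L]] <- df
    }
  }
  out <- if (length(all_rows) > 0L) do.call(rbind, all_rows) else
    data.frame(gene_id = character(0), family_id = character(0),
               site_type = character(0), start = integer(0),
               end = integer(0), stringsAsFactors = FALSE)
  out <- out[out$site_type %in% types, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## one-sided Fisher enrichment p by direct summation of the
## hypergeometric point masses of the upper tail
oracle_fisher_p <- function(a, b, c, d) {
  n1 <- a + b; k <- a + c; n <- a + b + c + d
  xs <- a:min(n1, k)
  sum(stats::dhyper(xs, k, n - k, n1))
}

## sorted dinucleotide multiset of a sequence
dinuc_multiset <- function(s) {
  n <- nchar(s)
  if (n < 2L) return(character(0))
  sort(substring(s, 1:(n - 1L), 2:n))
}

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}

## canonical site ordering for data.frame comparison
sort_sites <- function(df) {
  df <- df[order(df$gene_id, df$family_id, df$start, df$site_type), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}
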