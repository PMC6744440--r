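#!/usr/bin/env Rscript
## Stage 4: 7-mer enrichment in derepressed target 3'UTRs.
##
## Targets are dEJ-free genes derepressed beyond log2FC 0.2 under siUPF1
## that carry at least one effective site. Every possible 7-mer is
## compared between the target UTRs and one dinucleotide-preserving
## shuffle of each UTR (number-matched background) with a one-sided
## Fisher exact test at nominal P < 0.005, then annotated as miRNA
## recognition elements (7m8/7A1 strings) or extended CUG motifs
## (CCUG[AG][AG][AG]).

library(umdecay)

seed <- as.integer(Sys.getenv("UMD_SEED", "1"))
set.seed(stage_seed(seed, "enrich"))

dat <- "results/data"
utr3 <- read_fasta(file.path(dat, "utr3.fa"))
mirnas <- read_fasta(file.path(dat, "mirnas.fa"))
ab <- read.delim(file.path(dat, "mirna_abundance.tsv"))
expr <- read_expression_table(file.path(dat, "expression.tsv"))
kept <- read.delim("results/dej_free_genes.tsv")$gene_id
sites <- read.delim("results/sites.tsv")

fams_all <- build_families(mirnas, ab)
fams <- top_families(fams_all, 50)
rec <- compute_log2fc(expr, "siUPF1", "control", genes = kept)
eff <- effective_site_counts(sites, kept)
targets <- rec$gene_id[rec$log2fc > 0.2 & eff[rec$gene_id] > 0]
cat(length(targets), "derepressed target genes enter the enrichment.\n")

rows <- enrich_7mers(utr3[targets], alpha = 0.005)
ann <- annotate_mres(rows, fams_all, fams)
rows <- ann$rows[order(ann$rows$p_value), ]

cat(sum(rows$significant), "of", nrow(rows),
    "7-mers significantly enriched (nominal P < 0.005).\n")
cat(sprintf("MRE fraction among significant 7-mers: %.1f%% (chance %.1f%%; one-sided Fisher P = %.3g)\n",
            100 * ann$summary$frac_mre_significant,
            100 * ann$summary$frac_mre_chance, ann$summary$p_value))
cat("Extended CUG motifs among significant 7-mers:",
    sum(rows$significant & rows$is_ccug_pattern), "of 8\n")
cat("Top enriched 7-mers:\n")
print(head(rows[c("kmer", "obs_count", "bg_count", "p_value",
                  "is_mre", "is_ccug_pattern")], 10), row.names = FALSE)

write.table(rows, "results/enrichment_7mers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
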