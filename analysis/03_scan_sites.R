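#!/usr/bin/env Rscript
## Stage 3: annotate miRNA seed-match sites in the dEJ-free 3'UTRs.
##
## Builds seed families from the mature miRNA sequences and abundances
## (positions 2-8 define a family), keeps the 50 most abundant, and scans
## every retained 3'UTR for 8mer / 7mer-m8 / 7mer-A1 / 6mer / offset-6mer
## sites, recording each site's relation to CUG motifs (embedded in the
## site, within the 5-nt flank, or absent).

library(umdecay)

dat <- "results/data"
utr3 <- read_fasta(file.path(dat, "utr3.fa"))
mirnas <- read_fasta(file.path(dat, "mirnas.fa"))
ab <- read.delim(file.path(dat, "mirna_abundance.tsv"))
kept <- read.delim("results/dej_free_genes.tsv")$gene_id

fams <- top_families(build_families(mirnas, ab), 50)
sites <- scan_sites(utr3[kept], fams, types = SITE_TYPES)

cat("Scanned", length(kept), "3'UTRs for", nrow(fams), "families.\n")
print(table(sites$site_type))
eff <- effective_site_counts(sites, kept)
cat("Genes with >= 1 effective 7-mer site:", sum(eff > 0),
    "of", length(kept), "\n")
cat("CUG relation of effective sites:\n")
print(table(sites$cug_relation[sites$site_type %in% EFFECTIVE_TYPES]))

write.table(sites, "results/sites.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
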