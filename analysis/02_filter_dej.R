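#!/usr/bin/env Rscript
## Stage 2: select dEJ-free genes.
##
## Reads the stage-1 files back through the standard-format readers and
## applies the filtering cascade: spurious structure (5'UTR >= 25 nt,
## CDS >= 200 nt, 3'UTR >= 50 nt), annotated NMD flags, downstream exon
## junctions (> 50 nt past the stop codon, annotated or junction-BED
## supported) or cryptic GU..AG signals (inner distance > 60 nt),
## expression (>= 3 FPM in knockdown, non-zero control FPKM), and siRNA
## off-target 7-mer sites.

library(umdecay)

dat <- "results/data"
models <- read_transcript_models(file.path(dat, "annotation.gtf"))
utr3 <- read_fasta(file.path(dat, "utr3.fa"))
expr <- read_expression_table(file.path(dat, "expression.tsv"))
nmd <- read.delim(file.path(dat, "nmd_flags.tsv"))$gene_id
sir <- read.delim(file.path(dat, "sirnas.txt"), header = FALSE)
sirnas <- stats::setNames(sir$V2, sir$V1)
junc <- read.delim(file.path(dat, "junctions.bed"), header = FALSE,
                   col.names = c("chrom", "start", "end", "name",
                                 "score", "strand"))

evidence <- map_junctions_to_transcripts(models, junc)
filt <- run_dej_pipeline(models, utr3, evidence, nmd, sirnas, expr,
                         kd_condition = "siUPF1",
                         ctrl_condition = "control")

cat("Filtering cascade:\n")
print(filt$report[c("step", "n_in", "n_excluded", "n_out")])
cat(length(filt$genes), "dEJ-free genes retained.\n")

dir.create("results", showWarnings = FALSE)
write.table(data.frame(gene_id = filt$genes), "results/dej_free_genes.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(filt$report[c("step", "n_in", "n_excluded", "n_out")],
            "results/filter_report.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
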