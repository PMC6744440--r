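#!/usr/bin/env Rscript
## Stage 1: generate the synthetic study dataset.
##
## Emulates the statistical structure of a UPF1/Dicer1/SMG7 knockdown
## study: 3000 genes with log-uniform 3'UTR lengths (50 nt - 10 kb),
## planted filter categories (spurious structure, annotated NMD, dEJ,
## cryptic splice signal, siRNA off-target; 10% each), 50 miRNA seed
## families (12 with CAG embedded in the seed), one planted effective
## site per kb of 3'UTR, and five-condition expression with a 0.08
## log2FC-per-site UPF1 effect attenuated to 40% under siSMG7.

library(umdecay)

seed <- as.integer(Sys.getenv("UMD_SEED", "1"))
out <- "results/data"

syn <- synthetic_config(n_genes = 3000, rng_seed = stage_seed(seed, "simulate"))
ds <- generate_umd_dataset(syn)
paths <- write_umd_dataset(ds, out)

gt <- ds$ground_truth
cat("Simulated", nrow(gt), "genes on", length(unique(ds$models$chrom)),
    "synthetic chromosome(s).\n")
cat("Planted categories:\n")
print(table(gt$category))
cat("Planted effective sites:", sum(gt$n_sites),
    "(", round(mean(gt$n_sites / gt$utr3_len * 1000), 2), "per kb )\n")
cat("Files written under", out, "\n")
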