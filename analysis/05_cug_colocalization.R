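#!/usr/bin/env Rscript
## Stage 5: CUG/CAG motif statistics.
##
## Three views of the CUG-MRE relationship: (i) CUG counts in the 5-nt
## flanks of up to 1000 sampled effective sites versus a thousand random
## 7-mer positions in the same UTRs (one-sided Fisher on exposure);
## (ii) 3-mer signal-to-noise ratios (observed / dinucleotide-shuffle
## expectation) of target 3'UTRs correlated with those of
## reverse-complemented miRNAs; (iii) the fraction of the 50 most
## abundant families with CAG embedded in the seed versus 100
## dinucleotide-shuffled cohorts.

library(umdecay)

seed <- as.integer(Sys.getenv("UMD_SEED", "1"))
set.seed(stage_seed(seed, "cug"))

dat <- "results/data"
utr3 <- read_fasta(file.path(dat, "utr3.fa"))
mirnas <- read_fasta(file.path(dat, "mirnas.fa"))
ab <- read.delim(file.path(dat, "mirna_abundance.tsv"))
kept <- read.delim("results/dej_free_genes.tsv")$gene_id
sites <- read.delim("results/sites.tsv")

fams <- top_families(build_families(mirnas, ab), 50)
eff_sites <- sites[sites$site_type %in% EFFECTIVE_TYPES, ]
utrs <- utr3[kept]

flank <- count_cug_in_flanks(utrs, eff_sites, window = 5L, n_sample = 1000L)
ctrl <- random_flank_control(utrs, flank$n_sites, window = 5L)
p_flank <- flank_enrichment_test(flank$total, flank$exposure,
                                 ctrl$total, ctrl$exposure)
cat(sprintf("CUG in site flanks: %d over %d sites; random positions: %d (one-sided Fisher P = %.3g)\n",
            flank$total, flank$n_sites, ctrl$total, p_flank))

eff <- effective_site_counts(sites, kept)
target_utrs <- utrs[eff[kept] > 0]
snr_utr <- snr_3mers(target_utrs)
snr_mir <- snr_3mers(revcomp_set(mirnas))
cor_res <- correlate_snr(snr_mir, snr_utr)
cat(sprintf("3-mer SNR correlation (revcomp miRNAs vs target UTRs): r = %.2f (P = %.3g)\n",
            cor_res$r, cor_res$p))

cag <- cag_seed_enrichment(fams, mirnas, n_cohorts = 100)
cat(sprintf("CAG embedded in seed: %d of %d families (%.0f%%) vs %.1f%% in shuffled cohorts (P = %.3g)\n",
            cag$observed_count, nrow(fams), 100 * cag$observed_prop,
            100 * cag$cohort_mean_prop, cag$p_value))

out <- data.frame(
  statistic = c("flank_cug_count", "flank_cug_sites", "flank_cug_control",
                "flank_p", "snr_r", "snr_p", "cag_seed_count",
                "cag_seed_prop", "cag_shuffle_prop", "cag_p"),
  value = c(flank$total, flank$n_sites, ctrl$total, p_flank, cor_res$r,
            cor_res$p, cag$observed_count, cag$observed_prop,
            cag$cohort_mean_prop, cag$p_value))
write.table(out, "results/cug_statistics.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
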