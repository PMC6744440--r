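# umdecay

Tools for dissecting **UPF1/SMG7-dependent, microRNA-mediated mRNA decay
(UMD)** — the 3'UTR-length-dependent destabilization of mRNAs that
remains after every gene that could respond through classical,
exon-junction-complex-dependent nonsense-mediated decay (NMD) has been
filtered away.

The package is aimed at transcriptomics analysts working with knockdown
RNA-seq (UPF1, Dicer1, SMG7) who need to separate EJC-independent,
3'UTR-driven decay from classical NMD and to attribute it to miRNA
targeting. It implements, as tested R functions:

* the **dEJ-free filtering cascade**: remove genes with spurious
  structure (5'UTR < 25 nt, CDS < 200 nt, 3'UTR < 50 nt), annotated NMD
  transcripts, a *downstream exon junction* (dEJ: an exon–exon junction
  > 50 nt past the stop codon, annotated or junction-evidence-supported),
  a cryptic GU…AG splice signal with inner distance > 60 nt, low
  expression (< 3 FPM in knockdown, or zero control FPKM), or siRNA
  off-target 7-mer sites — with per-step exclusion accounting;
* **miRNA seed-site annotation** over seed families (positions 2–8):
  8mer, 7mer-m8, 7mer-A1, 6mer and offset-6mer site strings, maximal-type
  resolution per locus, effective-site counts, and weighted context++
  score summation with overlap resolution;
* **dinucleotide-preserving shuffle** backgrounds (Euler-path
  construction preserving the dinucleotide multiset and both endpoints)
  and all-7-mer enrichment by one-sided Fisher exact tests at nominal
  *P* < 0.005, with MRE and CCUG[AG][AG][AG] annotation;
* **CUG/CAG motif statistics**: CUG counts in ±5-nt site flanks versus
  random-position controls, 3-mer signal-to-noise ratios and their
  correlation with reverse-complemented miRNAs, and CAG-in-seed
  enrichment against dinucleotide-shuffled miRNA cohorts;
* **expression analysis**: log2 fold changes binned into equal-count
  3'UTR-length bins, median-normalized to the shortest bin (50–349-nt
  class), one-sided Kolmogorov–Smirnov shift tests, shuffled-miRNA
  cohort nulls with one-sample t-tests, mean fold change by
  effective-site count and by score bin, and CUG/site co-occurrence
  classes;
* a **synthetic-data generator** producing annotation (GTF), 3'UTR
  sequences (FASTA), miRNAs/siRNAs, junction evidence (BED) and
  five-condition expression tables with *exact* planted ground truth, so
  every stage is testable end to end without external downloads.

The statistical model behind the expression analyses: for gene *g* with
*S(g)* effective 7-mer sites of the top miRNA families, of which
*S\_CUG(g)* embed a CUG motif, the expected derepression under UPF1
knockdown is

    E[log2FC(g)] = beta_site * S(g) + beta_cug * S_CUG(g)

with beta_site = 0.08, beta_cug = 0.04 by default, attenuated by
alpha_SMG7 = 0.4 under SMG7 knockdown, and zero in any Dicer1-depleted
background — the signature that distinguishes miRNA-mediated UMD from
miRNA-independent effects.

## Worked example

The `analysis/` directory holds the six-stage workflow as numbered
scripts (`Rscript analysis/01_simulate.R`, … , `06_expression_analysis.R`;
set `UMD_SEED` to change the seed). Stage 2 prints the filtering
cascade on the default synthetic study:

```
             step n_in n_excluded n_out
1        spurious 3000        300  2700
2   annotated_nmd 2700        300  2400
3  dej_or_cryptic 2400        600  1800
4      expression 1800         60  1740
5 sirna_offtarget 1740        300  1440
1440 dEJ-free genes retained.
```

Every exclusion matches the generator's planted category labels exactly
(precision = recall = 1). Stage 5 relates the CUG motif to miRNA sites:

```
CUG in site flanks: 420 over 1000 sites; random positions: 207 (one-sided Fisher P = 2.69e-18)
CAG embedded in seed: 12 of 50 families (24%) vs 10.8% in shuffled cohorts (P = 0.00625)
```

— CUG is roughly twice as frequent next to seed-match sites as at random
positions in the same 3'UTRs, and 12 of the 50 most abundant families
carry CAG (the base-pairing partner of CUG) in their seed region. Stage
6 quantifies the expression signal:

```
Derepressed (log2FC > 0.2): 43.2%; downregulated (< -0.2): 13.5%
Fold-change slope per effective site: 0.088 log2 units
Same contrast under the siDicer1 background: K-S P = 0.37
Targets (n = 791) mean log2FC 0.321 vs 300 cohort nulls (mean 0.002): one-sample t P ~ 0
```

The per-site slope recovers the planted 0.08 (+ the CUG bonus share),
the longest-vs-shortest 3'UTR bin shift is significant under siUPF1 but
disappears when Dicer1 is co-depleted, and target derepression vastly
exceeds all shuffled-miRNA cohort nulls — the UMD signature.

`run_all()` wires the same stages programmatically and writes a manifest
of output digests; rerunning with the same configuration reproduces
every file byte for byte.

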