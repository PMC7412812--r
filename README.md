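# serbptools

Computational toolkit for an RNA-binding-protein (RBP) regulatory study
in glioblastoma, centered on the RBP SERBP1: it rebuilds, as tested and
reusable R functions, every analysis the study defines itself rather than
delegating to a published tool.

The package is for computational biologists who want to run, audit or
extend these procedures on their own data — or on fully synthetic data
with known ground truth, which the package also generates.

## What it implements

* **Probe pool design** (`design_pool()` and friends): an
  RNAcompete-style pool of 241,399 RNA oligos (≤ 41 nt) tiled from the
  lexicographically least order-11 de Bruijn sequence (Lyndon-word
  concatenation), with the SapI/BspQI sites GCTCTTC/CGAGAAG excised by
  logged minimal substitutions, an alternating A/B set split, an AGA/AGG
  T7 phi2.5 initiation prefix, and audited coverage guarantees — every
  attainable 9-mer ≥ 16 times pool-wide, every 7-mer (bar the excised
  pair) ≥ 155 times in each set.
* **Intensity scoring** (`kmer_zscores()`, `top_kmer_pfm()`): one-sided
  Z-scores of 7-mers from trimmed-mean log probe intensities, per set and
  combined, and a position-frequency motif from the top k-mers.
* **3'UTR motif enrichment** (`permutation_test()` et al.): the observed
  proportion of target genes carrying the GC-rich 7-mer GCGCGGG (or a
  PFM) in their 3'UTR versus a null of 10,000 same-size draws from the
  expressed background, with an add-one empirical p:
  p = (1 + #{null ≥ observed}) / (n + 1).
* **Promoter H3K27me3 calling** (`make_promoters()`,
  `call_methylation()`): ±3 kb TSS windows, FDR < 0.05 peaks,
  union-overlap per sample, and the ≥ 3-of-9-samples consensus rule.
* **DE thresholds and set integration** (`filter_de()`,
  `integrate_sets()`, `overlap_test()`): |log2FC| ≥ 1 & BH-FDR < 0.05
  (expression), log2FC ≥ 0.5 & FDR < 0.05 (RIP-Seq association),
  hypergeometric overlap tests.
* **Quantitative models** (`fit_fp()`, `pqn_normalize()`,
  `qc_cv_filter()`, `volcano_select()`): the one-site binding law
  FP(c) = FP0 + (FPmax − FP0)·c/(KD + c) fit by Levenberg–Marquardt with
  a bootstrap KD interval; probabilistic quotient normalization against
  the QC-median reference; the strict CV < 25% QC filter; volcano
  selection at |log2FC| ≥ 0.4 and Welch-t p < 0.05.
* **IHC scoring** (`score_ihc()`, `grade_association()`): intensity (0–3)
  × percent category (0–3) composite score, strong/moderate/weak/null
  classification, low/high binarization, chi-square association with
  WHO grade.
* **Synthetic data** (`sim_*()`): seeded generators with recorded planted
  truth for every input above.

## Worked example

Simulate a transcriptome whose designated targets carry the motif at 40%
against a 15% background, then test the targets for enrichment; fit a
noisy FP titration generated at the study's affinity:

```r
library(serbptools)

sim <- sim_transcriptome(n_genes = 2000, target_fraction = 0.1,
                         spike_rate_targets = 0.4,
                         spike_rate_background = 0.15, seed = 42)
bg  <- build_background(sim$counts)            # every simulated gene
res <- permutation_test(sim$targets, bg, sim$utrs,
                        n_iterations = 10000, seed = 42)
res
#> Motif enrichment permutation test
#>   targets: 200 of 2000 background genes
#>   observed proportion: 0.3900
#>   null: mean 0.1671, sd 0.0255 (10000 iterations)
#>   empirical p: 0.0002

fp  <- sim_fp(noise_sd = 1.5, n_replicates = 3, seed = 42)
fit <- fit_fp(fp$data, n_boot = 500, seed = 42)
fit
#> one-site FP fit: kd = 48 nM (fp0 = 61.2, fpmax = 160, SSE = 85)
#>   bootstrap 95% CI for kd: [43.9, 52.7] nM
```

The observed 39% of targets with the motif sits far above the null mean
of ~17% (the background spike rate), giving an empirical p at the
resolution of the permutation count; the binding fit recovers the true
KD of 47 nM within its bootstrap interval.

Designing and auditing the full default pool takes about 15 s:

```r
d <- design_pool()
d$reports$pool_9mer
#> k-mer coverage audit: k=9 scope=pool min=16 threshold=16 [PASS]
```

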