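---
title: "Methods: pool design, motif enrichment and the quantitative models"
author: "serbptools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pool design, motif enrichment and the quantitative models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serbptools)
```

serbptools collects the computational procedures around an RNA-binding
protein (RBP) regulatory study in glioblastoma: the design of an
RNAcompete-style oligonucleotide pool, 7-mer scoring of the hybridization
readout, a permutation test for motif enrichment in the 3'UTRs of RIP-Seq
targets, a promoter H3K27me3 caller, differential-expression threshold
filters with gene-set integration, a one-site fluorescence-polarization
(FP) binding model, metabolomics normalization and selection, and a
composite immunohistochemistry (IHC) score.  Every stage has a seeded
synthetic-data generator with recorded ground truth, so the whole pipeline
is testable on a desk without any external download.

## Probe pool design

The pool is built on the lexicographically least de Bruijn sequence of
order 11 over A<C<G<T, generated by the Fredricksen–Kessler–Maiorana
(Lyndon-word concatenation) construction.  The cyclic sequence of
4,194,304 nt contains every 11-mer exactly once; we linearize it by
appending the first 10 letters so every cyclic word also occurs as a plain
substring.  The construction is deterministic — no RNG is involved — which
is why two runs of `design_pool()` are byte-identical.

**Tiling.** 241,399 windows of 35 nt are cut from the linearized sequence
with the error-accumulating schedule `floor(i * (N - L) / (P - 1))`.
Steps then take exactly two adjacent values spread maximally evenly
(150,885 steps of 17 and 90,513 of 18 at default scale), the first window
starts at offset 0 and the last ends at the sequence end.  The resulting
overlap of at least 17 nt exceeds the 8 nt needed so that every 9-mer
occurrence of the source sequence lies wholly inside at least one window.

**Excision.** The SapI/BspQI restriction sites GCTCTTC and CGAGAAG must
not occur in any probe.  Each occurrence is repaired by substituting its
center base (falling back center-out) with the first alphabet-order base
that creates no new forbidden site within ±6 nt; every edit is logged.
The choice of replacement base cannot influence *which* k-mers are
destroyed — that is fixed by the position — only which are created, so the
deterministic alphabet-order rule loses nothing.

**Coverage audits and the attainability caveat.** The design is audited
for a minimum multiplicity of 16 over 9-mers pool-wide and 155 over
7-mers within each of sets A and B (the alternating split used for
internal comparisons), counting variable regions only, in DNA space, with
multiplicity.  One subtlety is forced by logic rather than choice: a
9-mer that *contains* a forbidden 7-mer can never occur in an excised
pool, so the 96 such 9-mers are structurally excluded from the audit
(`forbidden_supersets()`).  A pool-wide quota over all 262,144 9-mers is
unsatisfiable verbatim alongside the excision rule; the audit therefore
reads "every attainable 9-mer".

**Patching.** Excision collaterally destroys k-mers that overlap the
removed sites.  On the default construction this leaves 18 attainable
9-mers below 16 copies and a handful of 7-mers below the per-set quota of
155.  `design_pool()` restores them by replacing a small number of
windows (14 at default scale, bounded by 0.1% of the pool) with synthetic
patch probes packed with the deficient k-mers; donor windows are chosen,
scanning from the pool end, so that their removal leaves every eligible
k-mer at or above threshold.  Patch probes carry `start = -1` and
`patchNNNN` identifiers.  When a design is so tight that the deficits
cannot fit in the budget (for example a deliberately tiny pool), the
function warns and reports the failing audits honestly rather than
erroring: an audit is a measurement, not an assertion.

**Initiation prefix.** A phi2.5 T7 initiation trinucleotide (AGA,
falling back to AGG if the junction would recreate a forbidden site in
DNA space) is prepended and the sequence transcribed T→U.  With the
default forbidden pair the AGA junction can never complete either site,
so the pool is uniformly AGA-prefixed.  We read the 41-nt maximum as
including the prefix: 3 + 35 = 38 ≤ 41.

Secondary-structure minimization of the original pool is not reproduced —
the published description does not specify the procedure.  A simple
perfect-stem screen (`flag_hairpins()`) is provided but not applied by
default.  Not every 11-mer is represented after modification, and the
design does not try to enforce 11-mer completeness.

## 7-mer intensity scoring

`kmer_zscores()` scores each 7-mer by the 5%-per-tail trimmed mean of log
intensities of the probes containing it, within set A, set B and the
combined pool, then standardizes the raw scores across the scored k-mer
population.  The Z-score is one-sided in interpretation: only large
positive values indicate binding.  Three parameters matter:

* `trim` (default 0.05 per tail) — robustness to single bright probes;
* `min_probes` (default 10) — a k-mer is only scored in a scope where it
  has that many supporting probes.  The default suits the full pool,
  where a 7-mer is carried by roughly 430 probes; toy pools need a
  smaller value and the tests use 2–3;
* log base — natural log; standardization makes the choice immaterial,
  and the Z-scores are invariant to rescaling all intensities.

`top_kmer_pfm()` stacks the top-n 7-mers by combined Z, ungapped at
offset 0, into a position frequency matrix with an argmax consensus (ties
broken A<C<G<U).  Because high-scoring k-mers are often *shifted*
variants of the binding site, ungapped stacking can blur the consensus by
one position for larger n — the tests therefore pin the strict consensus
at n = 1 and check structural properties (column sums, GC content) at
n = 5.  The alignment-aware assembly of the original microarray pipeline
is out of scope.

## 3'UTR motif enrichment

The background universe is every gene with a count of at least 2 in at
least one sample (`build_background()`).  A gene "has the motif" if any
of its 3'UTR isoforms matches the query — either the exact 7-mer
GCGCGGG (default) or a PFM scored by log-odds against a uniform
background with a threshold at 80% of the maximal score; overlapping hits
count, N never matches, T and U are interchangeable.

`permutation_test()` compares the observed motif proportion among targets
with a null built by drawing the same number of genes *without
replacement* from the background, 10,000 iterations by default, matching
the study's 1,293-of-16,835 setting.  The empirical p uses the add-one
correction `(1 + #{null ≥ obs}) / (n + 1)` and is therefore never zero,
with the corresponding floor `1/(n+1)`.  When motif presence is binary
and genes exchangeable, the null proportion is hypergeometric and the
machinery can be checked against the closed form — with the caveat that
for events rarer than the floor the corrected estimator concentrates at
its floor, so the check must compare against the estimator's exact
expectation rather than the raw tail.  The sampler seed is recorded in
the result.

## Promoter H3K27me3 calling

Promoter windows are the symmetric ±3 kb flanks of each TSS (0-based
half-open, clipped at the chromosome origin; strand is irrelevant to a
symmetric window and retained only for provenance).  Peaks are filtered
at FDR-adjusted p < 0.05 when a p column is present; files without one
are treated as pre-filtered.  A window "has a peak" in a sample when the
union of that sample's peaks covers at least `min_overlap_bp` of it
(default 1 bp — any overlap; a stricter coverage reading is available via
the same parameter), computed with interval arithmetic that never double
counts overlapping peaks.  A gene is methylated when *some single window*
has peaks in at least 3 of the samples; with several TSS per gene the
windows are combined by OR.  Calls are monotone — adding a peak or
relaxing the FDR bound can only add samples — and invariant to peak order
and to splitting peaks into abutting pieces.

## Gene-set thresholds and integration

The threshold rules are read literally from their printed form: the
fold-change bound is inclusive (`log2FC ≥ 1` for expression, `≥ 0.5`
signed-positive for RIP-Seq association, with an absolute-value option),
and the FDR bound is strict (`padj < 0.05`), with BH adjustment computed
from raw p-values when the adjusted column is absent.  DE estimation
itself is consumed from finished tables; nothing in the filters depends
on how they were produced.  `integrate_sets()` annotates each
knockdown-upregulated gene with its membership in the GBM-down (vs LGG
and vs cortex) and H3K27me3 sets, and `overlap_test()` quantifies any
pairwise overlap with the hypergeometric upper tail and fold enrichment.

## Quantitative models

**FP binding.** The one-site law `FP(c) = fp0 + (fpmax − fp0)·c/(kd + c)`
is fit by Levenberg–Marquardt least squares, initialized from the data
(baseline = min reading, plateau = max, kd = concentration nearest
mid-saturation) with kd bounded positive, and a case-resampling bootstrap
for the 95% kd interval.  On the default grid (0–1000 nM, the study's
titration range, true kd 47 nM) the fit is exact on noiseless data and
recovers kd with median error under 2% at 1% noise.

**Metabolomics.** PQN divides each sample by the median, over features,
of its ratio to a reference spectrum; the reference is the feature-wise
median of the QC injections (an overall-median option exists because the
reference choice is a known degree of freedom).  The QC filter keeps
features with CV strictly below 25%.  Volcano selection requires both
|log2FC| ≥ 0.4 — we read the printed "0.4 fold-change threshold" on the
log2 scale, with the 1.4-linear-fold reading selectable — and a Welch
two-sample t-test p < 0.05 on log2 intensities.

**IHC.** Intensity (0–3) and the percent-positivity category (0; <25%;
25–75% with closed boundaries; >75%) combine into a total score.  The
operative sentence multiplies the two scores, and product is the default;
the additive reading that appears alongside it is available as
`mode = "sum"`, because under the product rule a total of 5 — a printed
moderate-category bound — is unattainable (attainable products are
{0,1,2,3,4,6,9}).  The package implements both and does not guess which
produced the cohort tables.  Classification is strong ≥ 6, moderate 4–5,
weak 1–3, null 0, binarized as high = {moderate, strong}; the grade
association is an uncorrected Pearson chi-square of binary expression
against low (WHO I–II) vs high (III–IV) grade.

## Synthetic data: what it does and does not emulate

All generators take an explicit seed, use the Mersenne-Twister stream in
a local scope (the session RNG is untouched), and return their planted
truth alongside the data; regeneration with the same seed is
byte-identical.

* `sim_transcriptome()` plants a 7-mer into motif-free (rejection
  sampled) UTRs at controlled per-group rates — 40% for targets by
  default, the study's observed target proportion, over a 15% background;
  counts guarantee the background filter recovers the full universe.
* `sim_peaks()` places TSS on a spaced grid so promoter windows are
  disjoint, gives each planted methylated gene a promoter-overlapping
  peak in exactly k samples (k = 3 by default, 9 samples as in the
  study), and confines decoys strictly between windows.
* `sim_de_table()` draws per-gene effects of ±2 log2 units and summarizes
  simulated replicates by mean difference and t-test.
* `sim_fp()` evaluates the one-site law (kd 47 nM, 0–1000 nM grid) plus
  Gaussian noise.
* `sim_metabolites()` builds QC replicates with *exact* per-feature CVs
  (a fixed unit-mean pattern rescaled per feature), so the 25% filter has
  deterministic truth, and derives group samples from the feature-wise QC
  median times planted fold changes, lognormal noise and per-sample
  dilution factors (0.5, 1, 2, 4).  With the group noise at zero the PQN
  quotients equal the dilution factors exactly; the default keeps a small
  noise (sdlog 0.05) for the testing of the t-based selection.
* `sim_intensities()` multiplies the intensity of probes containing a
  spiked 7-mer, under lognormal baseline and noise.

These generators are deliberately idealized: UTRs are i.i.d. with a flat
GC profile, peaks have no signal-strength model, counts are not
negative-binomial, and probe intensities have no sequence-composition
bias or spatial array effects.  Passing tests therefore demonstrate the
correctness of the algorithms under their stated models, not robustness
to the full messiness of real libraries.

## Numerical choices and problem sizes

Ties in consensus calling break in alphabet order; zero-variance Z-scores
are defined as 0; zero or missing features are excluded from PQN
quotients; zero-mean features are dropped (with a warning) by the CV
filter; degenerate flat FP titrations are rejected rather than fit.  The
test suite exercises the full default pool (241,399 probes) once, checks
it against an independent base-R k-mer counter, and runs the remaining
benchmarks at desk scale: 10,000-iteration permutation tests with a
closed-form oracle, 200 randomized caller instances against a per-base
oracle, 500 noisy FP fits, and a 2,000-feature null volcano calibration.
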