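---
title: "Models and methods behind snpdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind snpdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`snpdiv` analyses diploid biallelic SNP panels spanning many populations:
QC, within-population diversity, between-population distances and trees,
PCA, and admixture clustering. This vignette documents the statistical
models, the tunable parameters, the numerical choices, and what the
synthetic-data tests do and do not establish about real data.

## Data model

A `genotype_panel` stores an individuals-by-SNPs matrix of allele-b
dosages (0, 1, 2 copies; `NA` = missing call) with SNP metadata
(chromosome, 1-based position, two distinct alleles). The counting allele
is the ALT allele for VCF input and the second-observed allele for PLINK
text input. All statistics in the package are invariant to flipping the
counting allele at any subset of loci, which is why a single arbitrary
polarity convention is adequate.

One consequence worth knowing: a PED file stores only allele letters, so
the polarity of a SNP whose first non-missing call is homozygous for the
counting allele is not recoverable by any reader. `write_plink_text()` /
`read_plink_text()` therefore round-trip genotypes exactly, and dosages
exactly except for such columns, which read back flipped (`2 - d`) with
swapped allele labels — harmless downstream, and documented on the
functions.

## QC cascade

The filter order is fixed and not configurable (only the analysis stages
PCA/admixture can be switched off):

1. **Positional duplicates.** Any group of SNPs sharing chromosome and
   position is removed *entirely* — every member, not just the extra
   copies — because neither copy can be trusted when an array annotation
   maps two probes to one locus.
2. **Chromosome restriction.** Only a configured keep set survives
   (default autosomes "1".."28"); sex-linked, unplaced and ambiguously
   annotated SNPs drop out.
3. **Call rates.** Samples below the animal call rate (default ≥ 0.95,
   inclusive) are removed first; SNP call rates are then recomputed over
   the surviving samples and SNPs below the SNP threshold (default
   ≥ 0.99) removed. The order matters: a SNP missing only in discarded
   samples is retained.
4. **LD pruning.** A sliding window of `window_size` SNPs (default 50),
   advanced by `window_shift` (default 5), scans each chromosome
   separately. Within a window, while any retained pair has genotypic
   r² > `r2_threshold` (default 0.2), one member is removed. r² is the
   squared Pearson correlation of unphased dosages over pairwise-complete
   entries; it is undefined (and never causes pruning) when a vector is
   constant or fewer than two complete pairs exist. Window parameters are
   SNP counts, matching the conventional "50 5 0.2" triple.

   Which member of an offending pair to drop is not standardized across
   tools; `snpdiv` removes the SNP with the lower call rate and breaks
   ties by removing the later index. This is deterministic and
   data-preserving. The test suite checks the windowed implementation
   against a brute-force re-scan reference of the same greedy rule.
5. **Imputation.** Remaining missing calls are replaced by draws from
   Binomial(2, q̂), where q̂ is the sample's *within-population* allele
   frequency at that SNP (panel-wide frequency when the population has no
   observed call; 0.5 when nobody has one). This deliberately simple,
   seeded imputer preserves per-population allele frequencies and expected
   heterozygosity — the only properties the downstream statistics
   consume. It does not reconstruct haplotypes; linkage information at
   imputed cells is noise, which is acceptable because imputation runs
   *after* LD pruning in the cascade.

The `qc_report` reconciles exactly: input SNPs minus per-stage removals
equals the output count at every stage, and the tests assert this against
the generator's injected truth.

## Diversity statistics

With q the within-population allele-b frequency at a SNP (dosage sum over
twice the observed calls):

* **Observed heterozygosity** Hₒ: per SNP, the fraction of non-missing
  calls equal to 1; averaged over SNPs with at least one call. Computed
  over all post-QC SNPs, including those monomorphic panel-wide.
* **Expected heterozygosity** Hₑ = 2q(1 − q), averaged over SNPs with
  defined q; its biallelic maximum is 0.5.
* **Proportion of polymorphic loci** p: the fraction of defined-q SNPs
  with 0 < q < 1. No minor-allele-frequency threshold is applied —
  "polymorphic" means both alleles were actually observed in the sample.

Category summaries are *unweighted* means over member populations (each
population counts once, regardless of its sample size), because the
population is the sampling unit when categories are compared; the overall
mean Hₒ is likewise the unweighted population mean.

## Reynolds distance and neighbor joining

For two populations with per-locus frequencies p₁, p₂ (same allele),
heterozygosities αᵢ = 2pᵢ(1 − pᵢ) and diploid sample counts n₁, n₂, the
least-squares coancestry estimator accumulates per locus

```
num = (p1 - p2)^2 - (n1 + n2)(n1 a1 + n2 a2) / (4 n1 n2 (n1 + n2 - 1))
den = (p1 - p2)^2 + (4 n1 n2 - n1 - n2)(n1 a1 + n2 a2) / (4 n1 n2 (n1 + n2 - 1))
```

and θ = Σnum / Σden over loci — a ratio of sums, not a mean of per-locus
ratios, so information-poor loci do not dominate. Loci with an undefined
frequency on either side are skipped. θ is clamped to [0, 1]: small true
divergence can make Σnum slightly negative, and NJ needs non-negative
distances. The correction terms can be disabled (`correct = FALSE`) to
obtain the frequency-only simplification; the corrected form is the
default. The distance is θ itself by default, with `-ln(1 - θ)` available
as a monotone alternative that leaves NJ topologies unchanged at small θ.

Under the Balding–Nichols generator with two populations of drift F, the
estimator's large-sample limit equals F — E[(p₁−p₂)²] = 2F p₀q₀ against a
denominator of 2p₀q₀ — which the tests verify at F = 0.1, n = 50,
M = 5000.

Neighbor joining is the classical (unweighted) Saitou–Nei algorithm:
join the pair minimizing Q(i,j) = (r−2)d(i,j) − Rᵢ − Rⱼ, standard limb
lengths, negative limbs clamped to zero, final trifurcating root for ≥ 3
taxa. Ties in Q are broken by the lexicographically smallest label pair (a
cluster is keyed by its smallest leaf label) so the output is identical
across platforms. NJ is consistent on additive matrices; the tests verify
exact recovery of random 8- and 12-taxon trees and agreement with an
independent NJ implementation. The Newick writer quotes labels containing
metacharacters (quotes doubled) because common writers mangle them.

## PCA

Dosage columns are centered at 2p̂ and, by default, scaled by
√(2p̂(1−p̂)) — the variance of a binomial allele count — so that high- and
low-frequency SNPs contribute comparably (centering-only is available).
Monomorphic columns are dropped; an all-monomorphic panel is an error, as
is any missing call (impute first). Scores come from the SVD of the
normalized matrix; `explained` is each component's share of total
variance. Each component's sign is fixed so its largest-magnitude loading
is positive, for reproducibility. Population-mean scores are exact
arithmetic means of member individuals — a display device for panels with
hundreds of populations, not a new statistic.

## Admixture model

Genotypes are modelled as g_ij ~ Binomial(2, h_ij) with
h_ij = Σₖ q_ik f_kj, q the individual's ancestry proportions (rows sum
to 1) and f the ancestral cluster allele frequencies. The fit is plain EM:
per allele copy, responsibilities proportional to q_ik f_kj (and
q_ik(1 − f_kj) for the reference allele); the M-step renormalizes expected
copy counts. The M-step is exact (no clipping), which preserves the EM
guarantee that the log-likelihood never decreases; h is clipped to
[1e-10, 1 − 1e-10] only inside the likelihood to avoid log(0) at loci
fixed within a cluster. Initialization: seeded flat-Dirichlet q and panel
frequencies perturbed by ±0.05 for f. Convergence: relative log-likelihood
change < 1e-6 (default) or 2000 iterations. K = 1 reaches its closed form
(f = mean dosage / 2) in one step. Quasi-Newton acceleration used by
dedicated admixture software finds the same stationary points faster; at
the panel sizes this package targets, monotone EM is fast enough and much
easier to verify. Label switching is resolved only at evaluation time, by
greedy correlation matching of Q columns (`match_components()`), never
inside the fit.

**Choosing K.** `admixture_cv()` hides disjoint random fractions of cells
(default 10% × 5 folds), refits on the observed cells only (EM simply
skips hidden cells), predicts hidden dosages as 2h, and scores each K by
the mean squared error on hidden cells. The K minimizing CV error is
reported. The metric differs from the deviance residuals used by the
ADMIXTURE program, but only the *ranking* of K is consumed, and dosage MSE
ranks identically in the regimes tested while being directly checkable: at
K = 1 the CV error must approach the binomial variance benchmark
mean((g − 2p̂)²), which the tests assert. A mask that would leave a SNP
with no observation is redrawn (bounded retries).

## Synthetic panels

`simulate_panel()` generates the study conditions for every test:

* ancestral frequencies uniform on (0.05, 0.95); population frequencies
  Balding–Nichols, Beta(p₀(1−F)/F, (1−p₀)(1−F)/F), giving variance
  F·p₀(1−p₀) (verified within 10% at 20,000 SNPs);
* pure individuals Binomial(2, pop freq); admixed individuals draw each
  allele copy from a population sampled by their Dirichlet ancestry
  vector — exactly the admixture model's own assumption, so parameter
  recovery is well-posed;
* LD blocks share one latent frequency per block and copy a per-individual
  template haplotype with 5% per-copy noise, giving within-block r² ≈ 0.8
  in expectation — enough to exercise pruning deterministically without a
  coalescent simulator;
* duplicated SNPs are exact column copies placed adjacently with identical
  chromosome and position (missingness is injected afterwards, so masked
  cells may differ); trailing SNPs can be relabelled to chromosome "Z";
  MCAR missingness at a configurable rate, plus designated samples forced
  to 90% call rate (below the 95% animal threshold);
* everything flows from one root seed; the same seed reproduces the panel
  bit for bit.

What these panels do **not** emulate: ascertainment bias of array SNP
selection, realistic recombination maps and LD decay, genotyping error,
related individuals within populations, and sex-chromosome dosage. Tests
passing on these panels therefore establish the correctness of the
*estimators and algorithms* under their own model assumptions, not the
field behaviour of the statistics on any particular array.

## Problem sizes and determinism

The test and acceptance workloads use panels of 80–200 individuals and
400–5000 SNPs, sizes at which every property under test (drift recovery,
HWE consistency within ±0.01, ancestry MAE < 0.05, K selection in ≥ 7/10
seeds) is comfortably identifiable; larger panels sharpen the same
estimates without changing any conclusion. All randomness — simulation,
imputation, EM starts, CV masks — is seeded, and `run_pipeline()` derives
per-stage seeds from one root seed, so complete reruns are byte-identical
(numeric output is written through fixed-precision formatting to keep text
artifacts stable).

## Known limitations

* The imputer ignores haplotype structure by design; do not use its output
  for LD-sensitive analyses.
* Reynolds θ assumes biallelic loci and diploid samples of size ≥ 2
  everywhere; populations with a single sample must be merged or dropped
  before `reynolds_matrix()`.
* The admixture EM, like all mixture fits, has local optima: use several
  seeds and keep the best log-likelihood (the tests use three).
* CV-based K selection is only meaningful when clusters are actually
  separated; on continuous clines the CV curve can decrease without a
  clear minimum.
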