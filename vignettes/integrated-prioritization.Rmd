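---
title: "Integrated mouse-transcriptome / human-GWAS gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated mouse-transcriptome / human-GWAS gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abprio)
library(dplyr)
```

## The problem and the model

Genome-wide association studies of Alzheimer's disease detect loci, but
with moderate cohort sizes few genes beyond *APOE* reach genome-wide
significance, and SNP-level hits say little about mechanism. `abprio`
implements a cross-species prioritization that asks a narrower question:
which genes both (a) show genetically driven expression differences that
track amyloid-beta accumulation in mouse brain, and (b) carry at least
nominal association signal in a human case-control GWAS?

The pipeline has three statistical layers.

**Mouse two-step screen.** Non-transgenic inbred strains differ in their
susceptibility to amyloid pathology. Step one compares hippocampal
expression in the low-susceptibility strain (DBA) against each other
strain (C57BL/6, SJL) with an equal-variance two-tailed Student *t* test
per probe; because these animals carry no APP transgene and accumulate no
amyloid, any differential expression reflects genetic background rather
than a downstream consequence of pathology. The per-probe summary
p-value is, by default, the minimum over the two pairwise comparisons
("different from B6 *or* SJL"); `mode = "both"` and `mode = "pooled"`
are provided because the selection rule is a design choice, not a
mathematical necessity. Step two scores each candidate in APP transgenic
animals with mixed genetic background: the Pearson correlation *r*
between expression and the per-animal amyloid-beta level, with the
two-tailed p-value from
\(t = r\sqrt{(n-2)/(1-r^2)}\) on \(n-2\) degrees of freedom. The sign
of *r* is carried as an Up/Down annotation.

**Human gene-based statistics.** Per-SNP association uses additive-coded
logistic regression with age and sex as covariates (Wald test on the
dosage coefficient); the genomic inflation factor
\(\lambda = \mathrm{median}(\chi^2_{obs}) / 0.4549\) and QQ coordinates
are reported as diagnostics. SNPs are assigned to a gene when they fall
inside the transcript region extended by 3 kb on both flanks, or when
they are in high LD (\(r^2 > 0.8\), strict) with an in-region SNP;
LD proxies are searched within 1 Mb of the region, a bound chosen to
exceed typical LD range while keeping the search finite. Gene-level
p-values use the extended-Simes (GATES) statistic
\[
p_{gene} = \min_j \frac{M_e \, p_{(j)}}{M_e(j)},
\]
where \(p_{(j)}\) are the sorted SNP p-values, \(M_e\) is the effective
number of independent tests of the full p-value correlation matrix and
\(M_e(j)\) that of the leading \(j \times j\) block. The p-value
correlation is approximated from the genotype correlation by the
standard sixth-degree polynomial
\(0.2982 r^6 - 0.0127 r^5 + 0.0588 r^4 + 0.0099 r^3 + 0.6281 r^2 -
0.0009 r\); an `r2` fallback is provided. \(M_e\) is computed as
\(M - \sum_{\lambda_i > 1} (\lambda_i - 1)\) over the eigenvalues of
that matrix, clamped to \([1, M]\).

**Integration.** Mouse and human evidence meet through a curated
human–mouse ortholog table (symbols matched case-insensitively; when
several mouse genes map to one human gene, the smallest mouse p-value is
kept and the row flagged). Both two-tailed p-values are halved, converted
to one-tailed z-scores by the standard normal quantile function, and
combined without weights:
\[
Z_C = \frac{Z_{MEXP} + Z_{HGWAS}}{\sqrt{2}},
\qquad
p_C = 2\,\Phi(-Z_C) .
\]
Significance is called at \(0.05 / n_{tested} / 2\), the family-wise
level divided by the number of genes tested and by the final doubling.

A validation layer mirrors a qPCR follow-up in independent brain tissue:
target expression normalized to a reference gene (ratio on the linear
scale, \(2^{-\Delta Ct}\) on the cycle scale), equal-variance *t* test of
AD versus control, Benjamini–Hochberg adjustment across the genes tested,
and a descriptive flag recording whether the sign of the AD-minus-control
difference is concordant with the mouse direction.

## Conventions that were genuinely open

* **Halve-then-invert.** "One-tailed z from a two-tailed p" admits two
  readings. We use \(z = \Phi^{-1}(1 - p/2)\) for *both* inputs; it is
  the only convention under which the five shipped candidate-gene
  combined p-values reproduce from their input pairs at three
  significant figures (see `candidate_gene_stats()` and the worked
  example in the README).
* **Direction never flips the z.** A negatively correlated mouse gene
  contributes the same evidence as a positively correlated one;
  Up/Down is annotation. A consequence, quantified in the test suite:
  with two independent uniform p-values the combined p is
  *anticonservative* (folding both z-scores to be non-negative biases
  \(Z_C\) upward), so combined p-values are comparable with each other
  and with the stated threshold, but are not frequentist tail
  probabilities under the joint null. We report this rather than
  recalibrate, because the recipe itself is the method.
* **Probe-to-gene collapse.** Among a gene's probes the one with the
  smallest correlation p is kept; ties break by larger \(|r|\), then
  lexicographic probe id, making the collapse deterministic.
* **Either-mode screen.** The default `mode = "either"` (min over
  pairwise comparisons) makes the screen's selection rate up to twice
  the nominal \(\alpha\) under the null; `pooled` mode is exactly
  calibrated. The false-discovery proportion at a threshold is
  estimated by `fdr_at_threshold()` as \(m\alpha/k\).
* **GATES edge cases.** The p-value-correlation polynomial evaluates on
  \(|r|\) (even function) and is pinned to exactly 1 at \(|r| = 1\), so
  duplicated SNPs collapse to a single test and unit LD reduces the
  statistic exactly to the minimum p. Negative eigenvalues from the
  approximate correlation matrix are truncated at zero before computing
  \(M_e\). Sorting ties break by position then id, so the statistic is
  invariant to input order.
* **Genes with no assigned SNPs** are excluded from gene-based testing
  (and reported), as is standard.

## The synthetic-data generator

No raw cohort travels with the package; a seeded generator reproduces
the *structure* of each input so that every stage can be tested against
planted ground truth.

* **Strain expression**: gene baselines \(\mathcal{N}(8, 1)\), i.i.d.
  Gaussian array noise (SD 1 on the log-intensity scale), and a planted
  shift in the target strain only. The default shift is 6 noise-SD:
  with 4 arrays per strain, the noncentral-*t* power of the screen at
  \(p < 0.001\) is then above 90% per planted gene, so planted-recovery
  properties are testable. (A 3-SD shift, for comparison, gives only
  ~23% per-comparison power at this sample size.)
* **Transgenic cohort**: 28 animals; amyloid-beta is log-normal
  (`meanlog = log(50)`, `sdlog = 0.5`), positive and right-skewed as
  ELISA measurements are. Causal-gene expression is built as
  \(r \cdot A + \sqrt{1-r^2}\,\varepsilon\) with \(A\) standardized by
  the analytic log-normal moments, so the *population* correlation
  equals the signed target (default \(|r| = 0.7\)) exactly.
* **Genotypes**: two haplotypes per individual from a latent-Gaussian
  AR-1 threshold model within blocks (default 5 SNPs per block, latent
  \(\rho = 0.8\), MAF uniform on \([0.1, 0.5]\)), independent across
  blocks. Thresholding attenuates correlation: a latent \(\rho\) of
  0.95 yields a median adjacent dosage \(r^2\) near 0.64 at MAF 0.3;
  \(r^2 > 0.8\) requires \(\rho \approx 0.99\). Tests assert the
  attenuated values, not the latent ones.
* **Phenotypes**: logistic model with per-allele odds ratio 1.5 at each
  planted causal SNP plus small age (0.02/year) and sex (0.25) effects.
  The intercept is bisected against the *realized* case fraction (the
  uniform draws are fixed first), so the target fraction (default 0.5)
  is met within 0.02 deterministically.
* All randomness flows from one root seed through fixed per-stage
  offsets, so a stage can be regenerated without re-running the others,
  and identical configurations are bit-identical.

What the generator does *not* emulate: microarray probe-level artifacts
and normalization, genotyping error and imputation uncertainty,
population stratification, realistic demography, linkage between blocks,
and genes with many probes or overlapping regions. Passing tests
therefore demonstrate that the statistical machinery is correct and
calibrated under clean assumptions, not that the pipeline is robust to
those real-data complications.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run, among smaller unit
fixtures: a 50,000-SNP null GWAS (1,000 individuals) for the genomic
inflation and uniformity checks; 10,000 permutation replicates of a
10-SNP AR-1 (\(\rho = 0.8\)) gene for the type-I-error calibration of
the gene-based test, using score-statistic p-values
(\(z = \sqrt{n-1}\,\mathrm{cor}(x, y)\)) which are asymptotically the
Wald p-values the pipeline computes; Monte-Carlo oracles of \(10^6\)
draws for the p-value-correlation polynomial; and replicate end-to-end
studies of 200 genes (3 planted) at the default effect sizes — 50
replicates in the test suite, 20 in the acceptance script. These sizes
were chosen so each check has enough resolution for the band it asserts
(e.g. a Monte-Carlo SE of ~0.002 on the calibration rate against an
asserted band of \([0.03, 0.07]\)).

## Known limitations

* The combined statistic's anticonservatism under the joint null
  (documented above) means combined p-values should be read as a
  ranking score with a fixed threshold convention.
* GATES calibration is validated on AR-1 LD and limiting cases; exotic
  LD structures (long-range, non-positive-definite empirical matrices)
  are handled by eigenvalue truncation but not separately calibrated.
* The per-SNP logistic Wald test is anti-conservative for very rare
  variants; the generator's MAF floor (0.1) keeps the shipped checks
  away from that regime.
* The `fdr_at_threshold()` estimator is the simple expected-false-
  positives ratio; it can exceed 1 and is reported, not inverted into
  q-values (use `bh_adjust()` for that).

## Session info

```{r}
sessionInfo()
```
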