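---
title: "Methods: donor islet RNA-seq association, coexpression and eQTL analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: donor islet RNA-seq association, coexpression and eQTL analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletview)
```

# Scope and model

`isletview` implements the analytical backend of a donor-islet transcriptome
resource: starting from a raw gene × donor count matrix, donor phenotypes,
gene annotation and genotypes, it produces covariate-adjusted associations of
expression with diabetes phenotypes, empirically calibrated gene–gene
coexpression, a cis-eQTL scan, bootstrap gene-set enrichment, and per-gene
JSON reports. Because real donor-islet cohorts are controlled-access, the
package also ships a synthetic cohort generator with planted ground truth;
every stage of the pipeline is tested against that truth.

# Quality control and normalization

Two filters mirror standard bulk RNA-seq practice for islet cohorts:

* **Samples** with fewer than 10 million total reads are excluded
  (`filter_samples()`, strict inequality at the boundary).
* **Genes** are retained when detected (FPKM > 0) in at least 95% of samples
  *and* their mean FPKM exceeds 1 (`filter_genes()`). FPKM uses the merged
  exonic length from the GTF (or a `length` column in tabular annotation).

Between-sample scale factors are trimmed means of M-values
(`tmm_factors()`): the reference sample is the one whose 75th CPM percentile
is closest to the cohort mean; per sample, log2 expression ratios (M) and
average log2 abundances (A) against the reference are doubly trimmed (30% on
M, 5% on A) and the factor is the precision-weighted mean of the surviving
M-values, with weights the inverse asymptotic binomial variances. Factors
are rescaled to geometric mean 1. The test suite pins this behaviour against
a hand computation on a small fixture and against the independent edgeR
implementation.

Expression is transformed to log2-CPM with a prior count of 0.5 and an
effective library size `lib * factor + 1`. Precision weights
(`precision_weights()`) follow the mean–variance trend approach: per-gene
linear-model residual standard deviations (square-rooted) are smoothed
against average log2 count by lowess with span 0.5, and each observation's
weight is the predicted standard deviation at its fitted log-count raised to
the power −4. With fewer than 10 genes the trend is flat. The weights match
the limma voom implementation to numerical precision in the tests.

# Phenotype association

Donors are stratified by glycemia (`assign_strata()`): T2D with a clinical
diagnosis or HbA1c ≥ 6.5%, IGT at HbA1c in [6, 6.5), NGT otherwise. The
boundary convention (lower bound inclusive, upper exclusive) is pinned and
configurable, since percentage boundaries are ambiguous in prose. Donors who
are T2D by HbA1c alone — with no clinical diagnosis — are excluded from the
T2D-vs-control differential-expression contrast but keep their stratum for
the strata analysis.

For each phenotype (T2D status, HbA1c stratum, continuous HbA1c, BMI,
stimulatory index) a design matrix with intercept, phenotype encoding and
the covariates purity, sex, and age is built; islet purity is included
because exocrine contamination is the dominant expression confounder in
islet preparations (in the default simulation, roughly half of all genes
load on purity). Rows missing the phenotype are dropped only for that
phenotype's analysis. Per gene, a weighted least-squares fit yields the
phenotype effect; residual variances are shrunk toward a common prior by
moment matching of log residual variances against a scaled F distribution
(the prior degrees of freedom solved by a Newton inversion of the trigamma
function), giving moderated t statistics on `d0 + d` degrees of freedom.
The moderation can be switched off, in which case the fit equals an ordinary
per-gene weighted regression — the oracle used in the tests. For the HbA1c
strata the default test is a joint (moderated F) test of the two non-NGT
dummies, with per-stratum contrasts also reported; a trend test was the
other defensible choice, and the joint test was picked because it is
agnostic to monotonicity. The reported `r2` is the partial coefficient of
determination of the phenotype term given the covariates, i.e., the relative
reduction in weighted residual sum of squares — a single-number definition
chosen because per-gene "R²" is otherwise underdetermined. FDR is
Benjamini–Hochberg across genes; the percentage rank is
`100 * rank(p) / n_genes` with average ranks for ties.

Batch enters the analysis only on the eQTL path (below). Keeping batch out
of the association design and applying empirical-Bayes batch adjustment only
before the genotype scan are both configurable; the defaults reflect a
pipeline in which the association stage relies on the variance weights to
absorb technical noise.

# Coexpression and its empirical null

Gene–gene similarity is Spearman correlation (Pearson on average ranks).
Significance is **empirical**: `build_null()` samples 1 million unordered
gene pairs (uniformly, with replacement, self-pairs excluded) from the
filtered universe and stores the sorted absolute correlations. The p-value
of an observed correlation is the proportion of background pairs at least as
extreme in absolute value — a two-sided convention, since the prose
definition of "more extreme" does not fix sidedness and signed correlations
are still reported alongside. A zero count is floored at `1/n_pairs` so that
−log10 transforms stay finite; the raw proportion is available behind a
flag. The null records a digest of the gene universe and refuses queries
against a different universe. Sampling with replacement is used because at
10^6 draws from millions of possible pairs, collisions are immaterial.

Hormone panels correlate a query gene against the six islet secretory genes
(INS, GCG, SST, PPY, IAPP, GHRL) with significance at empirical p ≤ 0.05;
`coexpressed_with()` returns the top 100 co-expressed genes by |ρ| with ties
broken lexicographically.

# cis-eQTL scan

Variants within 2 Mb of the gene body (boundaries inclusive; distances
signed, negative upstream) are tested by regressing batch-adjusted,
residualized expression on residualized allele dosage. The batch adjustment
is the parametric empirical-Bayes location/scale method: per-gene
standardization protecting covariates, per-batch means and variances shrunk
toward batch-level priors (normal / inverse-gamma, moment-matched, solved by
fixed-point iteration), then back-transformation; it is verified against the
sva implementation to numerical precision. A single batch is an exact
identity. The scan statistic is `t = r sqrt(d / (1 - r^2))` with
`d = n - 1 - rank(intercept + covariates)`; FDR is computed across **all**
tests in the scan, not per gene. Per-gene summaries report the lead eQTL
(smallest p, ties to the nearer variant, then variant id) and the top 10.
The window is anchored at the gene body rather than the TSS because the
window rule is stated in genomic distance from the gene; dosage is additive
(0–2), with the alt allele as the effect allele.

# Bootstrap gene-set enrichment

To ask whether a gene set is enriched for genes co-expressed with a target
(typically a hormone gene), the observed statistic is the mean empirical
coexpression p of the set against the target. The null is built by drawing
10,000 random same-size gene sets from the universe and recomputing the
mean; the bootstrap p is `(1 + #{null ≤ observed}) / (B + 1)` (add-one, so
never exactly zero), one-sided for enrichment with a two-sided option.
Null sets are drawn without replacement within a set and do not exclude the
query set's genes, matching a plain "random sets of genes" scheme.

# Cross-tissue expression and reports

A gene is called expressed in a tissue when its CPM is at least 1 in
strictly more than 80% of that tissue's samples. Islet-expressed genes are
classified into segments A–H by which of fat/liver/muscle share them (A =
islet only … H = all four). Per-gene reports assemble the upstream tables —
tissue panel, purity correlation, expression percentile (mean log2-CPM by
default; median behind a flag, since the averaging statistic for the rank
panel is otherwise unspecified), the five phenotype associations, hormone
panels, top-100 coexpression, top-10 eQTLs, and an optional cell-type
lookup join — into schema-versioned JSON without recomputing any statistic.

# The synthetic cohort generator

`simulate_cohort()` emulates the cohort structure the analyses assume. The
defaults are fixed at the study conditions: 188 donors — 33 with a clinical
T2D diagnosis, 25 T2D by HbA1c only, 30 IGT — HbA1c drawn consistently with
each stratum, islet purity Uniform[40, 100] shifted 15 points lower in T2D
donors (creating a purity–status confound), purity loadings on 50% of genes
(log2 slope 0.01–0.03 per percentage point, random sign), 100 planted
differential genes at |log2FC| = 1, six hormone-anchored coexpression
modules of 30 genes driven by standard-normal latent factors with loading 1,
two sequencing batches with per-gene location shifts (SD 0.2 log2) and
dispersion scaling (SD 0.1 on the log), negative-binomial counts (dispersion
0.1) at donor depths of 12–60 million reads, and 50 planted cis-eQTLs at
MAF 0.3 with one causal variant among 10 cis variants per genotyped gene
plus decoy variants at 2.5–2.9 Mb that structurally probe the window
boundary. Counts use 2000 genes by default — a desk-scale universe that
keeps the full pipeline fast while leaving the gene filter, variance trend
and FDR machinery meaningfully exercised.

The generator is deliberately simple in ways worth naming: genotypes are
independent Binomial(2, maf) draws with no linkage disequilibrium; gene
lengths are log-normal rather than empirical; hormone genes dominate
library composition (as in real islets) but there is no explicit cell-type
mixture model — purity acts as a single linear confounder. Passing tests
therefore demonstrate that the statistical machinery recovers planted
structure under the stated generative model, not that it is robust to every
artefact of real islet data.

# Numerical choices and degenerate inputs

Ties in Spearman correlations use average ranks. Constant expression rows,
constant purity, single-sample batches, rank-deficient designs and zero
library sizes raise immediate errors naming the offending input. Zero-
variance dosages are skipped (and counted) by the scan rather than erroring,
since monomorphic variants surviving the MAF filter are a data property.
The EB fixed-point iteration stops at a relative change of 1e-4 (matching
the reference implementation's tolerance); the trigamma inversion runs
Newton to 1e-8. The genotype MAF filter defaults to 0.05 — a conventional
choice, made explicit because the analysis description itself states no MAF
threshold.

# Problem sizes used in the checks

The automated checks run the cohort generator at 2,000 genes with 60–188
donors (association and calibration), 1,000 genes × 150 donors × ~1,000
variants (eQTL recovery over 10 seeds), 20 seeds for differential-expression
recovery, and bootstrap enrichment at B = 1,000 with 200 calibration
replicates; the background correlation null uses 2 × 10^5 pairs in the
acceptance script (the API default remains 10^6). These sizes were chosen so
the whole suite completes in minutes while keeping every estimate's Monte
Carlo error far below the margins being asserted.

# Known limitations

No linkage disequilibrium or conditional eQTL analysis; no trans-eQTLs; no
mixed models or interaction terms; the non-parametric variant of the batch
adjustment is not implemented; pathway/network analysis is out of scope.
The empirical coexpression null is tied to one expression matrix — changing
the universe requires rebuilding it.
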