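---
title: "Models and methods behind sexomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sexomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`sexomics` reimplements, as one tested pipeline, an integrated
methylome + transcriptome analysis of sex differences in a small balanced
design: 6 males vs 6 females, paired RNA-seq counts and whole-genome
bisulfite sequencing (WGBS) cytosine calls from the same animals, plus
fat-percentage phenotypes. The pipeline chains phenotype comparison,
negative-binomial differential expression, per-sex signed co-expression
networks with a cross-sex differential co-expression (DcoExp) test,
beta-binomial differential methylation at locus (DML) and region (DMR)
level, multiblock sparse PLS-DA integration of the two omics, module-trait
correlation, and QTL/term enrichment. Every stage is exercised on synthetic
data with planted ground truth; no external downloads are required.

# Differential expression

Counts are FPKM-normalized for filtering; a gene is removed only when its
mean FPKM is below 0.2 in **both** sexes. Testing uses median-of-ratios
size factors and a group-mean negative-binomial Wald statistic:

$$\log_2 \mathrm{FC} = \log_2\frac{\bar{K}_F + c}{\bar{K}_M + c},$$

with normalized group means $\bar{K}$, pseudocount $c = 0.5$ (so that a
transcript expressed in one sex only still has a finite fold-change), and a
delta-method standard error using the NB variance
$\mu/s_j + \alpha\mu^2$ per sample. Positive values mean higher expression
in females. Per-gene dispersion $\alpha$ is method-of-moments on
normalized counts after removing the sex-group means, floored at
$10^{-4}$; no empirical-Bayes shrinkage is applied — a deliberate
simplification that keeps the estimator transparent and testable at this
scale. The Wald statistic is referred to a $t$ distribution with $n - 2$
degrees of freedom rather than a normal: with 12 samples the plug-in
variance is noisy, and simulation shows the normal reference inflates the
null rejection rate above 8% while the $t$ reference holds it near 5%.
DEGs require FDR < 0.05 and |log2FC| > 2 (strict inequalities);
integration candidates require only |log2FC| > 1.

# Co-expression networks and the DcoExp test

Per sex, on log2(FPKM+1): the signed adjacency
$a_{ij} = ((1 + r_{ij})/2)^\beta$ with the smallest $\beta \le 20$ whose
scale-free fit reaches $R^2 \ge 0.8$ (fallback 12), the topological
overlap matrix, average-linkage clustering on $1 - \mathrm{TOM}$, a static
branch cut, and up to 20 sweeps of k-means-style reallocation of genes to
the module eigengene (first principal component, sign-anchored to the mean
member profile) with maximal correlation. Members whose eigengene
correlation falls below 0.5 are released to grey.

The static cut is placed at 0.95 of the tallest merge height.
Unstructured genes merge close to the top of the tree, so a cut just
below it isolates them, while a cut at (or defined by a quantile of) the
merge heights lumps essentially every gene into some cluster — with only
six samples per network, unstructured genes then ride along inside real
modules and dilute the cross-sex overlap test. The cut fraction, minimum
module size (30) and kME membership threshold (0.5) are exposed
parameters. Before computing correlations each sample's mean
log-expression is removed (see below for why).

The DcoExp test follows the cross-tabulation logic: for every module in
one sex against every module of the other, a one-sided Fisher/hypergeometric
enrichment test of the membership overlap, BH-corrected within each
direction; a module is *differentially co-expressed* when no other-sex
module reaches FDR < 0.05 against it. The test universe is restricted to
genes assigned to a module in **both** sexes. This matters: a gene's
propensity to be clustered at all depends on its noise level and is
therefore correlated between the two networks, so leaving never-clustered
genes in the background inflates every overlap above its hypergeometric
expectation and spurious "counterparts" appear.

Module-trait association is the Pearson correlation between a module
eigengene and each fat-percentage trait, computed strictly within the
module's own sex (n = 6), flagged at p < 0.05. With six observations only
|r| ≳ 0.81 reaches significance; the tests make this explicit.

# Differential methylation

Per context (CG, CHG, CHH, processed independently end-to-end):
group methylation at a site is the pooled fraction over all same-context
sites within ±250 bp on the chromosome (window 500 bp, a config key;
window 0 disables smoothing). Per-site beta-binomial dispersion
$\varphi$ is method-of-moments, pooling squared deviations of per-sample
fractions from each sex's smoothed mean and solving
$\mathrm{Var}(x/n) = \mu(1-\mu)(1 + (n-1)\varphi)/n$, clamped to
$[10^{-3}, 0.5]$; sites with fewer than two covered samples per sex get
the floor, and no genome-wide shrinkage is applied.

The DML Wald statistic is $(\mu_F - \mu_M)/\sqrt{v_F + v_M}$ where $v$ is
the variance of the pooled **windowed** estimator,
$\mu(1-\mu)\,(N + \varphi(\sum_r n_r^2 - N))/N^2$ over all site-sample
cells in the window — matching the estimator actually used for the means;
using the single-site totals instead wastes the precision the smoothing
buys and costs real power on dense regions. The p-value uses a $t$
reference with (covered samples − 2) degrees of freedom for the same
small-sample reason as in the expression module; simulation puts the null
rejection rate at ~5% and the power at planted |Δ| = 0.5, 30× coverage at
essentially 1.

DMRs: candidate sites at p < 0.01 are clustered (gap ≤ 100 bp), clusters
kept when span ≥ 50 bp, ≥ 3 analyzed sites, and ≥ 50% of analyzed sites
significant; surviving regions merge when separated by fewer than 50
intervening bases (gap defined as start₂ − end₁ − 1, strict < 50).
Annotation precedence is Promoter > Exon > Intron with the promoter as
TSS ± 1 kb strand-aware; a DMR spanning several feature classes of its
assigned gene gets a compound label ("Exon/Intron"); DMRs outside every
gene are "Intergenic" with the nearest gene by edge distance. Opposite-
strand CpGs are not collapsed.

# Multiblock sparse PLS-DA

The integration couples two blocks — candidate-gene FPKM and per-DMR mean
methylation (feature-mean imputed, z-scored, zero-variance features
dropped) — with a centred class-indicator dummy matrix through a fully
connected design. Per component, each block's loading is iteratively
updated as the design-weighted sum of cross-covariances with the other
blocks' scores and the outcome score, soft-thresholded so that exactly
`keepX` entries stay nonzero, and unit-normalized; blocks are deflated by
regression on their own scores between the two components. With
`keepX = all` the procedure is dense multiblock PLS-DA and its first
component matches a brute-force eigendecomposition of $X^\top Y Y^\top X$
on one block (tested). The requested two components are capped at the data
rank for degenerate inputs.

Discriminant performance is the Mann–Whitney AUC of each block's scores
against sex, with a two-sided normal-approximation p-value (tie-corrected);
for perfect 6-vs-6 separation this gives p = 0.0039. The two components
are combined by averaging their score vectors before the AUC — the
combination rule is not dictated by the method and is recorded here as the
package's choice. After variable selection, DMRs pair with their
annotation-assigned genes; pairs where both sides were selected define the
overlap-restricted refit, which is evaluated the same way, and only the
paired features (not all DMR features) enter the refit.

# Synthetic data: what it emulates and what it does not

The generator reproduces the post-quantification products of the study
design: 12 samples (6 per sex) with ages drawn from the reported cohort
means; NB counts (per-gene dispersion uniform on [0.05, 0.3], library
size factors log-uniform on [0.7, 1.4]) with a fraction of genes carrying
a sex log2 fold-change split symmetrically (±lfc/2) so depth stays
sex-balanced; beta-binomial methylation (mean-dispersion
parameterization, Beta(μ(1−φ)/φ, (1−μ)(1−φ)/φ), φ = 0 binomial) with
context baselines CG 0.6, CHG 0.2, CHH 0.15 calibrated to the reported
context means; planted DMRs as dense site runs whose sex means differ by
the drawn delta, placed non-overlapping (≥1 kb apart), a configurable
fraction inside planted genes; five co-expression modules (one per-sex
specific, three shared) as a latent factor model; and fat-percentage
traits generated from module factors at a stated correlation.

Three generator design points deserve note, all aimed at making the
planted truth *identifiable* rather than easy:

* Module factors are drawn orthogonal within each sex. Two independent
  Gaussian factors over six samples are often strongly correlated by
  chance, which merges planted modules and makes "which module is which"
  ill-posed.
* Every gene (module or background) carries a per-gene biological residual
  (sd uniform on [0.1, 0.6]) on top of counting noise, and each module
  gene's factor loading is calibrated against its own noise so that every
  within-module pair has the configured correlation. If module genes
  formed a separable low-noise class they would spuriously co-cluster in
  the sex where their factor is silent — via the shared library-size
  component that survives FPKM normalization — and contaminate the DcoExp
  null.
* Default genome: 3 chromosomes × 10 Mb; large enough for interval logic,
  small enough for seconds-scale tests.

What the generator does **not** model: read-level artefacts, bisulfite
conversion error, the half-sib family structure of the real cohort,
GC/length biases, and compositional effects beyond library size. Passing
tests therefore validate the statistical machinery on clean generative
assumptions; they do not certify performance on real WGBS/RNA-seq with
batch structure.

# Problem sizes and numerical choices

The validation suite runs at deliberately modest scales chosen once:
networks on 400–800 genes, methylation on 2000–4000 sites, 20 simulation
seeds for the DcoExp property, one seed elsewhere. Tolerances follow the
Monte-Carlo error of those sizes. Ties in the k-means reallocation keep
the current module; hierarchical clustering and k-means refinement are
deterministic given the input, and the pipeline fans a single global seed
out to per-stage seeds by hashing stage names, so partial reruns
reproduce.

# Known limitations

* The DML variance treats the smoothing window's sites as sharing one
  dispersion (the centre site's); strongly heterogeneous dispersion within
  a window biases the statistic slightly.
* The DcoExp decision ("no significant counterpart") inherits the
  multiplicity behaviour of BH across all module pairs: with many small
  noise modules an occasional spurious counterpart persists even with the
  restricted universe (observed in roughly 1 in 7 simulated datasets at
  the validation scale; the corresponding acceptance property is reported
  as measured).
* Enrichment uses plain hypergeometric over-representation with
  user-supplied term tables; no GO graph propagation or semantic
  similarity.
* QTL enrichment backgrounds are the whole database by default; per-type
  backgrounds are an option.
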