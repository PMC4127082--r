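---
title: "Methods: integrated GWAS, coexpression, and cis-eSNP analysis"
author: "ariNet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated GWAS, coexpression, and cis-eSNP analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ariNet implements an integrated genomic analysis of a binary trait in an
ethnically structured cohort: per-group case/control association scans,
cross-group meta-analysis, weighted gene coexpression network analysis of
an expression-profiled subset, cis-eSNP mapping, and the statistics that
connect the three layers. This vignette is the package's account of the
models, the tunable parameters, and the design choices that were
genuinely open.

## The association scan

Within each ancestry group we fit the null logistic model

$$\mathrm{logit}\, P(y_i = 1) = \alpha + \gamma_1\,\mathrm{age}_i +
\gamma_2\,\mathrm{sex}_i + \sum_k \delta_k \mathrm{PC}_{ik}$$

once, and test each SNP's additive dosage $g$ with the efficient score
statistic

$$z = \frac{g^\top (y - \hat\mu)}{\sqrt{g^\top W g - g^\top W X
(X^\top W X)^{-1} X^\top W g}},\qquad W = \mathrm{diag}\{\hat\mu_i
(1 - \hat\mu_i)\},$$

which is standard normal under the null and signed by the
effect-allele direction. A score test was chosen over per-SNP
Wald/likelihood fits because it requires a single null fit per group
(the whole genome scan is then three matrix products), is the classical
construction behind standard case/control scan software, and honours
the "standard normal under the null, captures the direction" contract
without asserting any particular implementation's internals. SNPs with
a single genotype class, or with numerically zero score variance, are
flagged degenerate, carry no statistic, and are excluded from inflation
estimates.

Principal components are computed per group from dosages standardized
by mean $2\hat p$ and standard deviation $\sqrt{2\hat p(1-\hat p)}$,
the usual treatment that weights SNPs by inverse binomial variance;
monomorphic SNPs are dropped. The default of 10 components is the
common convention for stratification control; the count is exposed
because no single value is canonical.

## Meta-analysis and genomic control

Group statistics are combined with sample-size weights,

$$z_{\mathrm{meta}} = \frac{\sum_i w_i z_i}{\sqrt{\sum_i w_i^2}},
\qquad w_i = \sqrt{n_i},$$

the appropriate weighting for score-type statistics when per-group
effect sizes and standard errors are not retained (inverse-variance
weighting needs both). Allele orientation is reconciled by flipping
(negating $z$) where effect and other allele are swapped; records whose
alleles cannot be reconciled are dropped with a warning count. With one
group the combination is the identity.

The genomic inflation factor is
$\lambda = \mathrm{median}\{F^{-1}_{\chi^2_1}(1 - p_j)\} /
F^{-1}_{\chi^2_1}(0.5)$, with the null median
$F^{-1}_{\chi^2_1}(0.5) \approx 0.4549$; $\lambda = 1$ exactly when all
$p = 0.5$.

Loci are selected at $p \le 10^{-6}$ (inclusive) and tiered genome-wide
at $p \le 5\times10^{-8}$ (inclusive — a locus at exactly
$5.0\times10^{-8}$ is genome-wide significant). Independence is declared
by greedy positional clumping within a 500 kb window: the best remaining
p value indexes a locus and absorbs retained SNPs within the window.
LD-aware clumping is deliberately out of scope; ties in p are broken by
SNP id so the output is invariant to input order.

## Coexpression network and modules

Expression preprocessing is log2 transformation (strictly positive
input required) followed by quantile normalization across samples via
`limma::normalizeQuantiles`; afterwards every sample carries an
identical multiset of values and within-sample ranks are preserved.
Simulated expression is generated directly on the normalized scale, so
the pipeline applies only the quantile step there
(`log2Transform = FALSE`).

The network is unsigned: $a_{ij} = |\mathrm{cor}(g_i, g_j)|^\beta$,
Pearson by default. Unsigned power-transformed correlation is the
canonical default of weighted coexpression analysis; nothing in the
workflow depends on a signed variant. The soft power $\beta$ is the
smallest candidate whose connectivity distribution fits scale-free
topology with $R^2 \ge 0.8$ (log-log regression of binned frequency on
mean connectivity, $R^2$ signed by the slope so increasing trends never
qualify) subject to a mean-connectivity floor of 1, falling back to 6
when no candidate qualifies. The floor guards against a degenerate
failure mode: at extreme powers any network decays toward zero
connectivity, whose binned distribution looks spuriously scale-free —
the same artifact that randomized data show — while no longer
supporting module detection.

Topological overlap is

$$\mathrm{TOM}_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 -
a_{ij}},\qquad l_{ij} = \sum_{u \ne i,j} a_{iu}a_{uj},\qquad
k_i = \sum_{j \ne i} a_{ij},$$

with unit diagonal. The implementation is three matrix operations; the
test suite pins it to an exhaustive triple-loop oracle at $10^{-12}$ on
all networks up to 15 genes.

Module detection is a simplified branch cut in the spirit of dynamic
tree cutting: average-linkage clustering of $1 - \mathrm{TOM}$, a
static cut at height 0.99 on the dissimilarity scale, iterative merging
of branches smaller than `minModuleSize` (default 30) into their
nearest branch when the mean dissimilarity stays below the cut height
(otherwise grey), and a cohesion filter requiring a kept branch's mean
within-branch dissimilarity to undercut its mean dissimilarity to the
remaining genes by at least 0.05. Two choices deserve comment:

* **Absolute cut height, not a merge-height quantile.** A quantile of
  the merge heights tracks whatever part of the tree dominates the
  height distribution — in data with a large uncorrelated background
  that is the background, and the resulting cut sits above the joins
  between real modules and background, collapsing everything into one
  branch. The absolute 0.99 cut on the $1-\mathrm{TOM}$ scale is the
  standard static cut for TOM dendrograms and separates the regimes
  cleanly: coexpressed branches complete far below it, background
  merges sit above it.
* **The cohesion filter.** A pure height cut will certify any branch
  that happens to complete below the cut, including chance aggregates
  of uncorrelated genes. Requiring separation from the rest of the tree
  is the minimal branch-shape criterion that leaves independent-noise
  genes grey while never rejecting a genuinely coherent module (a
  single all-gene module has no "rest" and is kept).

Modules are renamed by descending size along a fixed color sequence
(turquoise, blue, brown, ...); grey is reserved for unassigned genes.
The colors are reproducible rank labels only.

Randomization controls mirror the two standard negative controls:
`labels` permutes the gene-id/profile mapping (values untouched),
`values` permutes each gene's values independently across samples,
destroying inter-gene correlation. Scale-free fit comparisons between
original and randomized networks are made at the power selected for the
original network: at very high powers even noise networks can produce a
high fit index with near-zero connectivity, so a max-over-powers
comparison would be misleading.

## cis-eSNP mapping

SNP-gene pairs are formed within an inclusive 1 Mb window measured from
the SNP position to the gene-body interval (distance 0 inside; the gene
body rather than the TSS because the contract is "near the gene", and
the choice is configurable). SNP maps are 1-based; BED gene input is
0-based half-open and converted on read; boundary behaviour is
property-tested.

The default association statistic is the 1-df additive score form
$n r^2$, chi-square under the null, with a 2-df genotype-class option
(`test = "genotypic"`). The 1-df additive model is the field default
for expression-genotype scans; the reported chi-squares in cohort
studies rarely state their df, so no equivalence with any particular
published value is asserted. Constant expression yields statistic 0 and
$p = 1$; degenerate genotypes are flagged untested.

A pair is called an eSNP iff its Benjamini-Hochberg $q \le 0.10$ *and*
$p \le 10^{-4}$, both inclusive, with $q$ computed over all tested
pairs.

## Integration statistics

A locus *tags* a module if the module contains a gene whose body lies
within 250 kb (inclusive) of the locus index SNP; the locus position is
the index SNP, not the clump extent, because the tagging rule references
a single locus position. One locus may tag several modules.

**Tagging enrichment.** For module $M$ with observed tag count $o$
among $n$ loci, the null probability $p_0$ is the fraction of all
tested SNP positions within 250 kb of any $M$ gene, the expectation is
$p_0 n$, fold $= o / (p_0 n)$, and the p value is the upper binomial
tail $P(X \ge o)$, $X \sim \mathrm{Bin}(n, p_0)$. This null makes the
fold ratio exactly the observed/expected ratio and the test auditable
against direct binomial summation; a published fold alone does not pin
down its null, so the construction is stated rather than assumed.

**Disease-eSNP enrichment.** A gene *carries a disease eSNP* iff some
called eSNP pair targets it and that SNP's disease-association p value
is at most 0.01. For each candidate module (those tagged by at least
one locus) the one-sided Fisher's exact test — the hypergeometric upper
tail — is computed on the 2×2 table of module membership × carriage
over the expression-profiled gene universe (the genes with coordinates
on the platform: eSNPs are only observable there), with fold the ratio
of carrier fractions and BH adjustment across candidates. All
enrichment tests are one-sided because only enrichment is of interest.

**Gene-set enrichment** uses the same hypergeometric machinery over a
user-supplied GMT collection (sets intersected with the universe
first); a packaged generator builds a synthetic collection with one
set concentrated in the planted disease module plus random decoys.

## The synthetic-data generator

The generator emulates the study design the pipeline targets: a
multi-center, three-ancestry-group cohort of several thousand subjects
with a roughly 48% case fraction, and an expression-profiled subset of
one cohort. The demo defaults are: 2 groups × 500 subjects, 2000 SNPs
on one 100 Mb chromosome (50 kb spacing), $F_{st} = 0.1$, exchangeable
latent LD $\rho = 0.3$ in 10-SNP blocks, 500 genes (5 planted modules
of 50; the remainder independent background), target within-module
correlation 0.7, 100 expression samples, 10 planted cis-eSNPs
($\beta = 2$ per allele) in the first module, 15 causal SNPs (OR 1.8
per allele) including all planted eSNP SNPs, and baseline prevalence
0.48.

Specific choices:

* **Genotypes.** Ancestral MAF uniform on (0.05, 0.5); group
  frequencies Balding-Nichols,
  $p_g \sim \mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, so the across-SNP
  variance of group frequencies is $F\,p(1-p)$. Haplotypes come from a
  block-wise latent Gaussian copula thresholded at $\Phi^{-1}(p_g)$;
  two independent haplotypes per subject give Hardy-Weinberg dosages.
  The LD model is deliberately simple — block structure is enough to
  exercise clumping and calibration; realistic recombination maps are a
  non-goal.
* **Planted effects at common variants.** The ancestral MAF of causal
  SNPs is drawn from [0.2, 0.5]. Planted GWAS loci are meant to model
  detectable common-variant associations; a rare planted variant would
  make every downstream recovery property a coin flip at desk-scale
  sample sizes.
* **Phenotype.** Logistic with intercept $\mathrm{logit}(0.48)$;
  per-allele effects $\log(\mathrm{OR})$ and age/sex effects enter
  *centered*, so the target prevalence remains the approximate marginal
  case fraction even with non-zero effects. Age is uniform on [5, 60]
  years, sex Bernoulli(0.5), with small default effects (0.01 per year,
  0.2 for sex) mirroring the standard adjustment set.
* **Expression.** Each module has a latent eigengene; member genes are
  $u_i L e_m + \sigma \varepsilon$ with per-gene loading multipliers
  $u_i \sim \mathrm{Unif}(0.2, 1)$ giving hub structure (real
  coexpression modules have heterogeneous connectivity, and without it
  no soft power shows scale-free topology), and the base loading $L$
  calibrated by root-finding so the population mean within-module
  correlation equals the target. With $\sigma = 0$ genes equal the
  eigengene. eSNP effects add $\beta \times$ dosage. Genes sit at fixed
  spacing on the same chromosome, so every planted pair is well inside
  the 1 Mb window and the 250 kb tagging rule is exactly testable.
* **Seeding.** One master seed; every stage derives its own stream
  through a fixed affine map, so outputs are bit-identical under an
  identical configuration and stages are individually reproducible.

What the generator does *not* emulate: array-specific noise,
imputation uncertainty, realistic LD decay, trans effects, covariate-
or batch-driven expression structure, and overlapping or nested
modules. Passing tests therefore demonstrate correctness of the
statistics and recoverability of planted structure under the stated
model — not performance on real cohort data.

## Problem sizes and numerical choices

The test suite and the acceptance script use the demo configuration for
planted-truth recovery; calibration checks use single-group nulls of
400-500 subjects with at least 10,000 independent SNP tests in total
for the association scan (λ and type-I error; pooled over replicate
scans, because tests within one scan share the phenotype vector and
the rejection-fraction uncertainty must come from the replicate
spread) and 50 replicates of a 100 × 100-SNP/30-gene null for the
realized eSNP FDP; the randomized-expression negative control uses 20
replicates. These sizes were chosen as the smallest at which the
sampling noise of the calibration quantities is clearly inside the
asserted bands.

Numerical details: score variances below $10^{-10}$ are treated as
degenerate; the scale-free fit needs at least 3 populated connectivity
bins; hypergeometric tails are computed on the log scale via
`phyper`; BH goes through `stats::p.adjust` (the hand-coded step-up
exists only as a test oracle); module-label ties in size are broken by
first gene index; the dendrogram cut handles the all-identical
(height 0) and all-singleton (no merge below cut) limits explicitly.

## Known limitations

* Meta-analysis supports sample-size weights only; inverse-variance
  weighting would require per-group effect estimates that the score
  scan does not produce.
* Clumping is positional, not LD-aware.
* The eSNP scan is unadjusted (no expression covariates or latent
  factors); with the simulated data there is nothing to adjust for.
* Module merging by eigengene correlation and module preservation
  statistics are out of scope.
* The cohort characteristics table bundled with the package records
  only marginal counts of the emulated study design; all summaries
  derived from it are column sums of that table.
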