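# ariNet

Integrated GWAS, coexpression network, and cis-eSNP analysis for
case-control traits, with a synthetic-data generator that plants a
recoverable ground truth at every stage.

## The problem

Genome-wide association studies of complex inflammatory traits such as
allergic rhinitis typically yield a handful of significant loci whose
biology is opaque: the associated variants often sit in intergenic
regions, and single-variant statistics ignore most of the signal in the
data. One remedy is to interpret GWAS results through gene expression
measured in a disease-relevant tissue from the *same* genotyped
subjects: build a weighted gene coexpression network, partition it into
modules, map cis expression-SNPs (eSNPs), and then ask which modules
are (a) tagged by GWAS loci and (b) enriched for eSNPs that are also
associated with the disease. A module supported by both lines of
evidence is a candidate disease module, and gene-set enrichment of its
members points at pathways.

ariNet implements that workflow as a tested, reusable R package for
statistical geneticists and systems biologists:

* **GWAS** — per-ancestry-group logistic *score* test on additive
  dosage, adjusted for age, sex and within-group genotype principal
  components. The statistic is standard normal under the null and
  signed by the effect-allele direction:
  `z = U / sqrt(V)`, `U = gᵀ(y − μ̂)`,
  `V = gᵀWg − gᵀWX (XᵀWX)⁻¹ XᵀWg`.
* **Meta-analysis** — sample-size-weighted Z combination across groups,
  `z_meta = Σ wᵢ zᵢ / sqrt(Σ wᵢ²)` with `wᵢ = sqrt(nᵢ)`, plus the
  genomic inflation factor
  `λ = median(χ²₁(1 − p)) / qchisq(0.5, 1)` and greedy positional
  clumping of loci (retained at `p ≤ 1e-6`, genome-wide at
  `p ≤ 5e-8`, both inclusive).
* **Coexpression** — unsigned weighted network `a_ij = |cor|^β` with β
  chosen for approximate scale-free topology, topological overlap
  `TOM_ij = (l_ij + a_ij) / (min(kᵢ, kⱼ) + 1 − a_ij)`, average-linkage
  clustering of `1 − TOM`, and a dendrogram cut with small-branch
  merging and a cohesion filter; modules get size-ranked color labels,
  grey = unassigned. Label- and value-randomization controls included.
* **cis-eSNP** — SNP-gene pairs within an inclusive 1 Mb window; 1-df
  additive score statistic `n·r²` (2-df genotype-class option); a pair
  is an eSNP iff its Benjamini-Hochberg `q ≤ 0.10` **and**
  `p ≤ 1e-4`.
* **Integration** — a locus tags a module if the module has a gene
  within 250 kb of the index SNP; tagging enrichment against an exact
  binomial null with a SNP-position-based background; Fisher's exact
  (hypergeometric tail) enrichment of modules for disease-associated
  eSNPs (`disease p ≤ 0.01`); generic GMT gene-set enrichment.
* **Synthetic data** — Balding-Nichols population structure, block-LD
  genotypes, a logistic binary trait at 48% prevalence, and a
  factor-model expression matrix with planted modules, hub structure,
  and cis-eSNP effects whose SNPs also carry phenotype effects (the
  planted disease module).

## Worked example

```r
library(ariNet)

cfg <- simulationConfig(seed = 7L)   # the demo study
geno  <- simulateGenotypes(cfg)
pheno <- simulatePhenotype(geno, cfg)
sim   <- simulateExpression(geno, cfg)

assoc <- associationScan(geno, pheno)
meta  <- metaAnalyze(assoc)
genomicInflation(meta$p_meta)$lambda
#> [1] 1.043752

(loci <- selectLoci(meta))[, c("index_snp", "p", "tier")]
#>   index_snp            p        tier
#> 1   snp0004 9.835578e-10 genome_wide
#> 2   snp0016 2.673351e-08 genome_wide
#> 3   snp0028 3.849558e-11 genome_wide
#> 4   snp1046 2.187251e-08 genome_wide

expr <- preprocessExpression(sim$expression, log2Transform = FALSE)
soft <- pickSoftThreshold(expr)
net  <- computeTom(expr, soft$power)
mods <- detectModules(net)
mods
#> ModuleAssignment
#>   genes: 500; modules (non-grey): 5; cut height: 0.9900
#>   sizes: turquoise=50, blue=49, brown=48, yellow=48, green=46, grey=259

pairs <- cisPairs(snpRanges(geno), geneRanges(sim$expression))
esnps <- callEsnps(esnpScan(geno, expr, pairs))
sum(esnps$is_esnp)
#> [1] 10

tags <- tagModules(loci, mods, geneRanges(sim$expression))
enr  <- arEsnpModuleEnrichment(esnps, meta, mods,
                               candidates = unique(tags$module))
enr[, c("module", "observed", "expected", "fold", "p", "q")]
#>   module observed expected     fold            p            q
#> 1  brown        8     0.96 8.333333 1.595792e-07 1.595792e-07
```

λ near 1 says stratification is controlled; four loci reach genome-wide
significance; five modules are recovered from the expression matrix
(the rest of the genes stay grey); three of the loci tag the brown
module, which carries 8 disease-associated eSNP genes against an
expectation of about 1 — an 8.3-fold enrichment identifying it as the
disease module, which is exactly where the generator planted its
cis effects. `runPipeline(cfg, outDir)` performs all of the above plus
gene-set enrichment in one call, writes each stage as TSV, and records
a manifest; reruns are byte-identical.

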