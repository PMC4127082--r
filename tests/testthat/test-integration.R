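makeGenes <- function(start, labels, width = 1000L) {
    gr <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start, width = width))
    names(gr) <- names(labels)
    gr
}

test_that("module tagging applies the inclusive 250 kb boundary", {
    labels <- c(g1 = "brown", g2 = "brown", g3 = "pink", g4 = "grey")
    ## locus at 1,000,000; gene bodies at varying distances
    genes <- makeGenes(c(1200000, 2000000, 1100000, 1000100), labels)
    loci <- data.frame(index_snp = "rs1", chrom = "chr1", pos = 1e6,
                       p = 1e-8, tier = "genome_wide")
    tags <- tagModules(loci, labels, genes)
    ## brown witnessed by g1 (200 kb away, inside); pink by g3; grey never
    expect_setequal(tags$module, c("brown", "pink"))
    expect_equal(tags$witness_gene[tags$module == "brown"], "g1")
    expect_equal(tags$distance_bp[tags$module == "brown"], 200000)
    ## tagged at exactly the window, missed one base beyond it
    genes2 <- makeGenes(1250000, c(g1 = "brown"))
    expect_equal(nrow(tagModules(loci, c(g1 = "brown"), genes2)), 1L)
    genes3 <- makeGenes(1250001, c(g1 = "brown"))
    expect_equal(nrow(tagModules(loci, c(g1 = "brown"), genes3)), 0L)
})

test_that("one locus can tag several modules and missing genes warn", {
    labels <- c(g1 = "brown", g2 = "pink", g3 = "magenta")
    genes <- makeGenes(c(1.05e6, 1.10e6, 9e6), labels[1:3])[1:2]
    loci <- data.frame(index_snp = "rs1", chrom = "chr1", pos = 1e6,
                       p = 1e-7, tier = "suggestive")
    expect_warning(tags <- tagModules(loci, labels, genes),
                   "lack coordinates")
    expect_equal(sort(tags$module), c("brown", "pink"))
})

test_that("tagging enrichment reproduces the fold arithmetic and binomial tail", {
    ## 22 loci, 6 tagging the module; background chosen so that 6 of 88
    ## SNP positions lie within the window: p0 = 6/88, expected = 1.5,
    ## fold = 4.0
    labels <- c(gA = "brown")
    genes <- makeGenes(5e6, labels)
    nearPos <- seq(4.8e6, by = 5e4, length.out = 6)     # within 250 kb
    farPos <- seq(2e7, by = 1e6, length.out = 82)       # far away
    snpMap <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(nearPos, farPos), width = 1L))
    names(snpMap) <- sprintf("rs%03d", seq_along(snpMap))
    loci <- data.frame(index_snp = sprintf("L%02d", 1:22), chrom = "chr1",
                       pos = c(nearPos[1:6], farPos[1:16]),
                       p = 1e-7, tier = "suggestive")
    tags <- tagModules(loci, labels, genes)
    expect_equal(nrow(tags), 6L)
    enr <- taggingEnrichment(tags, loci, labels, genes, snpMap)
    expect_equal(enr$observed, 6L)
    expect_equal(enr$expected, 22 * 6 / 88)
    expect_equal(enr$fold, 4.0)
    p0 <- 6 / 88
    oracle <- sum(dbinom(6:22, 22, p0))
    expect_equal(enr$p, oracle, tolerance = 1e-12)

    ## observed = expected -> fold 1; observed 0 -> fold 0, p 1
    enr0 <- taggingEnrichment(tags[0, ], loci, labels, genes, snpMap,
                              candidates = "brown")
    expect_equal(enr0$observed, 0L)
    expect_equal(enr0$fold, 0)
    expect_equal(enr0$p, 1)
})

test_that("an all-covering module has unit fold when all loci tag it", {
    labels <- c(gA = "brown")
    genes <- makeGenes(5e6, labels)
    snpMap <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(seq(4.9e6, by = 1e4, length.out = 10),
                         width = 1L))
    names(snpMap) <- sprintf("rs%02d", 1:10)
    loci <- data.frame(index_snp = sprintf("L%d", 1:10), chrom = "chr1",
                       pos = GenomicRanges::start(snpMap), p = 1e-7,
                       tier = "suggestive")
    tags <- tagModules(loci, labels, genes)
    enr <- taggingEnrichment(tags, loci, labels, genes, snpMap)
    expect_equal(enr$fold, 1)        # p0 = 1, observed = expected = 10
})

test_that("module eSNP enrichment matches the hypergeometric oracle", {
    ## 1000-gene universe; module of 100 with 30 carriers; 100 carriers
    ## overall -> fold (30/100)/(100/1000) = 3.0
    labels <- setNames(rep(c("brown", "grey"), c(100, 900)),
                       sprintf("g%04d", 1:1000))
    carriers <- c(sprintf("g%04d", 1:30), sprintf("g%04d", 101:170))
    esnps <- data.frame(snp_id = sprintf("s%03d", seq_along(carriers)),
                        gene_id = carriers, distance_bp = 0,
                        stat = 25, df = 1, p = 1e-6, q = 1e-4,
                        tested = TRUE, is_esnp = TRUE)
    gwas <- data.frame(snp_id = esnps$snp_id, p_meta = 0.001)
    enr <- arEsnpModuleEnrichment(esnps, gwas, labels,
                                  candidates = "brown")
    expect_equal(enr$observed, 30L)
    expect_equal(enr$fold, 3.0)
    expect_equal(enr$n11 + enr$n12 + enr$n21 + enr$n22, 1000)
    expect_equal(enr$p, hyperTailOracle(30, 100, 1000, 100),
                 tolerance = 1e-12)
    ## disease filter: SNPs above the nominal threshold do not count
    gwas2 <- gwas; gwas2$p_meta <- 0.5
    enr2 <- arEsnpModuleEnrichment(esnps, gwas2, labels,
                                   candidates = "brown")
    expect_equal(enr2$observed, 0L)
    expect_equal(enr2$fold, 0)
    expect_equal(enr2$p, 1)
})

test_that("fold enrichment is invariant to doubling the table margins", {
    labels1 <- setNames(rep(c("m", "grey"), c(50, 450)),
                        sprintf("a%03d", 1:500))
    labels2 <- setNames(rep(c("m", "grey"), c(100, 900)),
                        sprintf("b%04d", 1:1000))
    mkEsnps <- function(genes) data.frame(
        snp_id = sprintf("s%s", genes), gene_id = genes, distance_bp = 0,
        stat = 25, df = 1, p = 1e-6, q = 1e-4, tested = TRUE,
        is_esnp = TRUE)
    car1 <- c(sprintf("a%03d", 1:10), sprintf("a%03d", 51:90))
    car2 <- c(sprintf("b%04d", 1:20), sprintf("b%04d", 101:180))
    gw <- function(e) data.frame(snp_id = e$snp_id, p_meta = 1e-3)
    e1 <- mkEsnps(car1); e2 <- mkEsnps(car2)
    f1 <- arEsnpModuleEnrichment(e1, gw(e1), labels1, candidates = "m")$fold
    f2 <- arEsnpModuleEnrichment(e2, gw(e2), labels2, candidates = "m")$fold
    expect_equal(f1, f2)
})

test_that("the exact-test p equals exhaustive summation on small tables", {
    set.seed(71)
    for (i in 1:200) {
        N <- sample(2:50, 1)
        K <- sample.int(N, 1)
        n <- sample.int(N, 1)
        a <- sample(0:min(K, n), 1)
        expect_equal(ariNet:::.hyperUpperTail(a, K, N, n),
                     hyperTailOracle(a, K, N, n), tolerance = 1e-12)
    }
    ## and matches fisher.test's one-sided p on a spot-check
    tab <- matrix(c(8, 12, 2, 78), 2, 2)
    expect_equal(ariNet:::.hyperUpperTail(8, 10, 100, 20),
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
})

test_that("BH adjustment matches the hand-coded step-up", {
    expect_equal(bhAdjust(0.03), 0.03)
    expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    set.seed(73)
    p <- runif(200)^2
    expect_equal(bhAdjust(p), bhOracle(p), tolerance = 1e-12)
    expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("the planted disease module wins the enrichment ranking end-to-end", {
    d <- demoData()
    pairs <- cisPairs(snpRanges(d$geno), geneRanges(d$exprRaw))
    esnps <- callEsnps(esnpScan(d$geno, d$expr, pairs))
    assoc <- associationScan(d$geno, d$pheno)
    meta <- metaAnalyze(assoc)
    loci <- selectLoci(meta)
    expect_gt(nrow(loci), 0)
    genes <- geneRanges(d$exprRaw)
    tags <- tagModules(loci, d$mods, genes)
    expect_gt(nrow(tags), 0)
    enr <- arEsnpModuleEnrichment(esnps, meta, d$mods,
                                  candidates = unique(tags$module))
    ## identify the detected module matching the planted disease module
    truth <- plantedModules(d$truth)
    diseaseGenes <- names(truth)[truth == diseaseModule(d$truth)]
    detected <- moduleLabels(d$mods)[diseaseGenes]
    dmod <- names(sort(table(detected[detected != "grey"]),
                       decreasing = TRUE))[1]
    expect_true(dmod %in% enr$module)
    expect_equal(enr$module[which.min(enr$q)], dmod)
})

test_that("randomized expression removes the disease-module signal", {
    d <- demoData()
    assoc <- associationScan(d$geno, d$pheno)
    meta <- metaAnalyze(assoc)
    truth <- plantedModules(d$truth)
    pairs <- cisPairs(snpRanges(d$geno), geneRanges(d$exprRaw))
    qs <- vapply(1:3, function(s) {
        r <- randomizeExpression(d$exprRaw, "values", seed = 100L + s)
        esnps <- callEsnps(esnpScan(d$geno, r, pairs))
        enr <- arEsnpModuleEnrichment(esnps, meta, truth,
            candidates = setdiff(unique(truth), "background"))
        enr$q[enr$module == diseaseModule(d$truth)]
    }, 0)
    expect_true(all(qs > 0.05))
})
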