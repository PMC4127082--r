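test_that("invalid configurations are rejected with the field named", {
    expect_error(simulationConfig(mafRange = c(0, 0.5)), "mafRange")
    expect_error(simulationConfig(fst = 1), "fst")
    expect_error(simulationConfig(ldRho = -0.1), "ldRho")
    expect_error(simulationConfig(moduleCor = 1.2), "moduleCor")
    expect_error(simulationConfig(causalOr = 0), "causalOr")
    expect_error(simulationConfig(baselinePrevalence = 0), "baselinePrevalence")
    expect_error(simulationConfig(moduleSizes = rep(200L, 5L)), "moduleSizes")
    expect_error(simulationConfig(nCausalSnps = 5L, nCisEsnps = 10L),
                 "nCausalSnps")
})

test_that("the seed fully determines all simulated outputs", {
    cfg <- simulationConfig(nSubjectsPerGroup = 60L, nSnps = 120L,
                            nGenes = 80L, moduleSizes = rep(15L, 5L),
                            nExpressionSamples = 30L, nCisEsnps = 3L,
                            nCausalSnps = 5L, seed = 9L)
    g1 <- simulateGenotypes(cfg); g2 <- simulateGenotypes(cfg)
    expect_identical(dosages(g1), dosages(g2))
    p1 <- simulatePhenotype(g1, cfg); p2 <- simulatePhenotype(g2, cfg)
    expect_identical(p1, p2)
    e1 <- simulateExpression(g1, cfg); e2 <- simulateExpression(g2, cfg)
    expect_identical(exprValues(e1$expression), exprValues(e2$expression))
    expect_identical(esnpPairs(e1$truth), esnpPairs(e2$truth))
})

test_that("dosages are additive 0/1/2 with config-matched dimensions", {
    cfg <- simulationConfig(nSubjectsPerGroup = 40L, nGroups = 3L,
                            nSnps = 90L, nCausalSnps = 0L,
                            nCisEsnps = 0L, seed = 2L)
    g <- simulateGenotypes(cfg)
    expect_true(all(dosages(g) %in% 0:2))
    expect_equal(dim(dosages(g)), c(90L, 120L))
    expect_equal(unname(table(subjectGroups(g))), rep(40L, 3L),
                 ignore_attr = TRUE)
})

test_that("with no divergence the empirical frequency tracks the drawn MAF", {
    cfg <- simulationConfig(nSubjectsPerGroup = 1000L, nGroups = 1L,
                            nSnps = 200L, fst = 0, ldRho = 0,
                            nCausalSnps = 0L, nCisEsnps = 0L, seed = 4L)
    g <- simulateGenotypes(cfg)
    p <- mcols(snpRanges(g))$ancestralMaf
    phat <- rowMeans(dosages(g)) / 2
    se <- sqrt(p * (1 - p) / (2 * 1000))
    ## 3 binomial SE covers 99.7% of SNPs; none strays far
    expect_gte(mean(abs(phat - p) <= 3 * se), 0.985)
    expect_true(all(abs(phat - p) <= 5 * se))
})

test_that("group frequencies follow the Balding-Nichols moments", {
    cfg <- simulationConfig(nSubjectsPerGroup = 10L, nGroups = 2L,
                            nSnps = 4000L, mafRange = c(0.3, 0.3),
                            fst = 0.1, nCausalSnps = 0L, nCisEsnps = 0L,
                            seed = 6L)
    g <- simulateGenotypes(cfg)
    f <- mcols(snpRanges(g))$freq_group1
    ## Var(p_g) = fst * p * (1 - p) with p = 0.3
    expect_equal(var(f), 0.1 * 0.3 * 0.7, tolerance = 0.08)
    expect_equal(mean(f), 0.3, tolerance = 0.02)
})

test_that("a zero-frequency SNP is monomorphic with all dosages zero", {
    ## MAF at the lower boundary of its range: no alternate allele is
    ## ever drawn and every dosage is 0
    cfg <- simulationConfig(nSubjectsPerGroup = 80L, nGroups = 1L,
                            nSnps = 50L, mafRange = c(1e-12, 1e-12),
                            fst = 0, nCausalSnps = 0L, nCisEsnps = 0L,
                            seed = 8L)
    g <- simulateGenotypes(cfg)
    expect_true(all(dosages(g) == 0))
    ## saturated group frequencies (Balding-Nichols at strong drift)
    ## likewise give monomorphic SNPs
    cfg2 <- simulationConfig(nSubjectsPerGroup = 60L, nGroups = 1L,
                             nSnps = 3000L, mafRange = c(0.01, 0.02),
                             fst = 0.9, nCausalSnps = 0L,
                             nCisEsnps = 0L, seed = 10L)
    g2 <- simulateGenotypes(cfg2)
    f <- mcols(snpRanges(g2))$freq_group1
    if (any(f == 1))
        expect_true(all(dosages(g2)[f == 1, ] == 2))
    if (any(f == 0))
        expect_true(all(dosages(g2)[f == 0, ] == 0))
})

test_that("null phenotype prevalence matches the logistic intercept", {
    for (prev in c(0.5, 0.48)) {
        cfg <- simulationConfig(nSubjectsPerGroup = 2500L, nGroups = 1L,
                                nSnps = 50L, causalOr = 1,
                                ageBeta = 0, sexBeta = 0,
                                nCausalSnps = 0L, nCisEsnps = 0L,
                                baselinePrevalence = prev, seed = 12L)
        g <- simulateGenotypes(cfg)
        ph <- simulatePhenotype(g, cfg)
        se <- sqrt(prev * (1 - prev) / 2500)
        expect_lte(abs(mean(ph$ar_status) - prev), 3 * se)
    }
})

test_that("logistic regression recovers the planted per-allele log odds", {
    cfg <- simulationConfig(nSubjectsPerGroup = 5000L, nGroups = 1L,
                            nSnps = 40L, causalOr = 1.5,
                            nCausalSnps = 1L, nCisEsnps = 0L,
                            ageBeta = 0, sexBeta = 0, seed = 14L)
    g <- simulateGenotypes(cfg)
    ph <- simulatePhenotype(g, cfg)
    snp <- attr(ph, "causalSnpIds")
    fit <- glm(ph$ar_status ~ dosages(g)[snp, ], family = binomial())
    ci <- coef(fit)[2] + c(-1.96, 1.96) * sqrt(vcov(fit)[2, 2])
    expect_gt(log(1.5), ci[1])
    expect_lt(log(1.5), ci[2])
})

test_that("noiseless modules are perfectly correlated", {
    cfg <- simulationConfig(nSubjectsPerGroup = 40L, nGroups = 1L,
                            nSnps = 60L, nGenes = 30L, nModules = 2L,
                            moduleSizes = c(10L, 10L), noiseSd = 0,
                            nCisEsnps = 0L, nCausalSnps = 0L,
                            nExpressionSamples = 20L, seed = 16L)
    g <- simulateGenotypes(cfg)
    e <- exprValues(simulateExpression(g, cfg)$expression)
    cc <- cor(t(e[1:10, ]))
    expect_equal(unname(cc), matrix(1, 10, 10), tolerance = 1e-12)
})

test_that("within-module correlation is calibrated near the target", {
    d <- demoData()
    e <- exprValues(d$exprRaw)
    lab <- plantedModules(d$truth)
    ## exclude eSNP genes, whose dosage term adds variance by design
    m2 <- names(lab)[lab == "module2"]
    cc <- cor(t(e[m2, ]))
    expect_equal(mean(cc[upper.tri(cc)]), d$cfg@moduleCor,
                 tolerance = 0.12)
})

test_that("planted cis effects are recovered by regression on dosage", {
    cfg <- simulationConfig(nSubjectsPerGroup = 200L, nGroups = 1L,
                            nSnps = 100L, nGenes = 60L, nModules = 2L,
                            moduleSizes = c(20L, 20L), esnpBeta = 1,
                            noiseSd = 1, nCisEsnps = 4L, nCausalSnps = 4L,
                            nExpressionSamples = 200L, seed = 18L)
    g <- simulateGenotypes(cfg)
    se <- simulateExpression(g, cfg)
    pairs <- esnpPairs(se$truth)
    covered <- vapply(seq_len(nrow(pairs)), function(i) {
        y <- exprValues(se$expression)[pairs$gene_id[i], ]
        x <- dosages(g)[pairs$snp_id[i], colnames(se$expression)]
        fit <- lm(y ~ x)
        ci <- coef(fit)[2] + c(-1.96, 1.96) * sqrt(vcov(fit)[2, 2])
        ci[1] <= 1 && 1 <= ci[2]
    }, TRUE)
    expect_gte(mean(covered), 3 / 4)
})

test_that("between-module correlations sit at the null sampling scale", {
    d <- demoData()
    e <- exprValues(d$exprRaw)
    lab <- plantedModules(d$truth)
    m1 <- names(lab)[lab == "module2"][1:20]
    m2 <- names(lab)[lab == "module3"][1:20]
    cc <- abs(cor(t(e[m1, ]), t(e[m2, ])))
    ## E|r| under the null is about sqrt(2/pi)/sqrt(n)
    null <- sqrt(2 / pi) / sqrt(ncol(e))
    expect_lt(mean(cc), 3 * null)
})

test_that("the demo plants a disease module backed by causal cis-eSNPs", {
    d <- demoData()
    tr <- d$truth
    pairs <- esnpPairs(tr)
    expect_gte(nrow(pairs), d$cfg@nCisEsnps)
    expect_true(all(pairs$snp_id %in% causalSnpIds(tr)))
    lab <- plantedModules(tr)
    expect_true(all(lab[pairs$gene_id] == diseaseModule(tr)))
    expect_true(all(pairs$distance_bp <= 1e6))
    expect_true(diseaseModule(tr) %in% lab)
})
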