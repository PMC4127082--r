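test_that("preprocessing log2-transforms and quantile-normalizes", {
    ## single sample: log2 only (quantile normalization is the identity)
    m <- matrix(c(8, 2, 16), 3, 1,
                dimnames = list(c("g1", "g2", "g3"), "s1"))
    out <- preprocessExpression(m)
    expect_equal(out["g1", 1], 3)
    ## identical multisets across samples afterwards, ranks preserved
    set.seed(41)
    m <- matrix(2^rnorm(200, 8), 20, 10,
                dimnames = list(sprintf("g%02d", 1:20),
                                sprintf("s%02d", 1:10)))
    out <- preprocessExpression(m)
    sorted <- apply(out, 2L, sort)
    expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
    for (j in 1:10)
        expect_equal(rank(out[, j]), rank(m[, j]))
    ## non-positive entries are refused, naming the offender
    m[2, 3] <- 0
    expect_error(preprocessExpression(m), "g2")
})

test_that("power-1 adjacency equals |correlation| and connectivity is monotone", {
    set.seed(43)
    m <- matrix(rnorm(30 * 12), 30, 12,
                dimnames = list(sprintf("g%02d", 1:30),
                                sprintf("s%02d", 1:12)))
    net1 <- computeTom(m, 1)
    ac <- abs(cor(t(m)))
    expect_equal(adjacencyMatrix(net1)[upper.tri(ac)], ac[upper.tri(ac)],
                 tolerance = 1e-12)
    ## mean connectivity non-increasing in beta
    ks <- vapply(1:6, function(b) mean(connectivity(computeTom(m, b))), 0)
    expect_true(all(diff(ks) <= 0))
})

test_that("soft-threshold selection reaches scale-free fit on demo data", {
    d <- demoData()
    ft <- d$soft$fitTable
    expect_gte(ft$rsq[ft$power == d$soft$power], 0.8)
    expect_error(pickSoftThreshold(matrix(1, 25, 10,
        dimnames = list(sprintf("g%d", 1:25), sprintf("s%d", 1:10)))),
        "constant")
})

test_that("TOM matches its closed forms and the brute-force oracle", {
    ## empty network: zero off-diagonal adjacency
    A0 <- matrix(0, 6, 6)
    t0 <- ariNet:::.tomFromAdjacency(A0)
    expect_equal(t0, diag(6))
    ## clique with unit adjacency: TOM is 1 everywhere
    m <- 5
    A1 <- matrix(1, m, m); diag(A1) <- 0
    t1 <- ariNet:::.tomFromAdjacency(A1)
    expect_equal(t1, matrix(1, m, m))
    ## random 10-gene expression vs triple loop
    set.seed(47)
    e <- matrix(rnorm(10 * 8), 10, 8,
                dimnames = list(sprintf("g%02d", 1:10),
                                sprintf("s%02d", 1:8)))
    net <- computeTom(e, 6)
    A <- abs(cor(t(e)))^6; diag(A) <- 0
    expect_lt(max(abs(tomMatrix(net) - bruteForceTom(A))), 1e-12)
    ## constant gene is refused by name
    e["g03", ] <- 2
    expect_error(computeTom(e, 6), "g03")
    expect_error(computeTom(e[-3, ], 0.5), "at least 1")
})

test_that("TOM equals the brute-force oracle on all sizes up to 15", {
    set.seed(49)
    for (g in 2:15) {
        e <- matrix(rnorm(g * 9), g, 9,
                    dimnames = list(sprintf("g%02d", seq_len(g)),
                                    sprintf("s%02d", 1:9)))
        beta <- sample(c(1, 2, 6), 1L)
        got <- tomMatrix(computeTom(e, beta))
        A <- abs(cor(t(e)))^beta; diag(A) <- 0
        expect_lt(max(abs(got - bruteForceTom(A))), 1e-12)
    }
})

test_that("planted modules are recovered and labels partition the genes", {
    d <- demoData()
    lab <- moduleLabels(d$mods)
    truth <- plantedModules(d$truth)[names(lab)]
    expect_gte(ariIndex(lab, truth), 0.9)
    expect_setequal(names(lab), rownames(tomMatrix(d$net)))
    sz <- moduleSizes(d$mods)
    expect_true(all(sz[names(sz) != "grey"] >= 30))
    if (requireNamespace("mclust", quietly = TRUE))
        expect_equal(ariIndex(lab, truth),
                     mclust::adjustedRandIndex(lab, truth),
                     tolerance = 1e-12)
})

test_that("perfectly correlated genes collapse to a single module", {
    set.seed(53)
    v <- rnorm(20)
    m <- t(sapply(1:40, function(i) 0.5 * i * v + i))
    dimnames(m) <- list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:20))
    net <- computeTom(m, 6)
    mods <- detectModules(net, minModuleSize = 5L)
    expect_equal(unname(table(moduleLabels(mods))["turquoise"]), 40L,
                 ignore_attr = TRUE)
})

test_that("independent-noise genes are left unassigned", {
    set.seed(57)
    m <- matrix(rnorm(200 * 80), 200, 80,
                dimnames = list(sprintf("g%03d", 1:200),
                                sprintf("s%02d", 1:80)))
    mods <- detectModules(computeTom(m, 6))
    expect_gte(mean(moduleLabels(mods) == "grey"), 0.95)
})

test_that("module detection is invariant to gene input order", {
    d <- demoData()
    e <- exprValues(d$expr)[, ]
    set.seed(59)
    idx <- sample(150L)
    sub <- e[1:150, ]
    m1 <- detectModules(computeTom(sub, 6), minModuleSize = 20L)
    m2 <- detectModules(computeTom(sub[idx, ], 6), minModuleSize = 20L)
    l1 <- moduleLabels(m1)
    l2 <- moduleLabels(m2)[names(l1)]
    expect_equal(ariIndex(l1, l2), 1)
    expect_error(detectModules(d$net, minModuleSize = 1L), "at least 2")
})

test_that("label randomization permutes ids and value randomization kills correlation", {
    d <- demoData()
    e <- exprValues(d$exprRaw)
    lab <- randomizeExpression(e, "labels", seed = 7L)
    ## the multiset of per-gene profiles is preserved, the mapping is not
    expect_equal(sort(as.numeric(lab)), sort(as.numeric(e)))
    moved <- rownames(e)[rowSums(lab != e) > 0]
    expect_gt(length(moved), 0)
    ## each relocated profile exists somewhere in the original matrix
    key <- function(m) sort(unname(apply(m, 1L, function(r)
        paste(signif(r, 12), collapse = ","))))
    expect_identical(key(lab), key(e))

    val <- randomizeExpression(e, "values", seed = 7L)
    mod <- names(plantedModules(d$truth))[
        plantedModules(d$truth) == "module2"]
    ccOrig <- abs(cor(t(e[mod, ])))
    ccRand <- abs(cor(t(val[mod, ])))
    null <- sqrt(2 / pi) / sqrt(ncol(e))
    expect_lt(mean(ccRand[upper.tri(ccRand)]), 3 * null)
    expect_gt(mean(ccOrig[upper.tri(ccOrig)]), 0.5)
    expect_error(randomizeExpression(e, "bogus"), "arg")
})

test_that("value randomization degrades the scale-free fit", {
    ## compared at the power the unrandomized network selected (at very
    ## high powers even noise networks can look scale-free, with
    ## near-zero connectivity)
    d <- demoData()
    e <- exprValues(d$expr)
    val <- randomizeExpression(e, "values", seed = 11L)
    ft <- d$soft$fitTable
    fitOrig <- ft$rsq[ft$power == d$soft$power]
    ftRand <- suppressWarnings(pickSoftThreshold(val))$fitTable
    fitRand <- ftRand$rsq[ftRand$power == d$soft$power]
    expect_lt(fitRand, fitOrig - 0.2)
})

test_that("the coexpression pipeline is deterministic", {
    d <- demoData()
    net2 <- computeTom(d$expr, d$soft$power)
    mods2 <- detectModules(net2)
    expect_identical(moduleLabels(mods2), moduleLabels(d$mods))
})
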