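# Shared fixtures, built in code.  The demo study (the generator's
# default configuration) is expensive enough to build once and reuse
# across test files.

.demoCache <- new.env(parent = emptyenv())

demoData <- function(seed = 1L) {
    key <- paste0("demo", seed)
    if (!is.null(.demoCache[[key]]))
        return(.demoCache[[key]])
    cfg <- simulationConfig(seed = seed)
    geno <- simulateGenotypes(cfg)
    pheno <- simulatePhenotype(geno, cfg)
    se <- simulateExpression(geno, cfg)
    expr <- preprocessExpression(se$expression, log2Transform = FALSE)
    st <- pickSoftThreshold(expr)
    net <- computeTom(expr, st$power)
    mods <- detectModules(net)
    out <- list(cfg = cfg, geno = geno, pheno = pheno,
                exprRaw = se$expression, truth = se$truth, expr = expr,
                soft = st, net = net, mods = mods)
    .demoCache[[key]] <- out
    out
}

# Adjusted Rand index between two labelings (closed form from the
# pair-counting contingency table); mclust's implementation is used as
# a cross-check where available.
ariIndex <- function(a, b) {
    tab <- table(a, b)
    n <- sum(tab)
    sumij <- sum(choose(tab, 2))
    sumi <- sum(choose(rowSums(tab), 2))
    sumj <- sum(choose(colSums(tab), 2))
    expected <- sumi * sumj / choose(n, 2)
    maxidx <- (sumi + sumj) / 2
    if (maxidx == expected) return(1)
    (sumij - expected) / (maxidx - expected)
}

# Brute-force TOM oracle: explicit triple loop over the definition.
bruteForceTom <- function(A) {
    m <- nrow(A)
    tom <- matrix(0, m, m)
    k <- rowSums(A) - diag(A)
    for (i in seq_len(m)) for (j in seq_len(m)) {
        if (i == j) { tom[i, j] <- 1; next }
        l <- 0
        for (u in seq_len(m))
            if (u != i && u != j) l <- l + A[i, u] * A[u, j]
        tom[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    }
    tom
}

# Exhaustive hypergeometric upper tail: explicit summation of the
# sampling density over the extreme tables.
hyperTailOracle <- function(a, K, N, n) {
    kk <- a:min(K, n)
    sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Hand-coded Benjamini-Hochberg step-up.
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(m)
    out[o] <- q
    out
}

# Minimal hand-built genotype container for unit tests.
toyGenotypes <- function(dosage, positions = NULL, chrom = "chr1",
                         group = NULL) {
    if (is.null(rownames(dosage)))
        rownames(dosage) <- sprintf("snp%02d", seq_len(nrow(dosage)))
    if (is.null(colnames(dosage)))
        colnames(dosage) <- sprintf("subj%03d", seq_len(ncol(dosage)))
    if (is.null(positions))
        positions <- seq_len(nrow(dosage)) * 1000L
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(positions, width = 1L), ref = "A", alt = "G")
    names(gr) <- rownames(dosage)
    if (is.null(group)) group <- rep("group1", ncol(dosage))
    GenotypeExperiment(dosage, gr, group)
}

toyExpression <- function(mat, start = NULL, width = 1000L,
                          chrom = "chr1") {
    if (is.null(rownames(mat)))
        rownames(mat) <- sprintf("gene%02d", seq_len(nrow(mat)))
    if (is.null(colnames(mat)))
        colnames(mat) <- sprintf("subj%03d", seq_len(ncol(mat)))
    if (is.null(start))
        start <- seq_len(nrow(mat)) * 5000L
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start, width = width))
    names(gr) <- rownames(mat)
    ExpressionExperiment(mat, gr)
}
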