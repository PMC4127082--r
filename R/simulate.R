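## Synthetic-data generator.  Emulates the design of an ethnically
## structured case/control cohort with an expression-profiled subset:
## Balding-Nichols population structure, block LD, a logistic binary
## trait, and a factor-model expression matrix with planted modules and
## planted cis-eSNP effects whose SNPs also affect the trait.

## Deterministic layout and plant plan shared by the phenotype and
## expression stages.  Pure function of (config); its own derived seed
## draws the non-eSNP causal SNPs.
.planTruth <- function(config) {
    nSnps <- config@nSnps
    nGenes <- config@nGenes
    snpPos <- seq_len(nSnps) * config@snpSpacingBp
    genomeLen <- nSnps * config@snpSpacingBp
    geneSpacing <- max(1L, genomeLen %/% nGenes)
    geneStart <- (seq_len(nGenes) - 1L) * geneSpacing + 1L
    geneEnd <- geneStart + config@geneWidthBp - 1L
    snpIds <- .padIds("snp", nSnps)
    geneIds <- .padIds("gene", nGenes)

    ## planted modules occupy contiguous gene-index blocks; the first
    ## module is the disease module
    labels <- rep("background", nGenes)
    idx <- 1L
    for (m in seq_len(config@nModules)) {
        sz <- config@moduleSizes[m]
        labels[idx:(idx + sz - 1L)] <- paste0("module", m)
        idx <- idx + sz
    }
    names(labels) <- geneIds

    ## planted cis-eSNPs: the first nCisEsnps genes of the disease
    ## module, each paired to the SNP nearest its gene body
    k <- config@nCisEsnps
    esnpGene <- integer(0); esnpSnp <- integer(0)
    if (k > 0L) {
        esnpGene <- seq_len(k)
        mid <- (geneStart[esnpGene] + geneEnd[esnpGene]) / 2
        ## nearest unused SNP per gene, so pairs stay distinct even on
        ## dense gene layouts
        avail <- rep(TRUE, nSnps)
        esnpSnp <- vapply(mid, function(p) {
            i <- which(avail)[which.min(abs(snpPos[avail] - p))]
            avail[i] <<- FALSE
            i
        }, 0L)
        dist0 <- .pointIntervalDistance(snpPos[esnpSnp],
                                        geneStart[esnpGene],
                                        geneEnd[esnpGene])
        if (any(dist0 > 1e6))
            stop("cannot place planted eSNP SNPs within 1 Mb of their genes; ",
                 "increase nSnps or shrink the gene layout")
    }

    ## remaining causal SNPs drawn away from the planted eSNP SNPs
    set.seed(.stageSeed(config@seed, "truth"))
    extra <- config@nCausalSnps - k
    pool <- setdiff(seq_len(nSnps), esnpSnp)
    causal <- c(esnpSnp,
                if (extra > 0L) sort(sample(pool, extra)) else integer(0))

    dist <- if (k > 0L)
        .pointIntervalDistance(snpPos[esnpSnp], geneStart[esnpGene],
                               geneEnd[esnpGene]) else numeric(0)
    list(snpIds = snpIds, snpPos = snpPos, geneIds = geneIds,
         geneStart = geneStart, geneEnd = geneEnd,
         moduleLabels = labels,
         esnpPairs = data.frame(snp_id = snpIds[esnpSnp],
                                gene_id = geneIds[esnpGene],
                                beta = rep(config@esnpBeta, k),
                                distance_bp = dist,
                                stringsAsFactors = FALSE),
         causalIdx = causal)
}

#' Simulate genotypes with population structure and LD
#'
#' Draws ancestral minor-allele frequencies uniformly over
#' \code{mafRange}, derives per-group frequencies from the
#' Balding-Nichols model with divergence \code{fst} (group frequency
#' \eqn{p_g \sim \mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)}), and samples
#' two haplotypes per subject through a block-wise latent Gaussian
#' copula: within each block of \code{ldBlockSize} SNPs the latent
#' normals share an exchangeable correlation \code{ldRho}, which induces
#' linkage disequilibrium after thresholding at the group allele
#' frequency.  SNPs are placed every \code{snpSpacingBp} bp along one
#' simulated chromosome.
#'
#' @param config a [SimulationConfig-class].
#' @return A [GenotypeExperiment-class]; \code{rowRanges} carry the SNP
#'   map with ancestral and per-group allele frequencies.
#' @examples
#' geno <- simulateGenotypes(simulationConfig(
#'     nSubjectsPerGroup = 50L, nSnps = 100L, seed = 1L))
#' geno
#' @export
simulateGenotypes <- function(config) {
    validObject(config)
    set.seed(.stageSeed(config@seed, "genotypes"))
    nSnps <- config@nSnps
    nPerGroup <- config@nSubjectsPerGroup
    nGroups <- config@nGroups
    n <- nPerGroup * nGroups

    pAnc <- runif(nSnps, config@mafRange[1], config@mafRange[2])
    ## planted-effect SNPs sit at common variants (as GWAS-detectable
    ## loci do), so planted signals are recoverable at desk scale
    plan <- .planTruth(config)
    if (length(plan$causalIdx)) {
        lo <- max(config@mafRange[1], min(0.2, config@mafRange[2]))
        pAnc[plan$causalIdx] <- runif(length(plan$causalIdx), lo,
                                      config@mafRange[2])
    }
    fst <- config@fst
    groupFreq <- matrix(0, nSnps, nGroups)
    for (g in seq_len(nGroups)) {
        groupFreq[, g] <- if (fst > 0)
            rbeta(nSnps, pAnc * (1 - fst) / fst, (1 - pAnc) * (1 - fst) / fst)
        else pAnc
    }

    nBlocks <- ceiling(nSnps / config@ldBlockSize)
    blockOf <- rep(seq_len(nBlocks), each = config@ldBlockSize)[seq_len(nSnps)]
    rho <- config@ldRho

    drawHaplotypes <- function(freq, nSub) {
        ## latent z = sqrt(rho) * block factor + sqrt(1-rho) * noise
        thr <- qnorm(freq)          # allele carried iff z < threshold
        out <- matrix(0L, nSnps, nSub)
        for (h in 1:2) {
            u <- matrix(rnorm(nBlocks * nSub), nBlocks, nSub)
            e <- matrix(rnorm(nSnps * nSub), nSnps, nSub)
            z <- sqrt(rho) * u[blockOf, , drop = FALSE] + sqrt(1 - rho) * e
            out <- out + (z < thr)
        }
        out
    }

    dosage <- matrix(0L, nSnps, n)
    group <- rep(paste0("group", seq_len(nGroups)), each = nPerGroup)
    for (g in seq_len(nGroups)) {
        cols <- which(group == paste0("group", g))
        dosage[, cols] <- drawHaplotypes(groupFreq[, g], length(cols))
    }
    storage.mode(dosage) <- "integer"

    rownames(dosage) <- plan$snpIds
    colnames(dosage) <- .padIds("subj", n)

    snpMap <- GRanges("chr1", IRanges(start = plan$snpPos, width = 1L),
                      ref = "A", alt = "G",
                      ancestralMaf = pAnc)
    for (g in seq_len(nGroups))
        mcols(snpMap)[[paste0("freq_group", g)]] <- groupFreq[, g]
    names(snpMap) <- plan$snpIds

    GenotypeExperiment(dosage, snpMap, group)
}

#' Simulate a binary phenotype from a logistic model
#'
#' The linear predictor is \code{qlogis(baselinePrevalence)} plus
#' centered per-allele effects \code{log(causalOr)} at the planted causal
#' SNPs and centered age/sex covariate effects; centering keeps the
#' marginal case fraction near the target prevalence.  Age is uniform
#' over \code{ageRange}, sex is Bernoulli(0.5).
#'
#' @param genotypes a [GenotypeExperiment-class] from
#'   [simulateGenotypes()].
#' @param config the same [SimulationConfig-class].
#' @return A data.frame with columns \code{subject}, \code{group},
#'   \code{ar_status} (0/1), \code{age}, \code{sex}; the planted causal
#'   SNP ids are attached as \code{attr(, "causalSnpIds")}.
#' @export
simulatePhenotype <- function(genotypes, config) {
    validObject(config)
    if (config@causalOr <= 0)
        stop("'causalOr' must be positive")
    if (config@nCausalSnps > nrow(genotypes))
        stop("'nCausalSnps' exceeds the number of simulated SNPs")
    set.seed(.stageSeed(config@seed, "phenotype"))
    n <- ncol(genotypes)
    age <- runif(n, config@ageRange[1], config@ageRange[2])
    sex <- rbinom(n, 1L, 0.5)

    plan <- .planTruth(config)
    eta <- rep(qlogis(config@baselinePrevalence), n)
    b <- log(config@causalOr)
    if (length(plan$causalIdx) && b != 0) {
        g <- dosages(genotypes)[plan$causalIdx, , drop = FALSE]
        eta <- eta + as.numeric(b * colSums(g - rowMeans(g)))
    }
    eta <- eta + config@ageBeta * (age - mean(age)) +
        config@sexBeta * (sex - mean(sex))
    y <- rbinom(n, 1L, plogis(eta))

    out <- data.frame(subject = colnames(genotypes),
                      group = unname(subjectGroups(genotypes)),
                      ar_status = y, age = age, sex = sex,
                      stringsAsFactors = FALSE)
    attr(out, "causalSnpIds") <- plan$snpIds[plan$causalIdx]
    out
}

#' Simulate expression with planted modules and cis-eSNP effects
#'
#' Each planted module m has a latent eigengene (standard normal across
#' samples); member genes are \code{loading * eigengene + noiseSd *
#' noise} with the loading calibrated so the expected within-module
#' correlation equals \code{moduleCor} (with \code{noiseSd = 0} genes
#' equal the eigengene).  Background genes are independent noise.  Each
#' planted cis pair adds \code{esnpBeta * dosage} to its gene.  Genes are
#' laid at fixed spacing on the simulated chromosome so every planted
#' pair lies well inside the 1 Mb cis window.  Expression samples are the
#' first \code{nExpressionSamples} subjects of the first group,
#' emulating profiling a single-cohort subset of the genotyped study.
#' Values are on a normalized (log2-like) scale.
#'
#' @param genotypes a [GenotypeExperiment-class].
#' @param config the same [SimulationConfig-class].
#' @return A list with elements \code{expression}
#'   (an [ExpressionExperiment-class]) and \code{truth}
#'   (a [GroundTruth-class]).
#' @export
simulateExpression <- function(genotypes, config) {
    validObject(config)
    if (config@moduleCor <= 0 || config@moduleCor >= 1)
        stop("'moduleCor' must lie in (0, 1)")
    set.seed(.stageSeed(config@seed, "expression"))
    plan <- .planTruth(config)
    nGenes <- config@nGenes
    samples <- colnames(genotypes)[seq_len(config@nExpressionSamples)]
    ns <- length(samples)

    eig <- matrix(rnorm(config@nModules * ns), config@nModules, ns)
    noiseSd <- config@noiseSd

    ## per-gene loading multipliers give each module hub structure (a
    ## heterogeneous connectivity distribution, as in real coexpression
    ## data); the base loading is calibrated so the population mean
    ## within-module correlation equals moduleCor
    expr <- matrix(0, nGenes, ns,
                   dimnames = list(plan$geneIds, samples))
    for (m in seq_len(config@nModules)) {
        members <- which(plan$moduleLabels == paste0("module", m))
        u <- runif(length(members), config@loadingRange[1],
                   config@loadingRange[2])
        L <- if (noiseSd == 0) 1 else {
            target <- config@moduleCor
            f <- function(L) {
                s <- sqrt(u^2 * L^2 + noiseSd^2)
                C <- outer(u, u) * L^2 / outer(s, s)
                mean(C[upper.tri(C)]) - target
            }
            uniroot(f, c(1e-3, 1e5) * noiseSd, tol = 1e-10)$root
        }
        for (j in seq_along(members))
            expr[members[j], ] <- u[j] * L * eig[m, ] + noiseSd * rnorm(ns)
    }
    for (i in which(plan$moduleLabels == "background"))
        expr[i, ] <- noiseSd * rnorm(ns)
    if (nrow(plan$esnpPairs)) {
        d <- dosages(genotypes)[plan$esnpPairs$snp_id, samples,
                                drop = FALSE]
        expr[plan$esnpPairs$gene_id, ] <-
            expr[plan$esnpPairs$gene_id, , drop = FALSE] +
            plan$esnpPairs$beta * d
    }

    genes <- GRanges("chr1",
                     IRanges(start = plan$geneStart, end = plan$geneEnd))
    names(genes) <- plan$geneIds

    truth <- new("GroundTruth",
                 causalSnpIds = plan$snpIds[plan$causalIdx],
                 moduleLabels = plan$moduleLabels,
                 esnpPairs = plan$esnpPairs,
                 diseaseModule = "module1",
                 cisWindowBp = 1e6)
    validObject(truth)
    list(expression = ExpressionExperiment(expr, genes), truth = truth)
}

#' Synthetic gene-set collection aligned with the simulated genome
#'
#' Builds a toy GMT-style collection for the simulated gene universe: one
#' "mitochondrion-like" set concentrated in the planted disease module
#' (a fraction of its genes plus random background genes) and a number
#' of random sets, so pathway enrichment of a recovered disease module
#' has a planted positive.
#'
#' @param truth a [GroundTruth-class].
#' @param nRandomSets number of random decoy sets.
#' @param setSize genes per set.
#' @param coreFraction fraction of the target set drawn from the disease
#'   module.
#' @param seed integer seed.
#' @return A [GeneSets-class].
#' @export
syntheticGeneSets <- function(truth, nRandomSets = 20L, setSize = 40L,
                              coreFraction = 0.75, seed = 1L) {
    set.seed(.stageSeed(seed, "genesets"))
    genes <- names(plantedModules(truth))
    disease <- genes[plantedModules(truth) == diseaseModule(truth)]
    nCore <- min(length(disease), ceiling(setSize * coreFraction))
    target <- c(sample(disease, nCore),
                sample(setdiff(genes, disease), setSize - nCore))
    sets <- list(MITO_LIKE_SYNTH = sort(target))
    for (i in seq_len(nRandomSets))
        sets[[sprintf("RANDOM_SET_%02d", i)]] <- sort(sample(genes, setSize))
    new("GeneSets", sets = sets,
        descriptions = setNames(
            c("synthetic disease-module-enriched set",
              rep("synthetic random set", nRandomSets)),
            names(sets)))
}
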