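## Central S4 classes.  GenotypeExperiment / ExpressionExperiment follow the
## SummarizedExperiment convention: features (SNPs, genes) in rows, subjects
## in columns.

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator.  The defaults define the
#' package's "demo" study: two ancestry groups of 500 subjects genotyped
#' at 2000 SNPs on one simulated chromosome, a binary trait with target
#' prevalence 0.48, and an expression matrix over 100 of the subjects
#' with 5 planted coexpression modules of 50 genes each
#' (within-module correlation 0.7), 10 planted cis-eSNPs whose SNPs also
#' carry phenotype effects (the planted disease module), and 15 causal
#' SNPs in total.
#'
#' @slot nSubjectsPerGroup integer, subjects per ancestry group.
#' @slot nGroups integer, number of ancestry groups.
#' @slot nSnps integer, number of SNPs on the simulated chromosome.
#' @slot mafRange numeric(2), range of ancestral minor-allele
#'   frequencies, each in (0, 0.5].
#' @slot fst numeric, Balding-Nichols divergence parameter in [0, 1).
#' @slot ldBlockSize integer, SNPs per linkage-disequilibrium block.
#' @slot ldRho numeric, latent within-block haplotype correlation in
#'   [0, 1).
#' @slot snpSpacingBp integer, base pairs between adjacent SNPs.
#' @slot nGenes integer, genes on the expression platform.
#' @slot geneWidthBp integer, width of each simulated gene body.
#' @slot nModules integer, number of planted coexpression modules.
#' @slot moduleSizes integer vector of planted module sizes;
#'   \code{sum(moduleSizes) <= nGenes}, the remainder is background.
#' @slot moduleCor numeric, target population mean within-module
#'   gene-gene correlation in (0, 1).
#' @slot loadingRange numeric(2), range of the uniform per-gene loading
#'   multipliers that give each module hub structure; the base loading
#'   is calibrated so the mean within-module correlation hits
#'   \code{moduleCor}.
#' @slot noiseSd numeric, expression noise standard deviation.
#' @slot nCisEsnps integer, planted cis-eSNP pairs (all in the disease
#'   module).
#' @slot esnpBeta numeric, expression shift per effect allele.
#' @slot nCausalSnps integer, SNPs with phenotype effects; must be at
#'   least \code{nCisEsnps} because every planted eSNP SNP is causal.
#' @slot causalOr numeric, per-allele odds ratio of causal SNPs.
#' @slot baselinePrevalence numeric probability; the logistic intercept
#'   is \code{qlogis(baselinePrevalence)} and genetic/covariate terms are
#'   centered, so this is the approximate marginal case fraction.
#' @slot ageRange numeric(2), uniform range of the simulated age
#'   covariate (years).
#' @slot ageBeta,sexBeta numeric, log-odds covariate effects.
#' @slot nExpressionSamples integer, genotyped subjects (taken from the
#'   first group) that also receive expression profiles.
#' @slot seed integer master seed; it fully determines all outputs via
#'   per-stage derived streams.
#' @export
setClass("SimulationConfig", representation(
    nSubjectsPerGroup = "integer",
    nGroups           = "integer",
    nSnps             = "integer",
    mafRange          = "numeric",
    fst               = "numeric",
    ldBlockSize       = "integer",
    ldRho             = "numeric",
    snpSpacingBp      = "integer",
    nGenes            = "integer",
    geneWidthBp       = "integer",
    nModules          = "integer",
    moduleSizes       = "integer",
    moduleCor         = "numeric",
    loadingRange      = "numeric",
    noiseSd           = "numeric",
    nCisEsnps         = "integer",
    esnpBeta          = "numeric",
    nCausalSnps       = "integer",
    causalOr          = "numeric",
    baselinePrevalence = "numeric",
    ageRange          = "numeric",
    ageBeta           = "numeric",
    sexBeta           = "numeric",
    nExpressionSamples = "integer",
    seed              = "integer"
))

setValidity("SimulationConfig", function(object) {
    chkPos <- function(x, nm) {
        if (length(x) != 1L || is.na(x) || x < 1L)
            sprintf("'%s' must be a single positive integer", nm)
        else NULL
    }
    msgs <- c(
        chkPos(object@nSubjectsPerGroup, "nSubjectsPerGroup"),
        chkPos(object@nGroups, "nGroups"),
        chkPos(object@nSnps, "nSnps"),
        chkPos(object@ldBlockSize, "ldBlockSize"),
        chkPos(object@snpSpacingBp, "snpSpacingBp"),
        chkPos(object@nGenes, "nGenes"),
        chkPos(object@geneWidthBp, "geneWidthBp"),
        chkPos(object@nModules, "nModules")
    )
    mr <- object@mafRange
    if (length(mr) != 2L || any(is.na(mr)) || mr[1] > mr[2] ||
        mr[1] <= 0 || mr[2] > 0.5)
        msgs <- c(msgs, "'mafRange' must be increasing within (0, 0.5]")
    if (object@fst < 0 || object@fst >= 1)
        msgs <- c(msgs, "'fst' must lie in [0, 1)")
    if (object@ldRho < 0 || object@ldRho >= 1)
        msgs <- c(msgs, "'ldRho' must lie in [0, 1)")
    if (length(object@moduleSizes) != object@nModules)
        msgs <- c(msgs, "'moduleSizes' must have length 'nModules'")
    if (any(object@moduleSizes < 1L))
        msgs <- c(msgs, "'moduleSizes' must be positive")
    if (sum(object@moduleSizes) > object@nGenes)
        msgs <- c(msgs, "'moduleSizes' must sum to at most 'nGenes'")
    if (object@moduleCor <= 0 || object@moduleCor >= 1)
        msgs <- c(msgs, "'moduleCor' must lie in (0, 1)")
    if (length(object@loadingRange) != 2L || any(object@loadingRange <= 0) ||
        object@loadingRange[1] > object@loadingRange[2])
        msgs <- c(msgs, "'loadingRange' must be an increasing positive pair")
    if (object@noiseSd < 0)
        msgs <- c(msgs, "'noiseSd' must be non-negative")
    if (object@esnpBeta < 0)
        msgs <- c(msgs, "'esnpBeta' must be non-negative")
    if (object@nCisEsnps < 0L)
        msgs <- c(msgs, "'nCisEsnps' must be non-negative")
    if (object@nCisEsnps > min(object@moduleSizes[1], object@nGenes))
        msgs <- c(msgs, "'nCisEsnps' must not exceed the disease module size")
    if (object@causalOr <= 0)
        msgs <- c(msgs, "'causalOr' must be positive")
    if (object@nCausalSnps < object@nCisEsnps)
        msgs <- c(msgs, "'nCausalSnps' must be at least 'nCisEsnps'")
    if (object@nCausalSnps > object@nSnps)
        msgs <- c(msgs, "'nCausalSnps' must not exceed 'nSnps'")
    if (object@baselinePrevalence <= 0 || object@baselinePrevalence >= 1)
        msgs <- c(msgs, "'baselinePrevalence' must lie in (0, 1)")
    if (length(object@ageRange) != 2L || object@ageRange[1] > object@ageRange[2])
        msgs <- c(msgs, "'ageRange' must be an increasing pair")
    if (object@nExpressionSamples > object@nSubjectsPerGroup)
        msgs <- c(msgs,
            "'nExpressionSamples' must not exceed 'nSubjectsPerGroup'")
    if (length(object@seed) != 1L || is.na(object@seed))
        msgs <- c(msgs, "'seed' must be a single integer")
    if (length(msgs)) msgs else TRUE
})

#' Construct a simulation configuration
#'
#' See [SimulationConfig-class] for the meaning of each parameter.  All
#' arguments have demo-study defaults; any subset may be overridden.
#'
#' @param nSubjectsPerGroup,nGroups,nSnps,mafRange,fst,ldBlockSize,ldRho
#'   genotype parameters.
#' @param snpSpacingBp,geneWidthBp layout of the simulated chromosome.
#' @param nGenes,nModules,moduleSizes,moduleCor,noiseSd expression
#'   parameters.
#' @param nCisEsnps,esnpBeta,nCausalSnps,causalOr planted-effect
#'   parameters.
#' @param baselinePrevalence,ageRange,ageBeta,sexBeta phenotype-model
#'   parameters.
#' @param nExpressionSamples expression-profiled subject count
#'   (default: 100, capped at \code{nSubjectsPerGroup}).
#' @param seed master seed.
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(seed = 7L)
#' cfg
#' @export
simulationConfig <- function(nSubjectsPerGroup = 500L,
                             nGroups = 2L,
                             nSnps = 2000L,
                             mafRange = c(0.05, 0.5),
                             fst = 0.1,
                             ldBlockSize = 10L,
                             ldRho = 0.3,
                             snpSpacingBp = 50000L,
                             nGenes = 500L,
                             geneWidthBp = 1000L,
                             nModules = 5L,
                             moduleSizes = rep(50L, 5L),
                             moduleCor = 0.7,
                             loadingRange = c(0.2, 1),
                             noiseSd = 1,
                             nCisEsnps = 10L,
                             esnpBeta = 2,
                             nCausalSnps = 15L,
                             causalOr = 1.8,
                             baselinePrevalence = 0.48,
                             ageRange = c(5, 60),
                             ageBeta = 0.01,
                             sexBeta = 0.2,
                             nExpressionSamples = NULL,
                             seed = 1L) {
    if (is.null(nExpressionSamples))
        nExpressionSamples <- min(100L, as.integer(nSubjectsPerGroup))
    new("SimulationConfig",
        nSubjectsPerGroup = as.integer(nSubjectsPerGroup),
        nGroups = as.integer(nGroups),
        nSnps = as.integer(nSnps),
        mafRange = as.numeric(mafRange),
        fst = as.numeric(fst),
        ldBlockSize = as.integer(ldBlockSize),
        ldRho = as.numeric(ldRho),
        snpSpacingBp = as.integer(snpSpacingBp),
        nGenes = as.integer(nGenes),
        geneWidthBp = as.integer(geneWidthBp),
        nModules = as.integer(nModules),
        moduleSizes = as.integer(moduleSizes),
        moduleCor = as.numeric(moduleCor),
        loadingRange = as.numeric(loadingRange),
        noiseSd = as.numeric(noiseSd),
        nCisEsnps = as.integer(nCisEsnps),
        esnpBeta = as.numeric(esnpBeta),
        nCausalSnps = as.integer(nCausalSnps),
        causalOr = as.numeric(causalOr),
        baselinePrevalence = as.numeric(baselinePrevalence),
        ageRange = as.numeric(ageRange),
        ageBeta = as.numeric(ageBeta),
        sexBeta = as.numeric(sexBeta),
        nExpressionSamples = as.integer(nExpressionSamples),
        seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat(sprintf("  subjects: %d x %d group(s); SNPs: %d (Fst %.3g, LD rho %.3g, block %d)\n",
        object@nSubjectsPerGroup, object@nGroups, object@nSnps,
        object@fst, object@ldRho, object@ldBlockSize))
    cat(sprintf("  genes: %d; modules: %s (cor %.2f); expression samples: %d\n",
        object@nGenes, paste(object@moduleSizes, collapse = "/"),
        object@moduleCor, object@nExpressionSamples))
    cat(sprintf("  plants: %d cis-eSNPs (beta %.2f), %d causal SNPs (OR %.2f), prevalence %.2f\n",
        object@nCisEsnps, object@esnpBeta, object@nCausalSnps,
        object@causalOr, object@baselinePrevalence))
    cat(sprintf("  seed: %d\n", object@seed))
})

#' Planted ground truth of a simulated study
#'
#' @slot causalSnpIds character, SNPs with phenotype effects.
#' @slot moduleLabels named character, gene -> planted module label
#'   ("module1", ..., or "background").
#' @slot esnpPairs data.frame with columns \code{snp_id}, \code{gene_id},
#'   \code{beta}, \code{distance_bp}: planted cis effects.
#' @slot diseaseModule label of the planted module whose genes harbor the
#'   eSNPs with causal SNPs.
#' @slot cisWindowBp the cis window all planted pairs respect.
#' @export
setClass("GroundTruth", representation(
    causalSnpIds = "character",
    moduleLabels = "character",
    esnpPairs    = "data.frame",
    diseaseModule = "character",
    cisWindowBp  = "numeric"
))

setValidity("GroundTruth", function(object) {
    msgs <- character()
    if (!(object@diseaseModule %in% object@moduleLabels))
        msgs <- c(msgs, "'diseaseModule' must appear among 'moduleLabels'")
    if (nrow(object@esnpPairs) &&
        any(object@esnpPairs$distance_bp > object@cisWindowBp))
        msgs <- c(msgs, "all planted eSNP pairs must lie within the cis window")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth\n")
    cat(sprintf("  causal SNPs: %d; planted eSNP pairs: %d; disease module: %s\n",
        length(object@causalSnpIds), nrow(object@esnpPairs),
        object@diseaseModule))
    cat(sprintf("  planted modules: %s\n",
        paste(names(table(object@moduleLabels)), collapse = ", ")))
})

#' Genotype data container
#'
#' A \linkS4class{RangedSummarizedExperiment} with SNPs in rows and
#' subjects in columns.  The \code{"dosage"} assay holds additive effect-
#' allele dosages in \{0, 1, 2\}; \code{rowRanges} carries the SNP map
#' (1-based positions, ref/alt alleles); \code{colData} carries subject
#' metadata including the ancestry \code{group}.
#'
#' @export
setClass("GenotypeExperiment", contains = "RangedSummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
    msgs <- character()
    if (!"dosage" %in% assayNames(object))
        msgs <- c(msgs, "assay 'dosage' is required")
    else {
        d <- assay(object, "dosage")
        if (any(!is.na(d) & !(d %in% c(0, 1, 2))))
            msgs <- c(msgs, "dosages must be in {0, 1, 2}")
    }
    if (!"group" %in% colnames(colData(object)))
        msgs <- c(msgs, "colData column 'group' is required")
    if (length(msgs)) msgs else TRUE
})

#' Expression data container
#'
#' A \linkS4class{RangedSummarizedExperiment} with genes in rows and
#' samples in columns; the \code{"exprs"} assay holds expression values
#' and \code{rowRanges} the gene bodies (internally 1-based closed
#' intervals; BED I/O converts to/from 0-based half-open).
#'
#' @export
setClass("ExpressionExperiment", contains = "RangedSummarizedExperiment")

setValidity("ExpressionExperiment", function(object) {
    if (!"exprs" %in% assayNames(object))
        "assay 'exprs' is required"
    else TRUE
})

#' Weighted coexpression network
#'
#' @slot beta soft-threshold power applied to |correlation|.
#' @slot adjacency gene x gene matrix of \code{|cor|^beta} with unit
#'   diagonal.
#' @slot tom topological overlap matrix, unit diagonal.
#' @slot connectivity per-gene connectivity, row sums of adjacency over
#'   the off-diagonal.
#' @slot scaleFreeFit data.frame of scale-free fit diagnostics per
#'   candidate power (may have zero rows when the power was fixed by the
#'   caller).
#' @export
setClass("CoexpressionNetwork", representation(
    beta = "numeric",
    adjacency = "matrix",
    tom = "matrix",
    connectivity = "numeric",
    scaleFreeFit = "data.frame"
))

setValidity("CoexpressionNetwork", function(object) {
    msgs <- character()
    a <- object@adjacency; tm <- object@tom
    if (!isTRUE(all.equal(a, t(a), tolerance = 1e-8)))
        msgs <- c(msgs, "adjacency must be symmetric")
    if (!isTRUE(all.equal(tm, t(tm), tolerance = 1e-8)))
        msgs <- c(msgs, "TOM must be symmetric")
    if (any(a < -1e-12 | a > 1 + 1e-12))
        msgs <- c(msgs, "adjacency entries must lie in [0, 1]")
    if (any(tm < -1e-12 | tm > 1 + 1e-8))
        msgs <- c(msgs, "TOM entries must lie in [0, 1]")
    if (any(abs(diag(a) - 1) > 1e-12) || any(abs(diag(tm) - 1) > 1e-12))
        msgs <- c(msgs, "diagonals are defined as 1")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "CoexpressionNetwork", function(object) {
    cat("CoexpressionNetwork\n")
    cat(sprintf("  genes: %d; soft power beta: %g\n",
        nrow(object@adjacency), object@beta))
    cat(sprintf("  mean connectivity: %.3g; mean off-diagonal TOM: %.3g\n",
        mean(object@connectivity),
        mean(object@tom[upper.tri(object@tom)])))
    if (nrow(object@scaleFreeFit))
        cat(sprintf("  scale-free fit R^2 at beta: %.3f\n",
            object@scaleFreeFit$rsq[match(object@beta,
                object@scaleFreeFit$power)]))
})

#' Module assignment from the coexpression network
#'
#' @slot labels named character, gene -> module color ("grey" =
#'   unassigned).
#' @slot dendrogram the average-linkage \code{hclust} tree on 1 - TOM.
#' @slot cutHeight dendrogram cut height actually used.
#' @slot minModuleSize smallest allowed module.
#' @export
setClass("ModuleAssignment", representation(
    labels = "character",
    dendrogram = "ANY",
    cutHeight = "numeric",
    minModuleSize = "integer"
))

setValidity("ModuleAssignment", function(object) {
    msgs <- character()
    if (is.null(names(object@labels)))
        msgs <- c(msgs, "'labels' must be named by gene")
    sz <- table(object@labels[object@labels != "grey"])
    if (length(sz) && any(sz < object@minModuleSize))
        msgs <- c(msgs, "every non-grey module must meet the minimum size")
    if (length(msgs)) msgs else TRUE
})

#' @describeIn ModuleAssignment-class module sizes, largest first
#'   (grey last).
#' @param x,object a \code{ModuleAssignment}.
#' @export
moduleSizes <- function(x) {
    stopifnot(is(x, "ModuleAssignment"))
    sz <- table(x@labels)
    grey <- sz[names(sz) == "grey"]
    sz <- sort(sz[names(sz) != "grey"], decreasing = TRUE)
    c(sz, grey)
}

setMethod("show", "ModuleAssignment", function(object) {
    sz <- moduleSizes(object)
    cat("ModuleAssignment\n")
    cat(sprintf("  genes: %d; modules (non-grey): %d; cut height: %.4f\n",
        length(object@labels), sum(names(sz) != "grey"), object@cutHeight))
    cat("  sizes: ",
        paste(sprintf("%s=%d", names(sz), as.integer(sz)), collapse = ", "),
        "\n", sep = "")
})

#' Gene-set collection (GMT)
#'
#' @slot sets named list of character vectors of gene ids.
#' @slot descriptions named character of set descriptions.
#' @export
setClass("GeneSets", representation(
    sets = "list",
    descriptions = "character"
))

setValidity("GeneSets", function(object) {
    msgs <- character()
    if (any(lengths(object@sets) == 0L))
        msgs <- c(msgs, "empty gene sets are not allowed")
    if (any(vapply(object@sets, anyDuplicated, 0L) > 0L))
        msgs <- c(msgs, "gene ids must be unique within a set")
    if (anyDuplicated(names(object@sets)))
        msgs <- c(msgs, "set names must be unique")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "GeneSets", function(object) {
    cat(sprintf("GeneSets: %d sets, %d distinct genes\n",
        length(object@sets), length(unique(unlist(object@sets)))))
})
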