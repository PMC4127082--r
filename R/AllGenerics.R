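#' @name accessors
#' @title Accessors for ariNet containers
#' @description Slot access for the package's S4 classes goes through
#'   these accessors.
#' @param x an ariNet container object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeExperiment", function(x) assay(x, "dosage"))

#' @rdname accessors
#' @export
setGeneric("snpRanges", function(x) standardGeneric("snpRanges"))

#' @rdname accessors
#' @export
setMethod("snpRanges", "GenotypeExperiment", function(x) rowRanges(x))

#' @rdname accessors
#' @export
setGeneric("subjectGroups", function(x) standardGeneric("subjectGroups"))

#' @rdname accessors
#' @export
setMethod("subjectGroups", "GenotypeExperiment", function(x) {
    setNames(as.character(colData(x)$group), colnames(x))
})

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionExperiment", function(x) assay(x, "exprs"))

#' @rdname accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname accessors
#' @export
setMethod("geneRanges", "ExpressionExperiment", function(x) rowRanges(x))

#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname accessors
#' @export
setMethod("adjacencyMatrix", "CoexpressionNetwork", function(x) x@adjacency)

#' @rdname accessors
#' @export
setGeneric("tomMatrix", function(x) standardGeneric("tomMatrix"))

#' @rdname accessors
#' @export
setMethod("tomMatrix", "CoexpressionNetwork", function(x) x@tom)

#' @rdname accessors
#' @export
setGeneric("connectivity", function(x) standardGeneric("connectivity"))

#' @rdname accessors
#' @export
setMethod("connectivity", "CoexpressionNetwork", function(x) x@connectivity)

#' @rdname accessors
#' @export
setGeneric("softPower", function(x) standardGeneric("softPower"))

#' @rdname accessors
#' @export
setMethod("softPower", "CoexpressionNetwork", function(x) x@beta)

#' @rdname accessors
#' @export
setGeneric("scaleFreeFit", function(x) standardGeneric("scaleFreeFit"))

#' @rdname accessors
#' @export
setMethod("scaleFreeFit", "CoexpressionNetwork", function(x) x@scaleFreeFit)

#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @rdname accessors
#' @export
setMethod("moduleLabels", "ModuleAssignment", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("moduleDendrogram", function(x) standardGeneric("moduleDendrogram"))

#' @rdname accessors
#' @export
setMethod("moduleDendrogram", "ModuleAssignment", function(x) x@dendrogram)

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSets", function(x) x@sets)

#' @rdname accessors
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))

#' @rdname accessors
#' @export
setMethod("setDescriptions", "GeneSets", function(x) x@descriptions)

#' @rdname accessors
#' @export
setGeneric("causalSnpIds", function(x) standardGeneric("causalSnpIds"))

#' @rdname accessors
#' @export
setMethod("causalSnpIds", "GroundTruth", function(x) x@causalSnpIds)

#' @rdname accessors
#' @export
setGeneric("plantedModules", function(x) standardGeneric("plantedModules"))

#' @rdname accessors
#' @export
setMethod("plantedModules", "GroundTruth", function(x) x@moduleLabels)

#' @rdname accessors
#' @export
setGeneric("esnpPairs", function(x) standardGeneric("esnpPairs"))

#' @rdname accessors
#' @export
setMethod("esnpPairs", "GroundTruth", function(x) x@esnpPairs)

#' @rdname accessors
#' @export
setGeneric("diseaseModule", function(x) standardGeneric("diseaseModule"))

#' @rdname accessors
#' @export
setMethod("diseaseModule", "GroundTruth", function(x) x@diseaseModule)

#' Construct a GenotypeExperiment
#'
#' @param dosage numeric matrix of additive dosages, SNPs x subjects,
#'   with row and column names.
#' @param snpMap \link[GenomicRanges]{GRanges} of SNP positions (width-1,
#'   1-based) named like the rows of \code{dosage}, with metadata columns
#'   \code{ref} and \code{alt} (the counted effect allele).
#' @param group character/factor of per-subject ancestry group labels.
#' @param colData optional extra subject metadata (\code{DataFrame}).
#' @return A [GenotypeExperiment-class].
#' @export
GenotypeExperiment <- function(dosage, snpMap, group,
                               colData = NULL) {
    stopifnot(is.matrix(dosage), !is.null(rownames(dosage)),
              !is.null(colnames(dosage)))
    if (!identical(rownames(dosage), names(snpMap)))
        stop("rownames(dosage) must match names(snpMap)")
    if (length(group) != ncol(dosage))
        stop("'group' must have one entry per subject")
    cd <- S4Vectors::DataFrame(group = as.character(group),
                               row.names = colnames(dosage))
    if (!is.null(colData))
        cd <- cbind(cd, colData)
    se <- SummarizedExperiment(assays = list(dosage = dosage),
                               rowRanges = snpMap, colData = cd)
    new("GenotypeExperiment", se)
}

setMethod("show", "GenotypeExperiment", function(object) {
    cat(sprintf("GenotypeExperiment: %d SNPs x %d subjects (%d group(s))\n",
        nrow(object), ncol(object),
        length(unique(colData(object)$group))))
    callNextMethod()
})

#' Construct an ExpressionExperiment
#'
#' @param exprs numeric matrix of expression values, genes x samples,
#'   with row and column names.
#' @param genes \link[GenomicRanges]{GRanges} of gene bodies named like
#'   the rows of \code{exprs} (internally 1-based closed intervals).
#' @param colData optional sample metadata.
#' @return An [ExpressionExperiment-class].
#' @export
ExpressionExperiment <- function(exprs, genes, colData = NULL) {
    stopifnot(is.matrix(exprs), !is.null(rownames(exprs)),
              !is.null(colnames(exprs)))
    if (!identical(rownames(exprs), names(genes)))
        stop("rownames(exprs) must match names(genes)")
    if (is.null(colData))
        colData <- S4Vectors::DataFrame(row.names = colnames(exprs))
    se <- SummarizedExperiment(assays = list(exprs = exprs),
                               rowRanges = genes, colData = colData)
    new("ExpressionExperiment", se)
}

setMethod("show", "ExpressionExperiment", function(object) {
    cat(sprintf("ExpressionExperiment: %d genes x %d samples\n",
        nrow(object), ncol(object)))
    callNextMethod()
})
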