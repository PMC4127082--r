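## Weighted coexpression network: soft-thresholded adjacency,
## topological overlap, and dendrogram-based module detection, plus the
## randomization controls used to check network specificity.

#' Preprocess a raw expression matrix
#'
#' Log2 transformation (requires strictly positive values) followed by
#' quantile normalization across samples (via
#' \code{limma::normalizeQuantiles}), after which every sample carries an
#' identical multiset of values and within-sample ranks are preserved.
#' Data already on a normalized log scale can skip the log step with
#' \code{log2Transform = FALSE}.
#'
#' @param raw an [ExpressionExperiment-class] or genes x samples matrix.
#' @param log2Transform logical, apply \code{log2} first.
#' @return Object of the same type with normalized values.
#' @export
preprocessExpression <- function(raw, log2Transform = TRUE) {
    mat <- .asMatrix(raw)
    if (log2Transform) {
        bad <- which(mat <= 0, arr.ind = TRUE)
        if (nrow(bad)) {
            show <- head(apply(bad, 1L, function(ij)
                sprintf("[%s, %s] = %g",
                        rownames(mat)[ij[1]] %||% ij[1],
                        colnames(mat)[ij[2]] %||% ij[2],
                        mat[ij[1], ij[2]])), 5L)
            stop("log2 requires strictly positive values; offending entries: ",
                 paste(show, collapse = "; "),
                 if (nrow(bad) > 5L) sprintf(" (and %d more)", nrow(bad) - 5L))
        }
        mat <- log2(mat)
    }
    norm <- limma::normalizeQuantiles(mat)
    dimnames(norm) <- dimnames(mat)
    if (is(raw, "ExpressionExperiment")) {
        out <- raw
        assay(out, "exprs") <- norm
        out
    } else norm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Scale-free topology fit: bin the connectivity distribution, regress
## log10 frequency on log10 mean connectivity, report R^2 signed by the
## slope (scale-free topology requires a decreasing relationship).
.scaleFreeFitIndex <- function(k, nBins = 10L) {
    k <- k[k > 0]
    if (length(k) < 2L)
        return(c(rsq = NA_real_, slope = NA_real_))
    cuts <- cut(k, breaks = nBins)
    freq <- tapply(k, cuts, length)
    kMean <- tapply(k, cuts, mean)
    keep <- !is.na(freq) & freq > 0 & kMean > 0
    if (sum(keep) < 3L)
        return(c(rsq = NA_real_, slope = NA_real_))
    fit <- lm(log10(freq[keep] / sum(freq[keep])) ~ log10(kMean[keep]))
    r2 <- summary(fit)$r.squared
    slope <- coef(fit)[2]
    c(rsq = unname(-sign(slope) * r2), slope = unname(slope))
}

#' Choose the soft-threshold power
#'
#' For each candidate power the weighted adjacency
#' \code{|cor|^power} is formed and the scale-free topology fit of its
#' connectivity distribution computed (R-squared of the log-log
#' frequency vs connectivity regression, signed by the slope).  The
#' smallest power reaching \code{rsqCut} while keeping mean
#' connectivity at least \code{minMeanK} is chosen; when no power
#' qualifies the configured \code{fallback} is returned.  The
#' connectivity floor matters: at extreme powers any network decays to
#' near-zero connectivity whose binned distribution looks spuriously
#' scale-free, exactly as in randomized data.
#'
#' @param expr an [ExpressionExperiment-class] or genes x samples
#'   matrix; at least 20 genes.
#' @param powers candidate powers (at least 3).
#' @param rsqCut scale-free fit threshold (default 0.8).
#' @param fallback power used when no candidate reaches \code{rsqCut}.
#' @param nBins connectivity histogram bins for the fit.
#' @param minMeanK minimum mean connectivity for an admissible power
#'   (default 1).
#' @return list with \code{power} and \code{fitTable} (data.frame:
#'   \code{power}, \code{rsq}, \code{slope}, \code{meanK},
#'   \code{medianK}, \code{maxK}).
#' @export
pickSoftThreshold <- function(expr, powers = c(1:10, 12L, 14L, 16L),
                              rsqCut = 0.8, fallback = 6L, nBins = 10L,
                              minMeanK = 1) {
    mat <- .asMatrix(expr)
    if (length(powers) < 3L)
        stop("at least 3 candidate powers are required")
    if (nrow(mat) < 20L)
        stop("at least 20 genes are required")
    sds <- apply(mat, 1L, sd)
    if (all(sds == 0))
        stop("all genes are constant")
    if (any(sds == 0))
        stop("constant gene(s): ",
             paste(head(rownames(mat)[sds == 0], 5L), collapse = ", "))
    absCor <- abs(cor(t(mat)))
    diag(absCor) <- 0
    rows <- lapply(powers, function(b) {
        k <- rowSums(absCor^b)
        f <- .scaleFreeFitIndex(k, nBins = nBins)
        data.frame(power = b, rsq = f[["rsq"]], slope = f[["slope"]],
                   meanK = mean(k), medianK = median(k), maxK = max(k))
    })
    fitTable <- do.call(rbind, rows)
    ok <- which(!is.na(fitTable$rsq) & fitTable$rsq >= rsqCut &
                fitTable$meanK >= minMeanK)
    power <- if (length(ok)) fitTable$power[ok[1]] else fallback
    list(power = power, fitTable = fitTable)
}

#' Adjacency, connectivity and topological overlap
#'
#' The unsigned weighted adjacency is \eqn{a_{ij} = |cor(g_i,
#' g_j)|^\beta} (diagonal defined as 1) and the topological overlap is
#' \deqn{TOM_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},
#' \quad l_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj},}
#' with \eqn{k_i = \sum_{j \ne i} a_{ij}} and \eqn{TOM_{ii} = 1}.
#'
#' @param expr an [ExpressionExperiment-class] or genes x samples
#'   matrix; no constant genes.
#' @param beta soft-threshold power, at least 1.
#' @return A [CoexpressionNetwork-class].
#' @export
computeTom <- function(expr, beta) {
    mat <- .asMatrix(expr)
    if (beta < 1)
        stop("'beta' must be at least 1")
    sds <- apply(mat, 1L, sd)
    if (any(sds == 0))
        stop("constant gene(s): ",
             paste(head(rownames(mat)[sds == 0], 5L), collapse = ", "))
    A <- abs(cor(t(mat)))^beta
    diag(A) <- 0
    k <- rowSums(A)
    tom <- .tomFromAdjacency(A)
    diag(A) <- 1
    dimnames(tom) <- dimnames(A)
    new("CoexpressionNetwork", beta = as.numeric(beta), adjacency = A,
        tom = tom, connectivity = k, scaleFreeFit = data.frame())
}

## TOM from an adjacency with zero diagonal; with diag(A) = 0 the matrix
## product (A %*% A)_ij equals sum_{u != i,j} a_iu a_uj exactly.
.tomFromAdjacency <- function(A) {
    k <- rowSums(A)
    L <- A %*% A
    minK <- outer(k, k, pmin)
    tom <- (L + A) / (minK + 1 - A)
    diag(tom) <- 1
    tom
}

## Deterministic size-ranked module palette; grey is reserved for
## unassigned genes.
.moduleColors <- c("turquoise", "blue", "brown", "yellow", "green",
    "red", "black", "pink", "magenta", "purple", "greenyellow", "tan",
    "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
    "lightgreen", "lightyellow", "royalblue", "darkred", "darkgreen",
    "darkturquoise", "darkgrey", "orange", "darkorange", "white",
    "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
    "darkolivegreen", "darkmagenta")

#' Detect coexpression modules from the topological overlap
#'
#' Average-linkage hierarchical clustering of the dissimilarity
#' \code{1 - TOM}; the tree is cut at a fixed height on the
#' dissimilarity scale (default 0.99, the conventional static cut for
#' TOM-based dendrograms), branches smaller than \code{minModuleSize}
#' are iteratively merged into the nearest branch (when their mean
#' dissimilarity to it stays below the cut height) or set aside, and a
#' branch is kept as a module only if it is cohesive: its mean
#' within-branch dissimilarity must undercut its mean dissimilarity to
#' the remaining genes by at least \code{cohesionMargin}.  Genes in no
#' retained module are labeled \code{"grey"}.  Modules are renamed by
#' descending size along a fixed color sequence, so labels are
#' reproducible but carry no meaning beyond rank.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param minModuleSize smallest allowed module (default 30, at
#'   least 2).
#' @param cutHeight dendrogram cut height on the 1 - TOM scale
#'   (default 0.99).
#' @param cohesionMargin minimum separation between within-branch and
#'   branch-to-rest mean dissimilarity (default 0.05).
#' @return A [ModuleAssignment-class].
#' @export
detectModules <- function(network, minModuleSize = 30L,
                          cutHeight = 0.99,
                          cohesionMargin = 0.05) {
    stopifnot(is(network, "CoexpressionNetwork"))
    if (minModuleSize < 2L)
        stop("'minModuleSize' must be at least 2")
    tom <- tomMatrix(network)
    if (any(!is.finite(tom)))
        stop("TOM contains non-finite entries")
    d <- 1 - tom
    genes <- rownames(tom)
    h <- hclust(as.dist(d), method = "average")
    cutH <- cutHeight
    cl <- if (any(h$height <= cutH)) cutree(h, h = cutH)
          else seq_along(genes)             # cut below all merges

    meanCross <- function(a, b) mean(d[a, b, drop = FALSE])
    meanWithin <- function(a) {
        if (length(a) < 2L) return(0)
        dd <- d[a, a, drop = FALSE]
        mean(dd[upper.tri(dd)])
    }

    ## iteratively absorb small branches into their nearest large branch
    ## (when close enough), otherwise set them aside as grey
    grey <- rep(FALSE, length(cl))
    repeat {
        sizes <- table(cl[!grey])
        small <- names(sizes)[sizes < minModuleSize]
        large <- names(sizes)[sizes >= minModuleSize]
        if (!length(small)) break
        s <- small[order(sizes[small], as.integer(small))][1]
        a <- which(cl == as.integer(s) & !grey)
        if (length(large)) {
            cross <- vapply(large, function(l)
                meanCross(a, which(cl == as.integer(l) & !grey)), 0)
            if (min(cross) <= cutH) {
                cl[a] <- as.integer(large[which.min(cross)])
                next
            }
        }
        grey[a] <- TRUE
    }

    ## cohesion filter: a module must stand off from the rest of the tree
    for (m in unique(cl[!grey])) {
        a <- which(cl == m & !grey)
        rest <- setdiff(seq_along(cl), a)
        if (!length(rest)) next
        if (meanCross(a, rest) - meanWithin(a) < cohesionMargin)
            grey[a] <- TRUE
    }
    cl[grey] <- 0L

    ## size-ranked color labels; ties broken by first gene index
    ids <- setdiff(unique(cl), 0L)
    if (length(ids)) {
        sz <- vapply(ids, function(m) sum(cl == m), 0L)
        first <- vapply(ids, function(m) which(cl == m)[1], 0L)
        ids <- ids[order(-sz, first)]
        pal <- rep_len(.moduleColors, length(ids))
        labels <- rep("grey", length(cl))
        for (i in seq_along(ids))
            labels[cl == ids[i]] <- pal[i]
    } else labels <- rep("grey", length(cl))
    names(labels) <- genes

    new("ModuleAssignment", labels = labels, dendrogram = h,
        cutHeight = cutH, minModuleSize = as.integer(minModuleSize))
}

#' Randomization controls for the coexpression network
#'
#' \code{mode = "labels"} permutes the gene-id/row mapping only (each
#' expression profile is reassigned to a different gene id; the matrix
#' values are untouched).  \code{mode = "values"} permutes each gene's
#' values independently across samples, destroying inter-gene
#' correlation while preserving each gene's marginal distribution.
#'
#' @param expr an [ExpressionExperiment-class] or genes x samples
#'   matrix.
#' @param mode \code{"labels"} or \code{"values"}.
#' @param seed integer seed.
#' @return Object of the same type.
#' @export
randomizeExpression <- function(expr, mode = c("labels", "values"),
                                seed = 1L) {
    mode <- match.arg(mode)
    mat <- .asMatrix(expr)
    set.seed(.stageSeed(seed, "randomize"))
    out <- switch(mode,
        labels = {
            perm <- sample(nrow(mat))
            m <- mat[perm, , drop = FALSE]
            rownames(m) <- rownames(mat)
            m
        },
        values = t(apply(mat, 1L, sample)))
    colnames(out) <- colnames(mat)
    if (is(expr, "ExpressionExperiment")) {
        res <- expr
        assay(res, "exprs") <- out
        res
    } else out
}
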