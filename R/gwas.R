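## Case/control association scan, meta-analysis, genomic control, and
## locus selection.
##
## The per-SNP statistic is the logistic score test for the additive
## dosage term, adjusted for age, sex and within-group genotype
## principal components.  It is standard normal under the null and its
## sign follows the effect-allele direction, matching the contract of
## the standard case/control scan tools without asserting their exact
## internals.

#' Genotype principal components
#'
#' SNP-wise standardization by mean \code{2p} and standard deviation
#' \code{sqrt(2p(1-p))} (with \code{p} the sample allele frequency),
#' followed by a singular value decomposition of the subject x SNP
#' matrix; monomorphic SNPs are excluded.  Scores are returned as
#' \code{U \%*\% diag(d)}, so columns are orthogonal.
#'
#' @param genotypes a [GenotypeExperiment-class] or dosage matrix
#'   (SNPs x subjects).
#' @param k number of components (default 10, the usual convention for
#'   stratification control).
#' @return Numeric matrix, subjects x k, rownames = subjects.
#' @export
computePcs <- function(genotypes, k = 10L) {
    d <- .asMatrix(genotypes)
    n <- ncol(d)
    if (n < 2L)
        stop("at least 2 subjects are required")
    p <- rowMeans(d) / 2
    keep <- p > 0 & p < 1 & apply(d, 1L, function(x) length(unique(x)) > 1L)
    if (!any(keep))
        stop("degenerate input: no polymorphic SNPs with non-zero variance")
    if (k >= min(n, sum(keep)))
        stop(sprintf(
            "k = %d must be smaller than min(subjects, polymorphic SNPs) = %d",
            k, min(n, sum(keep))))
    p <- p[keep]
    x <- (t(d[keep, , drop = FALSE]) - rep(2 * p, each = n)) /
        rep(sqrt(2 * p * (1 - p)), each = n)
    s <- svd(x, nu = k, nv = 0L)
    scores <- s$u %*% diag(s$d[seq_len(k)], k, k)
    dimnames(scores) <- list(colnames(d), paste0("PC", seq_len(k)))
    scores
}

## Vectorized logistic score test of each SNP given a fitted null model.
.scoreScan <- function(G, y, X) {
    fit <- glm.fit(X, y, family = binomial())
    mu <- fit$fitted.values
    w <- mu * (1 - mu)
    r <- y - mu
    XtWXi <- solve(crossprod(X, X * w))
    A <- G %*% (X * w)                       # m x p
    U <- as.numeric(G %*% r)
    V <- as.numeric((G * G) %*% w) - rowSums((A %*% XtWXi) * A)
    list(U = U, V = V)
}

#' Per-group case/control association scan
#'
#' Within each ancestry group the null logistic model (phenotype ~ age +
#' sex + within-group genotype principal components) is fitted once, and
#' each SNP's additive dosage term is tested with the efficient score
#' statistic, returned as a signed standard-normal \code{z} with
#' two-sided \code{p}.  SNPs with a single genotype class (or zero score
#' variance) in a group are flagged degenerate and carry no statistic.
#'
#' @param genotypes a [GenotypeExperiment-class].
#' @param phenotype data.frame as returned by [simulatePhenotype()]
#'   (columns \code{subject}, \code{ar_status}, \code{age}, \code{sex});
#'   \code{ar_status} must be binary 0/1.
#' @param nPcs principal components per group (default 10).
#' @param covariates character, phenotype columns used as covariates.
#' @param subset optional character/logical selecting subjects (e.g. a
#'   comorbidity stratum) before the scan.
#' @return data.frame with one row per (SNP, group): \code{snp_id},
#'   \code{chrom}, \code{pos}, \code{group}, \code{effect_allele},
#'   \code{other_allele}, \code{n}, \code{z}, \code{p},
#'   \code{degenerate}.
#' @export
associationScan <- function(genotypes, phenotype, nPcs = 10L,
                            covariates = c("age", "sex"),
                            subset = NULL) {
    stopifnot(is(genotypes, "GenotypeExperiment"))
    ph <- phenotype[match(colnames(genotypes), phenotype$subject), ,
                    drop = FALSE]
    if (anyNA(ph$subject))
        stop("phenotype table does not cover all genotyped subjects")
    if (!all(ph$ar_status %in% c(0, 1)))
        stop("phenotype must be binary 0/1")
    keep <- rep(TRUE, ncol(genotypes))
    if (!is.null(subset)) {
        keep <- if (is.logical(subset)) subset
                else colnames(genotypes) %in% subset
    }
    gr <- snpRanges(genotypes)
    groups <- unique(unname(subjectGroups(genotypes)))
    out <- vector("list", length(groups))
    for (gi in seq_along(groups)) {
        g <- groups[gi]
        sel <- keep & unname(subjectGroups(genotypes)) == g
        n <- sum(sel)
        G <- dosages(genotypes)[, sel, drop = FALSE]
        y <- ph$ar_status[sel]
        covs <- as.matrix(ph[sel, covariates, drop = FALSE])
        pcs <- computePcs(G, k = min(nPcs, n - 3L, nrow(G) - 1L))
        X <- cbind(`(Intercept)` = 1, covs, pcs)
        sc <- .scoreScan(G, y, X)
        degen <- apply(G, 1L, function(x) length(unique(x)) < 2L) |
            sc$V <= 1e-10
        z <- ifelse(degen, NA_real_, sc$U / sqrt(pmax(sc$V, 1e-300)))
        out[[gi]] <- data.frame(
            snp_id = rownames(G),
            chrom = as.character(seqnames(gr)),
            pos = start(gr),
            group = g,
            effect_allele = mcols(gr)$alt,
            other_allele = mcols(gr)$ref,
            n = n,
            z = z,
            p = 2 * pnorm(-abs(z)),
            degenerate = degen,
            stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Sample-size-weighted Z-score meta-analysis
#'
#' Combines per-group signed statistics as \deqn{z_{meta} = \sum_i w_i
#' z_i / \sqrt{\sum_i w_i^2}} with default weights \eqn{w_i =
#' \sqrt{n_i}}.  With one group the meta statistic is the group
#' statistic.  A record whose effect allele is the consensus other
#' allele has its z negated before combination; a record whose alleles
#' cannot be reconciled by flipping is dropped (a warning reports the
#' count).
#'
#' @param groupResults data.frame from [associationScan()] (rows from
#'   all groups stacked) or a list of such per-group data.frames.
#' @param weights optional named numeric of per-group weights; default
#'   \code{sqrt(n)} per record.
#' @return data.frame with \code{snp_id}, \code{chrom}, \code{pos},
#'   \code{effect_allele}, \code{other_allele}, \code{n_groups},
#'   \code{n_total}, \code{z_meta}, \code{p_meta}.
#' @export
metaAnalyze <- function(groupResults, weights = NULL) {
    res <- if (is.data.frame(groupResults)) groupResults
           else do.call(rbind, groupResults)
    res <- res[!res$degenerate & !is.na(res$z), , drop = FALSE]
    if (!nrow(res))
        return(data.frame(snp_id = character(), chrom = character(),
                          pos = integer(), effect_allele = character(),
                          other_allele = character(), n_groups = integer(),
                          n_total = integer(), z_meta = numeric(),
                          p_meta = numeric()))
    split_ <- split(res, res$snp_id)
    dropped <- 0L
    rows <- lapply(split_, function(d) {
        ea <- d$effect_allele[1]; oa <- d$other_allele[1]
        z <- d$z
        flip <- d$effect_allele == oa & d$other_allele == ea
        ok <- (d$effect_allele == ea & d$other_allele == oa) | flip
        if (any(!ok)) {
            dropped <<- dropped + 1L
            return(NULL)
        }
        z[flip] <- -z[flip]
        w <- if (is.null(weights)) sqrt(d$n) else weights[d$group]
        zm <- sum(w * z) / sqrt(sum(w^2))
        data.frame(snp_id = d$snp_id[1], chrom = d$chrom[1], pos = d$pos[1],
                   effect_allele = ea, other_allele = oa,
                   n_groups = nrow(d), n_total = sum(d$n),
                   z_meta = zm, p_meta = 2 * pnorm(-abs(zm)),
                   stringsAsFactors = FALSE)
    })
    if (dropped > 0L)
        warning(sprintf("%d SNP(s) dropped: alleles unresolvable by flip",
                        dropped))
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (!length(rows))
        return(data.frame(snp_id = character(), chrom = character(),
                          pos = integer(), effect_allele = character(),
                          other_allele = character(), n_groups = integer(),
                          n_total = integer(), z_meta = numeric(),
                          p_meta = numeric()))
    out <- do.call(rbind, rows)
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Genomic inflation factor
#'
#' \eqn{\lambda} = median of the 1-df chi-square quantiles of the
#' observed p values divided by the null median
#' \code{qchisq(0.5, 1)} (about 0.4549).  Values near 1 indicate
#' adequate control of population stratification.
#'
#' @param pValues numeric p values (NA ignored); at least 100 are
#'   recommended for a stable median.
#' @return list with \code{lambda} and \code{nTests}.
#' @export
genomicInflation <- function(pValues) {
    p <- pValues[!is.na(pValues)]
    if (length(p) < 2L)
        stop("at least 2 p values are required")
    if (any(p < 0 | p > 1))
        stop("p values must lie in [0, 1]")
    lambda <- median(qchisq(p, df = 1L, lower.tail = FALSE)) /
        qchisq(0.5, df = 1L)
    list(lambda = lambda, nTests = length(p))
}

#' Select and clump association loci
#'
#' Retains SNPs with \code{p <= suggestiveP} and greedily clumps them:
#' the best remaining p value becomes a locus index and retained SNPs on
#' the same chromosome within \code{clumpKb} kilobases join its clump.
#' Tiers are inclusive: \code{genome_wide} iff \code{p <= gwP}
#' (default 5e-8), otherwise \code{suggestive}.  Ties in p are broken by
#' SNP id so the result does not depend on input order.
#'
#' @param results data.frame with \code{snp_id}, \code{chrom},
#'   \code{pos} and a p-value column (\code{p_meta} or \code{p}).
#' @param suggestiveP retention threshold (default 1e-6).
#' @param gwP genome-wide significance threshold (default 5e-8).
#' @param clumpKb clump half-window in kb (default 500).
#' @return data.frame of loci: \code{index_snp}, \code{chrom},
#'   \code{pos}, \code{p}, \code{tier}, \code{n_clumped},
#'   \code{clumped_snps} (comma-separated).
#' @export
selectLoci <- function(results, suggestiveP = 1e-6, gwP = 5e-8,
                       clumpKb = 500) {
    pcol <- if ("p_meta" %in% names(results)) "p_meta" else "p"
    d <- results[!is.na(results[[pcol]]) &
                 results[[pcol]] <= suggestiveP, , drop = FALSE]
    if (!nrow(d))
        return(data.frame(index_snp = character(), chrom = character(),
                          pos = integer(), p = numeric(),
                          tier = character(), n_clumped = integer(),
                          clumped_snps = character()))
    d <- d[order(d[[pcol]], d$snp_id), , drop = FALSE]
    win <- clumpKb * 1000
    used <- rep(FALSE, nrow(d))
    loci <- list()
    for (i in seq_len(nrow(d))) {
        if (used[i]) next
        member <- !used & d$chrom == d$chrom[i] &
            abs(d$pos - d$pos[i]) <= win
        used[member] <- TRUE
        p <- d[[pcol]][i]
        loci[[length(loci) + 1L]] <- data.frame(
            index_snp = d$snp_id[i], chrom = d$chrom[i], pos = d$pos[i],
            p = p,
            tier = if (p <= gwP) "genome_wide" else "suggestive",
            n_clumped = sum(member),
            clumped_snps = paste(sort(d$snp_id[member]), collapse = ","),
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, loci)
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' QQ-plot coordinates for a set of p values
#'
#' @param pValues numeric p values.
#' @return data.frame of expected and observed \code{-log10(p)},
#'   ascending.
#' @export
qqCoordinates <- function(pValues) {
    p <- sort(pValues[!is.na(pValues)])
    data.frame(expected = -log10(ppoints(length(p))),
               observed = -log10(p))
}
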