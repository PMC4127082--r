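## cis-eSNP mapping: SNP-gene pairing within a genomic window and an
## additive-dosage association scan between genotype and expression.

#' Enumerate cis SNP-gene pairs
#'
#' A pair is emitted iff the SNP lies on the same chromosome as the gene
#' and the arithmetic distance from the SNP position to the gene body
#' interval is at most \code{windowBp} (inclusive; 0 inside the
#' interval).  SNP positions are 1-based points; gene intervals are the
#' package's internal 1-based closed convention (BED input is converted
#' on read).
#'
#' @param snpMap \link[GenomicRanges]{GRanges} of SNP positions (named).
#' @param genes \link[GenomicRanges]{GRanges} of gene bodies (named).
#' @param windowBp cis window in base pairs (default 1e6).
#' @return data.frame with \code{snp_id}, \code{gene_id},
#'   \code{distance_bp}.
#' @export
cisPairs <- function(snpMap, genes, windowBp = 1e6) {
    .checkSeqlevels(snpMap, genes, c("SNP map", "gene annotation"))
    ## maxgap over-captures by one base relative to the arithmetic
    ## distance; the exact inclusive filter is applied after.
    hits <- findOverlaps(snpMap, genes, maxgap = windowBp)
    if (!length(hits))
        return(data.frame(snp_id = character(), gene_id = character(),
                          distance_bp = numeric()))
    sIdx <- queryHits(hits); gIdx <- subjectHits(hits)
    dist <- .pointIntervalDistance(start(snpMap)[sIdx],
                                   start(genes)[gIdx], end(genes)[gIdx])
    keep <- dist <= windowBp
    out <- data.frame(snp_id = names(snpMap)[sIdx][keep],
                      gene_id = names(genes)[gIdx][keep],
                      distance_bp = dist[keep],
                      stringsAsFactors = FALSE)
    out <- out[order(out$snp_id, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Genotype-expression association scan over cis pairs
#'
#' For each pair, expression is regressed on additive dosage over the
#' subjects shared by the two data sets.  The default 1-df statistic is
#' the score form \eqn{n r^2} (chi-square with 1 df under the null);
#' \code{test = "genotypic"} uses the 2-df genotype-class model
#' \eqn{n R^2}.  Pairs whose SNP has fewer than two genotype classes
#' among shared subjects are flagged untested; a constant expression
#' vector yields statistic 0 and p = 1.
#'
#' @param genotypes a [GenotypeExperiment-class].
#' @param expr an [ExpressionExperiment-class].
#' @param pairs data.frame from [cisPairs()].
#' @param test \code{"additive"} (1 df) or \code{"genotypic"} (2 df).
#' @return data.frame with \code{snp_id}, \code{gene_id},
#'   \code{distance_bp}, \code{stat}, \code{df}, \code{p},
#'   \code{tested}.
#' @export
esnpScan <- function(genotypes, expr, pairs,
                     test = c("additive", "genotypic")) {
    test <- match.arg(test)
    shared <- intersect(colnames(genotypes), colnames(expr))
    if (!length(shared))
        stop("no subjects shared between genotype and expression data")
    G <- dosages(genotypes)[, shared, drop = FALSE]
    E <- exprValues(expr)[, shared, drop = FALSE]
    n <- length(shared)

    stat <- df <- p <- rep(NA_real_, nrow(pairs))
    tested <- rep(FALSE, nrow(pairs))

    if (test == "additive") {
        ## standardized rows once; per-SNP matrix-vector products over
        ## that SNP's cis genes
        gSd <- apply(G, 1L, sd)
        eMean <- rowMeans(E); eSd <- apply(E, 1L, sd)
        Ez <- (E - eMean) / ifelse(eSd > 0, eSd, 1)
        bySnp <- split(seq_len(nrow(pairs)), pairs$snp_id)
        for (snp in names(bySnp)) {
            rows <- bySnp[[snp]]
            g <- G[snp, ]
            if (length(unique(g)) < 2L) next
            gz <- (g - mean(g)) / gSd[snp]
            gi <- pairs$gene_id[rows]
            r <- as.numeric(Ez[gi, , drop = FALSE] %*% gz) / (n - 1)
            r[eSd[gi] == 0] <- 0
            stat[rows] <- n * r^2
            df[rows] <- 1
            p[rows] <- pchisq(n * r^2, df = 1L, lower.tail = FALSE)
            p[rows][eSd[gi] == 0] <- 1
            stat[rows][eSd[gi] == 0] <- 0
            tested[rows] <- TRUE
        }
    } else {
        for (i in seq_len(nrow(pairs))) {
            g <- G[pairs$snp_id[i], ]
            classes <- length(unique(g))
            if (classes < 2L) next
            e <- E[pairs$gene_id[i], ]
            if (sd(e) == 0) {
                stat[i] <- 0; df[i] <- classes - 1L; p[i] <- 1
            } else {
                fit <- lm(e ~ factor(g))
                r2 <- summary(fit)$r.squared
                stat[i] <- n * r2
                df[i] <- classes - 1L
                p[i] <- pchisq(stat[i], df = df[i], lower.tail = FALSE)
            }
            tested[i] <- TRUE
        }
    }
    out <- cbind(pairs,
                 data.frame(stat = stat, df = df, p = p, tested = tested))
    rownames(out) <- NULL
    out
}

#' Call eSNPs at an FDR and a p-value ceiling
#'
#' Benjamini-Hochberg q values are computed over all tested pairs; a
#' pair is an eSNP iff \code{q <= fdr} and \code{p <= pMax} (both
#' inclusive; defaults 10\% FDR and 1e-4).
#'
#' @param results data.frame from [esnpScan()].
#' @param fdr FDR level (default 0.10).
#' @param pMax p-value ceiling (default 1e-4).
#' @return The input with columns \code{q} and \code{is_esnp} added.
#' @export
callEsnps <- function(results, fdr = 0.10, pMax = 1e-4) {
    if (!nrow(results)) {
        results$q <- numeric(0); results$is_esnp <- logical(0)
        return(results)
    }
    if (any(!is.na(results$p) & (results$p < 0 | results$p > 1)))
        stop("p values must lie in [0, 1]")
    q <- rep(NA_real_, nrow(results))
    q[results$tested] <- p.adjust(results$p[results$tested], method = "BH")
    results$q <- q
    results$is_esnp <- !is.na(q) & q <= fdr &
        !is.na(results$p) & results$p <= pMax
    results
}
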