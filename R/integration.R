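## Integration of the GWAS, coexpression, and eSNP layers: the locus ->
## module tagging rule, enrichment of loci tagging a module over a
## positional null, and module enrichment for disease-associated eSNPs.

#' Tag coexpression modules with GWAS loci
#'
#' A locus tags a module iff the module contains a gene whose body lies
#' within \code{windowBp} (inclusive) of the locus index SNP position.
#' One locus may tag several modules; for each (locus, module) tag the
#' nearest member gene is recorded as witness.  Genes lacking
#' coordinates are excluded with a warning.
#'
#' @param loci data.frame from [selectLoci()].
#' @param modules a [ModuleAssignment-class] (or named character of
#'   gene -> module labels); \code{"grey"} genes never generate tags.
#' @param genes \link[GenomicRanges]{GRanges} of gene bodies, named.
#' @param windowBp tagging window in base pairs (default 250000).
#' @return data.frame with \code{index_snp}, \code{module},
#'   \code{witness_gene}, \code{distance_bp}.
#' @export
tagModules <- function(loci, modules, genes, windowBp = 250000) {
    labels <- if (is(modules, "ModuleAssignment")) moduleLabels(modules)
              else modules
    missing <- setdiff(names(labels), names(genes))
    if (length(missing)) {
        warning(sprintf("%d gene(s) lack coordinates and were excluded",
                        length(missing)))
        labels <- labels[!names(labels) %in% missing]
    }
    labels <- labels[labels != "grey"]
    if (!nrow(loci) || !length(labels))
        return(data.frame(index_snp = character(), module = character(),
                          witness_gene = character(),
                          distance_bp = numeric()))
    g <- genes[names(labels)]
    rows <- list()
    for (i in seq_len(nrow(loci))) {
        onChrom <- as.character(seqnames(g)) == loci$chrom[i]
        if (!any(onChrom)) next
        dist <- .pointIntervalDistance(loci$pos[i],
                                       start(g)[onChrom], end(g)[onChrom])
        lab <- labels[onChrom]
        for (m in unique(lab[dist <= windowBp])) {
            dm <- dist[lab == m]
            wg <- names(g)[onChrom][lab == m][which.min(dm)]
            rows[[length(rows) + 1L]] <- data.frame(
                index_snp = loci$index_snp[i], module = m,
                witness_gene = wg, distance_bp = min(dm),
                stringsAsFactors = FALSE)
        }
    }
    out <- if (length(rows)) do.call(rbind, rows)
           else data.frame(index_snp = character(), module = character(),
                           witness_gene = character(),
                           distance_bp = numeric())
    rownames(out) <- NULL
    out
}

#' Enrichment of GWAS loci tagging a module
#'
#' For each tagged module the observed count is the number of loci
#' tagging it.  The null probability \code{p0} that a random locus
#' would tag the module is the fraction of all tested SNP positions
#' lying within \code{windowBp} of any module gene; the expected count
#' is \code{p0 * nLoci}, fold enrichment is observed/expected, and the
#' p value is the upper tail of Binomial(nLoci, p0) at the observed
#' count.  q values are Benjamini-Hochberg over the modules tested.
#'
#' @param tags data.frame from [tagModules()].
#' @param loci data.frame from [selectLoci()].
#' @param modules a [ModuleAssignment-class] or gene -> label vector.
#' @param genes \link[GenomicRanges]{GRanges} of gene bodies, named.
#' @param snpMap \link[GenomicRanges]{GRanges} of all tested SNP
#'   positions (the candidate-locus background).
#' @param windowBp tagging window (default 250000).
#' @param candidates modules to report (default: the tagged modules; an
#'   untagged candidate gets observed = 0, fold = 0, p = 1).
#' @return data.frame with \code{module}, \code{observed},
#'   \code{expected}, \code{fold}, \code{p}, \code{q}.
#' @export
taggingEnrichment <- function(tags, loci, modules, genes, snpMap,
                              windowBp = 250000, candidates = NULL) {
    if (!nrow(loci))
        stop("at least one locus is required")
    labels <- if (is(modules, "ModuleAssignment")) moduleLabels(modules)
              else modules
    labels <- labels[labels != "grey" & names(labels) %in% names(genes)]
    nLoci <- nrow(loci)
    mods <- if (is.null(candidates)) sort(unique(tags$module))
            else sort(unique(candidates))
    if (!length(mods))
        return(data.frame(module = character(), observed = integer(),
                          expected = numeric(), fold = numeric(),
                          p = numeric(), q = numeric()))
    rows <- lapply(mods, function(m) {
        obs <- length(unique(tags$index_snp[tags$module == m]))
        mg <- genes[names(labels)[labels == m]]
        near <- rep(FALSE, length(snpMap))
        sameChrom <- as.character(seqnames(snpMap)) %in%
            as.character(seqnames(mg))
        if (any(sameChrom)) {
            pos <- start(snpMap)[sameChrom]
            hit <- rep(FALSE, length(pos))
            for (j in seq_along(mg)) {
                onC <- as.character(seqnames(snpMap))[sameChrom] ==
                    as.character(seqnames(mg))[j]
                d <- .pointIntervalDistance(pos, start(mg)[j], end(mg)[j])
                hit <- hit | (onC & d <= windowBp)
            }
            near[sameChrom] <- hit
        }
        p0 <- mean(near)
        if (p0 == 0 && obs > 0)
            stop(sprintf(
                "module '%s': tagged by %d loci but no SNP position falls within the window (annotation inconsistency)",
                m, obs))
        expected <- p0 * nLoci
        data.frame(module = m, observed = obs, expected = expected,
                   fold = if (obs == 0) 0 else obs / expected,
                   p = if (obs == 0) 1
                       else pbinom(obs - 1L, nLoci, p0, lower.tail = FALSE),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- p.adjust(out$p, method = "BH")
    rownames(out) <- NULL
    out
}

#' Module enrichment for disease-associated eSNPs
#'
#' A gene \emph{carries a disease eSNP} iff some called eSNP pair
#' targets it and that SNP's disease-association p value is at most
#' \code{diseaseP}.  For each candidate module a one-sided Fisher's
#' exact test (hypergeometric upper tail) is computed on the 2x2 table
#' of module membership x disease-eSNP carriage over the
#' expression-profiled gene universe; fold enrichment is the in-module
#' carrier fraction over the universe carrier fraction.  q values are
#' Benjamini-Hochberg across the candidate modules.
#'
#' @param esnps data.frame from [callEsnps()].
#' @param gwas data.frame of disease association results with
#'   \code{snp_id} and \code{p_meta} (or \code{p}).
#' @param modules a [ModuleAssignment-class] or gene -> label vector;
#'   its genes define the universe.
#' @param candidates character of candidate module labels (typically
#'   the modules with at least one tag); default: all non-grey modules.
#' @param diseaseP nominal disease-association threshold (default
#'   0.01).
#' @return data.frame with \code{module}, \code{observed},
#'   \code{expected}, \code{fold}, \code{p}, \code{q} and the 2x2
#'   counts \code{n11}, \code{n12}, \code{n21}, \code{n22}.
#' @export
arEsnpModuleEnrichment <- function(esnps, gwas, modules,
                                   candidates = NULL, diseaseP = 0.01) {
    labels <- if (is(modules, "ModuleAssignment")) moduleLabels(modules)
              else modules
    universe <- names(labels)
    if (!length(universe))
        stop("empty gene universe")
    if (is.null(candidates))
        candidates <- sort(unique(labels[labels != "grey"]))
    pcol <- if ("p_meta" %in% names(gwas)) "p_meta" else "p"
    diseaseSnps <- gwas$snp_id[!is.na(gwas[[pcol]]) &
                               gwas[[pcol]] <= diseaseP]
    carriers <- unique(esnps$gene_id[esnps$is_esnp &
                                     esnps$snp_id %in% diseaseSnps])
    carriers <- intersect(carriers, universe)
    K <- length(carriers)
    N <- length(universe)
    if (!length(candidates))
        return(data.frame(module = character(), observed = integer(),
                          expected = numeric(), fold = numeric(),
                          p = numeric(), q = numeric(), n11 = integer(),
                          n12 = integer(), n21 = integer(),
                          n22 = integer()))
    rows <- lapply(candidates, function(m) {
        mg <- universe[labels == m]
        a <- length(intersect(mg, carriers))
        tab <- c(n11 = a, n12 = length(mg) - a,
                 n21 = K - a, n22 = N - length(mg) - (K - a))
        expected <- length(mg) * K / N
        fold <- if (a == 0) 0 else (a / length(mg)) / (K / N)
        p <- if (K == 0) 1
             else .hyperUpperTail(a, K, N, length(mg))
        data.frame(module = m, observed = a, expected = expected,
                   fold = fold, p = p,
                   n11 = tab[1], n12 = tab[2], n21 = tab[3], n22 = tab[4],
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- p.adjust(out$p, method = "BH")
    out <- out[, c("module", "observed", "expected", "fold", "p", "q",
                   "n11", "n12", "n21", "n22")]
    rownames(out) <- NULL
    out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; values are validated to lie in [0, 1].
#'
#' @param pValues numeric p values.
#' @return numeric adjusted values.
#' @export
bhAdjust <- function(pValues) {
    if (any(!is.na(pValues) & (pValues < 0 | pValues > 1)))
        stop("p values must lie in [0, 1]")
    p.adjust(pValues, method = "BH")
}
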