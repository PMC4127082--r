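## Plain-text interchange: TSV is the lingua franca between stages; VCF
## (1-based, GT field) and BED (0-based half-open) writers/readers
## normalize to the package's internal 1-based point/interval
## convention.

.writeTsv <- function(d, path, comments = character()) {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(comments))
        writeLines(paste0("# ", comments), con)
    write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.readTsv <- function(path) {
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
               check.names = FALSE)
}

#' Write and read the SNP map (TSV; 1-based positions)
#'
#' Columns: \code{chrom}, \code{pos}, \code{snp_id}, \code{ref},
#' \code{alt}.
#'
#' @param snpMap named \link[GenomicRanges]{GRanges} of SNP positions.
#' @param path file path.
#' @return \code{writeSnpMap}: the path, invisibly; \code{readSnpMap}: a
#'   named GRanges.
#' @export
writeSnpMap <- function(snpMap, path) {
    .writeTsv(data.frame(chrom = as.character(seqnames(snpMap)),
                         pos = start(snpMap),
                         snp_id = names(snpMap),
                         ref = mcols(snpMap)$ref,
                         alt = mcols(snpMap)$alt), path)
}

#' @rdname writeSnpMap
#' @export
readSnpMap <- function(path) {
    d <- .readTsv(path)
    gr <- GRanges(d$chrom, IRanges(d$pos, width = 1L),
                  ref = d$ref, alt = d$alt)
    names(gr) <- d$snp_id
    gr
}

#' Write and read a dosage matrix (TSV)
#'
#' Rows are SNPs (first column \code{snp_id}), remaining columns are
#' subjects.
#'
#' @param genotypes a [GenotypeExperiment-class] (write) or dosage TSV
#'   path (read).
#' @param path file path.
#' @param snpMap a GRanges from [readSnpMap()].
#' @param group named or unnamed per-subject group labels (single group
#'   assumed when omitted).
#' @return \code{readGenotypes}: a [GenotypeExperiment-class].
#' @export
writeGenotypes <- function(genotypes, path) {
    d <- dosages(genotypes)
    .writeTsv(data.frame(snp_id = rownames(d), d, check.names = FALSE),
              path)
}

#' @rdname writeGenotypes
#' @export
readGenotypes <- function(path, snpMap, group = NULL) {
    d <- .readTsv(path)
    m <- as.matrix(d[, -1L, drop = FALSE])
    rownames(m) <- d$snp_id
    storage.mode(m) <- "integer"
    if (is.null(group))
        group <- rep("group1", ncol(m))
    GenotypeExperiment(m, snpMap[rownames(m)], group)
}

#' Write genotypes as VCF (v4.2, GT field, 1-based positions)
#'
#' Dosages 0/1/2 of the alternate (effect) allele become GT values
#' \code{0/0}, \code{0/1}, \code{1/1}.
#'
#' @param genotypes a [GenotypeExperiment-class].
#' @param path output path (plain text).
#' @return Invisibly, \code{path}.
#' @export
writeVcf <- function(genotypes, path) {
    d <- dosages(genotypes)
    gr <- snpRanges(genotypes)
    gt <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow(d), ncol(d))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##source=ariNet",
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", colnames(d)),
                       collapse = "\t")), con)
    body <- cbind(as.character(seqnames(gr)), start(gr), names(gr),
                  mcols(gr)$ref, mcols(gr)$alt, ".", "PASS", ".", "GT", gt)
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
    invisible(path)
}

#' Read a VCF with GT calls into a GenotypeExperiment
#'
#' Uses \pkg{vcfR} for parsing; the alternate allele is counted as the
#' effect allele.
#'
#' @param path VCF path.
#' @param group optional per-subject group labels.
#' @return A [GenotypeExperiment-class].
#' @export
readVcfDosage <- function(path, group = NULL) {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("reading VCF requires the 'vcfR' package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    count <- function(x) {
        a <- strsplit(x, "[/|]")
        vapply(a, function(p) sum(p != "0" & p != "."), 0L)
    }
    m <- apply(gt, 2L, count)
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(gt),
                                     dimnames = dimnames(gt))
    rownames(m) <- v@fix[, "ID"]
    storage.mode(m) <- "integer"
    gr <- GRanges(v@fix[, "CHROM"],
                  IRanges(as.integer(v@fix[, "POS"]), width = 1L),
                  ref = v@fix[, "REF"], alt = v@fix[, "ALT"])
    names(gr) <- rownames(m)
    if (is.null(group))
        group <- rep("group1", ncol(m))
    GenotypeExperiment(m, gr, group)
}

#' Write and read gene annotation as BED (0-based half-open)
#'
#' Internal gene intervals are 1-based closed; on write, start is
#' decremented; on read, it is incremented back.
#'
#' @param genes named \link[GenomicRanges]{GRanges} (write) or BED path
#'   (read).
#' @param path file path.
#' @return \code{readBedGenes}: a named GRanges.
#' @export
writeBedGenes <- function(genes, path) {
    d <- data.frame(chrom = as.character(seqnames(genes)),
                    start = start(genes) - 1L,
                    end = end(genes),
                    name = names(genes))
    write.table(d, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeBedGenes
#' @export
readBedGenes <- function(path) {
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
        gr <- rtracklayer::import(path, format = "BED")
        names(gr) <- mcols(gr)$name
        mcols(gr) <- NULL
        return(gr)
    }
    d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(d)[1:4] <- c("chrom", "start", "end", "name")
    gr <- GRanges(d$chrom, IRanges(d$start + 1L, d$end))
    names(gr) <- d$name
    gr
}

#' Write and read an expression matrix (TSV)
#'
#' Rows are genes (first column \code{gene_id}), remaining columns are
#' samples.
#'
#' @param expr an [ExpressionExperiment-class] (write) or TSV path
#'   (read).
#' @param path file path.
#' @param genes a named GRanges of gene bodies (read).
#' @return \code{readExpression}: an [ExpressionExperiment-class].
#' @export
writeExpression <- function(expr, path) {
    m <- exprValues(expr)
    .writeTsv(data.frame(gene_id = rownames(m), m, check.names = FALSE),
              path)
}

#' @rdname writeExpression
#' @export
readExpression <- function(path, genes) {
    d <- .readTsv(path)
    m <- as.matrix(d[, -1L, drop = FALSE])
    rownames(m) <- d$gene_id
    ExpressionExperiment(m, genes[rownames(m)])
}

#' Export a module dendrogram in Newick format
#'
#' @param modules a [ModuleAssignment-class].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeDendrogramNewick <- function(modules, path) {
    phy <- ape::as.phylo(moduleDendrogram(modules))
    ape::write.tree(phy, file = path)
    invisible(path)
}

#' Write the planted ground truth (long-format TSV)
#'
#' Records of type \code{causal_snp}, \code{module_label},
#' \code{esnp_pair} and \code{disease_module}.
#'
#' @param truth a [GroundTruth-class].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeGroundTruth <- function(truth, path) {
    rows <- rbind(
        data.frame(record = "causal_snp", snp_id = causalSnpIds(truth),
                   gene_id = NA_character_, value = NA_character_),
        data.frame(record = "module_label", snp_id = NA_character_,
                   gene_id = names(plantedModules(truth)),
                   value = unname(plantedModules(truth))),
        if (nrow(esnpPairs(truth)))
            data.frame(record = "esnp_pair",
                       snp_id = esnpPairs(truth)$snp_id,
                       gene_id = esnpPairs(truth)$gene_id,
                       value = as.character(esnpPairs(truth)$beta)),
        data.frame(record = "disease_module", snp_id = NA_character_,
                   gene_id = NA_character_, value = diseaseModule(truth)))
    .writeTsv(rows, path)
}
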