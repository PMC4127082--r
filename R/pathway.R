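## Gene-set (GO-style) enrichment of module gene lists against a
## user-supplied GMT collection.

#' Read a GMT gene-set collection
#'
#' One set per tab-separated line: set name, description, then gene
#' ids.  Duplicate gene ids within a line are de-duplicated; duplicate
#' set names or lines with fewer than three fields are errors naming
#' the offending line.
#'
#' @param path path to a GMT file (or a character vector of GMT lines).
#' @return A [GeneSets-class].
#' @examples
#' gmt <- system.file("extdata", "gene_sets_synthetic_demo.gmt",
#'                    package = "ariNet")
#' readGmt(gmt)
#' @export
readGmt <- function(path) {
    lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
             else path
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3L)
    if (length(short))
        stop(sprintf("GMT line %d has fewer than 3 fields", short[1]))
    nm <- vapply(fields, `[[`, "", 1L)
    dup <- nm[duplicated(nm)]
    if (length(dup))
        stop("duplicate set name(s): ", paste(unique(dup), collapse = ", "))
    sets <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(sets) <- nm
    new("GeneSets", sets = sets,
        descriptions = setNames(vapply(fields, `[[`, "", 2L), nm))
}

#' Write a GeneSets collection as GMT
#'
#' @param x a [GeneSets-class].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeGmt <- function(x, path) {
    stopifnot(is(x, "GeneSets"))
    lines <- vapply(names(geneSets(x)), function(nm)
        paste(c(nm, setDescriptions(x)[[nm]], geneSets(x)[[nm]]),
              collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}

#' Gene-set enrichment of one module
#'
#' Each set is intersected with the universe; the one-sided Fisher's
#' exact p (hypergeometric upper tail) is computed on the 2x2 table of
#' module membership x set membership over the universe, and fold
#' enrichment is \code{(overlap/moduleSize) / (setSize/universeSize)}.
#' q values are Benjamini-Hochberg across the sets tested.
#'
#' @param moduleGenes character, gene ids of the module (must be a
#'   subset of the universe).
#' @param collection a [GeneSets-class].
#' @param universe character, the gene universe (typically all
#'   annotated genes on the expression platform).
#' @return data.frame with \code{set_name}, \code{overlap},
#'   \code{set_size}, \code{module_size}, \code{fold}, \code{p},
#'   \code{q}.
#' @export
enrichModule <- function(moduleGenes, collection, universe) {
    stopifnot(is(collection, "GeneSets"))
    if (!length(universe))
        stop("empty universe")
    if (!length(moduleGenes))
        stop("empty module")
    if (!all(moduleGenes %in% universe))
        stop("module genes must be a subset of the universe")
    N <- length(universe)
    nMod <- length(moduleGenes)
    rows <- lapply(names(geneSets(collection)), function(nm) {
        s <- intersect(geneSets(collection)[[nm]], universe)
        K <- length(s)
        a <- length(intersect(moduleGenes, s))
        fold <- if (a == 0 || K == 0) 0 else (a / nMod) / (K / N)
        p <- if (K == 0) 1
             else .hyperUpperTail(a, K, N, nMod)
        data.frame(set_name = nm, overlap = a, set_size = K,
                   module_size = nMod, fold = fold, p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- p.adjust(out$p, method = "BH")
    rownames(out) <- NULL
    out
}

#' Gene-set enrichment of every module
#'
#' Applies [enrichModule()] to each non-grey module and adjusts q
#' values across all (module, set) tests jointly.
#'
#' @param modules a [ModuleAssignment-class] or gene -> label vector.
#' @param collection a [GeneSets-class].
#' @param universe gene universe; default all genes in \code{modules}.
#' @return data.frame with a \code{module} column prepended.
#' @export
enrichModules <- function(modules, collection, universe = NULL) {
    labels <- if (is(modules, "ModuleAssignment")) moduleLabels(modules)
              else modules
    if (is.null(universe))
        universe <- names(labels)
    mods <- sort(unique(labels[labels != "grey"]))
    rows <- lapply(mods, function(m) {
        res <- enrichModule(names(labels)[labels == m], collection,
                            universe)
        cbind(module = m, res, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- p.adjust(out$p, method = "BH")
    rownames(out) <- NULL
    out
}
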