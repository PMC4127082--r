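## Internal helpers shared across modules.

## One master seed, one derived stream per stage.  The derivation is a
## fixed affine map kept inside 32-bit integer range so a run is fully
## reproducible from the master seed alone.
.stageSeed <- function(seed, stage) {
    offsets <- c(genotypes = 11L, phenotype = 23L, expression = 37L,
                 truth = 41L, randomize = 53L, genesets = 67L)
    if (!stage %in% names(offsets))
        stop("unknown stage: ", stage)
    as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

## Arithmetic distance from a 1-based point to 1-based closed intervals:
## 0 inside, otherwise base pairs to the nearest edge.  Used for the cis
## window and the locus tagging window, whose boundary semantics are
## inclusive at exactly the window size.
.pointIntervalDistance <- function(pos, start, end) {
    d <- pmax(start - pos, pos - end)
    pmax(d, 0)
}

## Normalize chromosome naming between two GRanges-like sources; error if
## the naming conventions cannot be reconciled.
.checkSeqlevels <- function(a, b, what = c("SNP map", "gene annotation")) {
    la <- unique(as.character(seqnames(a)))
    lb <- unique(as.character(seqnames(b)))
    if (length(la) && length(lb) && !length(intersect(la, lb)))
        stop(sprintf(
            "chromosome naming mismatch between %s (%s) and %s (%s)",
            what[1], paste(head(la, 3), collapse = ","),
            what[2], paste(head(lb, 3), collapse = ",")))
    invisible(TRUE)
}

.padIds <- function(prefix, n) {
    sprintf(paste0(prefix, "%0", max(4L, nchar(n)), "d"), seq_len(n))
}

## Deterministic non-cryptographic hash of a config for the run manifest.
.configHash <- function(x) {
    s <- paste(deparse(x), collapse = "")
    bytes <- utf8ToInt(s)
    h <- 0
    for (b in bytes) h <- (h * 31 + b) %% 2147483647
    sprintf("%08x", as.integer(h))
}

## One-sided Fisher's exact test for enrichment = hypergeometric upper
## tail: P(X >= a) with X ~ Hypergeometric(N, K, n).  Shared by the
## module-eSNP and gene-set enrichment tests.
.hyperUpperTail <- function(a, K, N, n) {
    phyper(a - 1L, K, N - K, n, lower.tail = FALSE)
}

.asMatrix <- function(x) {
    if (is(x, "ExpressionExperiment")) exprValues(x)
    else if (is(x, "GenotypeExperiment")) dosages(x)
    else if (is.matrix(x)) x
    else stop("expected a matrix or an ariNet experiment container")
}
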