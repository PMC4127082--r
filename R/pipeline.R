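## One-call orchestration: simulate -> gwas -> meta -> loci ->
## coexpress -> esnp -> integrate -> pathway, with TSV stage outputs and
## a JSON manifest.  Rerunning with an identical configuration
## reproduces byte-identical outputs.

#' Run the integrated analysis pipeline on simulated data
#'
#' Executes all stages of the integrated analysis on data drawn from
#' \code{config}: genotype/phenotype/expression simulation, per-group
#' association scans with principal-component adjustment, sample-size
#' weighted meta-analysis, locus selection, coexpression network and
#' module detection, cis-eSNP mapping, module tagging and enrichment
#' statistics, and gene-set enrichment against a synthetic collection.
#' Every stage writes a TSV under \code{outDir} and the manifest
#' records the configuration hash, seeds, package version and
#' per-stage row counts.
#'
#' All thresholds default to the conventional values of this study
#' design: loci at p <= 1e-6 (genome-wide 5e-8), a 250 kb tagging
#' window, a 1 Mb cis window, 10\% eSNP FDR with p <= 1e-4, and
#' disease association at p <= 0.01.
#'
#' @param config a [SimulationConfig-class].
#' @param outDir output directory (created if needed).
#' @param suggestiveP,gwP,clumpKb locus selection thresholds.
#' @param tagWindowBp module tagging window.
#' @param cisWindowBp cis-eSNP window.
#' @param esnpFdr,esnpPMax eSNP calling thresholds.
#' @param diseaseP nominal disease-association threshold for
#'   disease-eSNP carriage.
#' @param nPcs principal components per group in the association scan.
#' @param minModuleSize,cutHeight module detection parameters.
#' @param randomizeMode optional \code{"labels"} or \code{"values"}:
#'   analyze a randomized expression matrix (network specificity
#'   control) instead of the simulated one.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config = simulationConfig(),
                        outDir,
                        suggestiveP = 1e-6, gwP = 5e-8, clumpKb = 500,
                        tagWindowBp = 250000, cisWindowBp = 1e6,
                        esnpFdr = 0.10, esnpPMax = 1e-4,
                        diseaseP = 0.01, nPcs = 10L,
                        minModuleSize = 30L, cutHeight = 0.99,
                        randomizeMode = NULL) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(
        package = "ariNet",
        version = as.character(packageVersion("ariNet")),
        config = lapply(slotNames(config), function(s) slot(config, s)),
        configHash = .configHash(lapply(slotNames(config),
                                        function(s) slot(config, s))),
        seed = config@seed,
        thresholds = list(suggestive_p = suggestiveP, gw_p = gwP,
                          clump_kb = clumpKb, tag_window_bp = tagWindowBp,
                          cis_window_bp = cisWindowBp, esnp_fdr = esnpFdr,
                          esnp_p_max = esnpPMax, disease_p = diseaseP),
        stages = list())
    names(manifest$config) <- slotNames(config)

    writeManifest <- function() {
        jsonlite::write_json(manifest,
                             file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    runStage <- function(name, fun) {
        res <- tryCatch(fun(), error = function(e) {
            writeManifest()
            stop(sprintf("stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE)
        })
        manifest$stages[[name]] <<- res$rows
        res$value
    }

    env <- new.env()
    ## 1. simulate -------------------------------------------------------
    sim <- runStage("simulate", function() {
        geno <- simulateGenotypes(config)
        pheno <- simulatePhenotype(geno, config)
        se <- simulateExpression(geno, config)
        writeSnpMap(snpRanges(geno), file.path(outDir, "snp_map.tsv"))
        writeGenotypes(geno, file.path(outDir, "dosage.tsv"))
        .writeTsv(pheno, file.path(outDir, "phenotype.tsv"))
        writeBedGenes(geneRanges(se$expression),
                      file.path(outDir, "genes.bed"))
        writeExpression(se$expression, file.path(outDir, "expression.tsv"))
        writeGroundTruth(se$truth, file.path(outDir, "ground_truth.tsv"))
        list(value = list(geno = geno, pheno = pheno,
                          expr = se$expression, truth = se$truth),
             rows = list(snps = nrow(geno), subjects = ncol(geno),
                         genes = nrow(se$expression)))
    })

    ## 2. gwas -----------------------------------------------------------
    assoc <- runStage("gwas", function() {
        a <- associationScan(sim$geno, sim$pheno, nPcs = nPcs)
        .writeTsv(a, file.path(outDir, "association.tsv"))
        list(value = a, rows = list(tests = nrow(a)))
    })

    ## 3. meta -----------------------------------------------------------
    meta <- runStage("meta", function() {
        m <- metaAnalyze(assoc)
        lam <- genomicInflation(m$p_meta)
        .writeTsv(m, file.path(outDir, "meta.tsv"),
                  comments = sprintf("lambda=%.6f", lam$lambda))
        .writeTsv(qqCoordinates(m$p_meta),
                  file.path(outDir, "qq_meta.tsv"))
        list(value = list(meta = m, lambda = lam),
             rows = list(snps = nrow(m)))
    })

    ## 4. loci -----------------------------------------------------------
    loci <- runStage("loci", function() {
        groupLoci <- selectLoci(assoc, suggestiveP, gwP, clumpKb)
        metaLoci <- selectLoci(meta$meta, suggestiveP, gwP, clumpKb)
        ## a locus qualifies via any group or the meta-analysis; merge by
        ## greedy clumping over the union
        pool <- rbind(groupLoci[, c("index_snp", "chrom", "pos", "p")],
                      metaLoci[, c("index_snp", "chrom", "pos", "p")])
        merged <- if (nrow(pool)) {
            pool <- pool[order(pool$p, pool$index_snp), , drop = FALSE]
            names(pool)[1] <- "snp_id"
            selectLoci(pool, suggestiveP, gwP, clumpKb)
        } else groupLoci
        .writeTsv(merged, file.path(outDir, "loci.tsv"))
        list(value = merged, rows = list(loci = nrow(merged)))
    })

    ## 5. coexpress ------------------------------------------------------
    coex <- runStage("coexpress", function() {
        e <- sim$expr
        if (!is.null(randomizeMode))
            e <- randomizeExpression(e, mode = randomizeMode,
                                     seed = config@seed)
        e <- preprocessExpression(e, log2Transform = FALSE)
        st <- pickSoftThreshold(e)
        net <- computeTom(e, st$power)
        net@scaleFreeFit <- st$fitTable
        mods <- detectModules(net, minModuleSize = minModuleSize,
                              cutHeight = cutHeight)
        .writeTsv(st$fitTable, file.path(outDir, "scale_free_fit.tsv"))
        .writeTsv(data.frame(gene_id = names(moduleLabels(mods)),
                             module = unname(moduleLabels(mods)),
                             k = unname(connectivity(net))),
                  file.path(outDir, "modules.tsv"),
                  comments = sprintf("beta=%g", st$power))
        writeDendrogramNewick(mods, file.path(outDir, "dendrogram.nwk"))
        list(value = list(expr = e, net = net, modules = mods),
             rows = list(modules = sum(names(moduleSizes(mods)) != "grey"),
                         grey = sum(moduleLabels(mods) == "grey")))
    })

    ## 6. esnp -----------------------------------------------------------
    esnp <- runStage("esnp", function() {
        pairs <- cisPairs(snpRanges(sim$geno), geneRanges(sim$expr),
                          windowBp = cisWindowBp)
        res <- esnpScan(sim$geno, coex$expr, pairs)
        res <- callEsnps(res, fdr = esnpFdr, pMax = esnpPMax)
        .writeTsv(res[res$is_esnp, , drop = FALSE],
                  file.path(outDir, "esnps.tsv"),
                  comments = sprintf("cis_window_bp=%d; fdr=%g; p_max=%g",
                                     as.integer(cisWindowBp), esnpFdr,
                                     esnpPMax))
        list(value = res,
             rows = list(pairs = nrow(res), esnps = sum(res$is_esnp)))
    })

    ## 7. integrate ------------------------------------------------------
    integ <- runStage("integrate", function() {
        genes <- geneRanges(sim$expr)
        if (nrow(loci)) {
            tags <- tagModules(loci, coex$modules, genes,
                               windowBp = tagWindowBp)
            tagEnr <- if (nrow(tags))
                taggingEnrichment(tags, loci, coex$modules, genes,
                                  snpRanges(sim$geno),
                                  windowBp = tagWindowBp)
            else data.frame()
            cand <- unique(tags$module)
        } else {
            tags <- data.frame(); tagEnr <- data.frame(); cand <- character()
        }
        esnpEnr <- if (length(cand))
            arEsnpModuleEnrichment(esnp, meta$meta, coex$modules,
                                   candidates = cand, diseaseP = diseaseP)
        else data.frame()
        hdr <- sprintf("window_bp=%d; disease_p=%g",
                       as.integer(tagWindowBp), diseaseP)
        .writeTsv(tags, file.path(outDir, "module_tags.tsv"),
                  comments = hdr)
        .writeTsv(tagEnr, file.path(outDir, "tagging_enrichment.tsv"),
                  comments = hdr)
        .writeTsv(esnpEnr, file.path(outDir, "esnp_enrichment.tsv"),
                  comments = hdr)
        list(value = list(tags = tags, taggingEnrichment = tagEnr,
                          esnpEnrichment = esnpEnr),
             rows = list(tags = nrow(tags),
                         candidate_modules = length(cand)))
    })

    ## 8. pathway --------------------------------------------------------
    path <- runStage("pathway", function() {
        sets <- syntheticGeneSets(sim$truth, seed = config@seed)
        writeGmt(sets, file.path(outDir, "gene_sets_synthetic.gmt"))
        enr <- enrichModules(coex$modules, sets)
        .writeTsv(enr, file.path(outDir, "pathway_enrichment.tsv"))
        list(value = enr, rows = list(tests = nrow(enr)))
    })

    writeManifest()
    invisible(list(sim = sim, association = assoc, meta = meta,
                   loci = loci, coexpression = coex, esnp = esnp,
                   integration = integ, pathway = path,
                   manifest = manifest))
}
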