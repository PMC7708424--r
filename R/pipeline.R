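## End-to-end orchestration: simulate (or load) -> define hits ->
## expand / propagate / score -> enrich -> summarize.

.allMethods <- c("complex", "ligand_receptor", "net_neighbor1",
    "net_neighbor2", "pathway_clique", "pathway_neighbor1",
    "pathway_neighbor2", "random", "hotnet", "pascal")

#' Expand proxy sets for one trait with the naive methods
#'
#' @param seeds seed genes (the trait's high-confidence hits).
#' @param kb a [KnowledgeBase-class].
#' @param traitId trait label.
#' @param methods subset of \code{complex}, \code{ligand_receptor},
#'   \code{net_neighbor1}, \code{net_neighbor2}, \code{pathway_clique},
#'   \code{pathway_neighbor1}, \code{pathway_neighbor2},
#'   \code{random}.
#' @param randomSize,randomSeed random baseline controls.
#' @return named list of [ProxySet-class].
#' @export
expandProxies <- function(seeds, kb, traitId = "trait",
        methods = c("complex", "ligand_receptor", "net_neighbor1",
            "net_neighbor2", "pathway_clique", "pathway_neighbor1",
            "pathway_neighbor2", "random"),
        randomSize = NULL, randomSeed = 1) {
    out <- list()
    for (m in methods) {
        out[[m]] <- switch(m,
            complex = complexProxies(seeds, kb@complexes, traitId),
            ligand_receptor = ligandReceptorProxies(seeds, kb@lrPairs,
                traitId),
            net_neighbor1 = suppressWarnings(networkNeighbors(seeds,
                kb@interactome, 1, traitId)),
            net_neighbor2 = suppressWarnings(networkNeighbors(seeds,
                kb@interactome, 2, traitId)),
            pathway_clique = pathwayCliqueProxies(seeds, kb@pathways,
                traitId),
            pathway_neighbor1 = pathwayNeighbors(seeds, kb@pathways, 1,
                traitId),
            pathway_neighbor2 = pathwayNeighbors(seeds, kb@pathways, 2,
                traitId),
            random = randomProxies(kb@universe, n = randomSize,
                seed = randomSeed, seeds = seeds, traitId = traitId),
            stop("unknown method: ", m))
    }
    out
}

#' Run the full pipeline on a synthetic world
#'
#' Classifies outcomes, defines high-confidence hits per trait, applies
#' the trait retention rule, expands every requested method, pools the
#' per-trait contingency tables per method with the
#' Cochran-Mantel-Haenszel framework, and (when gene scores are in
#' scope) computes sum gene scores, pathway enrichment and the
#' proxy gene-score distributions. Deterministic for fixed seeds.
#'
#' @param world a [SyntheticWorld-class] (or result of [readWorld()]).
#' @param methods methods to run (default: all ten).
#' @param beta restart probability for heat diffusion.
#' @param kMin minimum module size.
#' @param nPermDelta permutations for the module threshold.
#' @param nPermPathway permutations for the empirical pathway p-value.
#' @param seed master seed for the stochastic stages (random baseline,
#'   threshold permutations, empirical nulls).
#' @param traitBlacklist traits dropped before analysis.
#' @param outDir optional directory; when given, writes
#'   \code{hcgh.tsv}, \code{proxies.tsv}, \code{enrichment.tsv},
#'   \code{tables.tsv}, \code{gene_scores.tsv},
#'   \code{pathway_enrichment.tsv}, \code{score_distributions.tsv} and
#'   \code{run_manifest.yaml}.
#' @param verbose log stage-level counts with \code{message()}.
#' @return list with \code{hcgh} (per-trait hit sets), \code{traits}
#'   (retained), \code{outcomes}, \code{proxySets} (method -> trait ->
#'   [ProxySet-class]), \code{enrichment} (per-method pooled summary),
#'   \code{tables} (all corrected strata), \code{geneScores},
#'   \code{pathwayEnrichment}, \code{scoreDistributions}, and
#'   \code{manifest}.
#' @export
runPipeline <- function(world, methods = .allMethods, beta = 0.4,
                        kMin = 3, nPermDelta = 20, nPermPathway = 1000,
                        seed = 1, traitBlacklist = character(),
                        outDir = NULL, verbose = FALSE) {
    stopifnot(all(methods %in% .allMethods))
    kb <- world@kb
    say <- function(...) if (verbose) message(...)

    outcomes <- classifyTargetIndication(world@assets)
    say("outcomes: ", nrow(outcomes), " target-indication pairs")

    hcghSets <- defineHcghsByTrait(world@coloc, kb@universe,
        blacklist = traitBlacklist)
    traits <- retainTraits(hcghSets, outcomes, world@traitIndication)
    say("traits retained: ", length(traits), " of ", length(hcghSets))
    hcghSets <- hcghSets[traits]

    colocByTrait <- split(world@coloc, world@coloc$trait_id)

    needScores <- "pascal" %in% methods
    geneScores <- NULL
    pwEnrich <- NULL
    if (needScores) {
        geneScores <- scoreGenes(world@variants)
        pwEnrich <- pathwayEnrichment(world@variants, geneScores,
            kb@pathways, world@windows, nPerm = nPermPathway,
            seed = seed)
        say("pathways enriched (BH<0.05): ",
            sum(pwEnrich$table$adj_p < 0.05))
    }

    diffOp <- if ("hotnet" %in% methods)
        suppressWarnings(diffusionOperator(kb@interactome, beta)) else
        NULL

    proxySets <- setNames(vector("list", length(methods)), methods)
    naive <- setdiff(methods, c("hotnet", "pascal"))
    for (i in seq_along(traits)) {
        tr <- traits[i]
        seeds <- hcghGenes(hcghSets[[tr]])
        if (length(naive)) {
            ps <- expandProxies(seeds, kb, tr, naive,
                randomSeed = seed + i)
            for (m in naive) proxySets[[m]][[tr]] <- ps[[m]]
        }
        if ("hotnet" %in% methods) {
            heat <- colocHeat(colocByTrait[[tr]])
            hp <- hotnetProxies(diffOp, heat, seeds, tr, kMin = kMin,
                nPerm = nPermDelta, seed = seed + i)
            proxySets[["hotnet"]][[tr]] <- hp$proxies
        }
        if ("pascal" %in% methods) {
            proxySets[["pascal"]][[tr]] <- selectPathwayProxies(
                pwEnrich, hlaGenes(kb@universe), seeds, tr)
        }
    }

    results <- lapply(proxySets, methodEnrichment, outcomes = outcomes,
        traitIndication = world@traitIndication,
        universe = kb@universe)
    enrichment <- summarizeMethods(results, proxySets)
    tables <- do.call(rbind, lapply(results, `[[`, "tables"))
    say("strata pooled: ", sum(enrichment$n_strata), " across ",
        length(methods), " methods")

    scoreDist <- if (needScores)
        proxyScoreDistributions(proxySets, geneScores) else NULL

    manifest <- list(methods = methods, beta = beta, kMin = kMin,
        nPermDelta = nPermDelta, nPermPathway = nPermPathway,
        seed = seed, nTraitsRetained = length(traits),
        worldSeed = if (inherits(world@config, "SimulationConfig"))
            world@config$seed else NA)

    res <- list(hcgh = hcghSets, traits = traits, outcomes = outcomes,
        proxySets = proxySets, enrichment = enrichment,
        tables = tables, geneScores = geneScores,
        pathwayEnrichment = pwEnrich, scoreDistributions = scoreDist,
        manifest = manifest)
    if (!is.null(outDir)) writeRunOutputs(res, outDir)
    res
}

writeRunOutputs <- function(res, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    hcghTab <- do.call(rbind, lapply(res$hcgh, function(h)
        if (nrow(h@hits)) cbind(data.frame(trait_id = h@traitId),
            h@hits[c("gene_id", "locus_id", "p12")]) else NULL))
    writeTsv(hcghTab, file.path(outDir, "hcgh.tsv"))
    writeProxySets(res$proxySets, file.path(outDir, "proxies.tsv"))
    writeTsv(res$enrichment, file.path(outDir, "enrichment.tsv"))
    if (!is.null(res$tables))
        writeTsv(res$tables, file.path(outDir, "tables.tsv"))
    writeTsv(res$outcomes, file.path(outDir, "outcomes.tsv"))
    if (!is.null(res$geneScores))
        writeTsv(res$geneScores, file.path(outDir, "gene_scores.tsv"))
    if (!is.null(res$pathwayEnrichment))
        writeTsv(res$pathwayEnrichment$table,
            file.path(outDir, "pathway_enrichment.tsv"))
    if (!is.null(res$scoreDistributions))
        writeTsv(res$scoreDistributions,
            file.path(outDir, "score_distributions.tsv"))
    yaml::write_yaml(res$manifest, file.path(outDir, "run_manifest.yaml"))
    invisible(outDir)
}

#' Gene-score distributions of proxy genes per method
#'
#' For each method, pools the \eqn{-\log_{10}} gene-score p-values of
#' all proxy genes across traits (seeds are excluded by construction
#' of the proxy sets) and reports boxplot-style summary quantiles
#' (median, 25-75th and 5-95th centiles).
#'
#' @param proxySets method -> trait -> [ProxySet-class] nested list.
#' @param geneScores data.frame from [scoreGenes()].
#' @return data.frame with one row per method: \code{n},
#'   \code{q05}, \code{q25}, \code{median}, \code{q75}, \code{q95}.
#' @export
proxyScoreDistributions <- function(proxySets, geneScores) {
    lp <- setNames(-log10(geneScores$p), geneScores$gene_id)
    rows <- lapply(names(proxySets), function(m) {
        sc <- unlist(lapply(proxySets[[m]], function(p)
            lp[intersect(p@proxies, names(lp))]), use.names = FALSE)
        if (!length(sc)) sc <- NA_real_
        q <- quantile(sc, c(0.05, 0.25, 0.5, 0.75, 0.95), na.rm = TRUE)
        data.frame(method = m, n = sum(!is.na(sc)), q05 = q[1],
            q25 = q[2], median = q[3], q75 = q[4], q95 = q[5],
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
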