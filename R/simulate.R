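## Synthetic-world generator. Produces a complete, seed-deterministic
## bundle of pipeline inputs with the statistical structure the
## analysis assumes: a scale-free interactome, prior-knowledge
## structures partially coherent with it, per-trait planted disease
## modules with strong colocalization at a subset of module genes,
## hub-biased trial records whose success odds can be enriched around
## the planted signal, and LD-correlated variant statistics.

#' Simulation configuration
#'
#' All knobs of the synthetic world. The defaults describe the study
#' conditions the package is demonstrated under; see the methods
#' vignette for the rationale behind each value.
#'
#' @param nGenes number of genes in the universe.
#' @param codingFraction proportion of protein-coding genes.
#' @param hlaFraction proportion of genes flagged HLA.
#' @param paEdges edges added per node by preferential attachment.
#' @param topology \code{"pa"} (Barabasi-Albert preferential
#'   attachment, the default: the failed-target result hinges on
#'   scale-free topology) or \code{"er"} (Erdos-Renyi contrast).
#' @param nComplexes,complexSizeRange protein complex count and size
#'   range (sizes 2-10 by default).
#' @param nLrPairs number of ligand-receptor pairs.
#' @param nPathways,pathwaySizeRange pathway count and size range
#'   (10-100 by default).
#' @param structureCoherence fraction of complexes / pathways / LR
#'   pairs grown from interactome neighborhoods rather than sampled
#'   uniformly, so functional structures align with network topology as
#'   they do in real prior knowledge.
#' @param nTraits number of traits (each with its own indication).
#' @param lociPerTrait inclusive range of disease-associated loci per
#'   trait.
#' @param moduleSize inclusive range of planted module sizes; the
#'   module is a connected subgraph of the interactome.
#' @param moduleGwasFraction fraction of module genes that are causal
#'   at some locus (carry direct GWAS support); causal genes form a
#'   connected core of the module. The rest of the module is
#'   discoverable only through the network.
#' @param moduleInPathway probability a trait's module is planted
#'   inside a coherent pathway rather than grown freely, mirroring
#'   pathway-level disease biology.
#' @param subthresholdEvidenceProb probability a non-causal module
#'   gene carries sub-threshold colocalization evidence (intermediate
#'   p12, non-significant GWAS p): invisible to the HCGH filters but a
#'   heat source for diffusion.
#' @param p12Hit,p12Mid,p12Null Beta(shape1, shape2) parameters for
#'   colocalization posteriors of causal genes (concentrated above
#'   0.8), locus-neighborhood decoys (intermediate) and null-locus
#'   candidates (concentrated below 0.5).
#' @param gwasLogpHitRange,gwasLogpNullRange \eqn{-\log_{10}} GWAS
#'   p-value ranges at hit and null loci (hits exceed the genome-wide
#'   8.5 > -log10(5e-8) bound by construction).
#' @param eqtlLogpHitRange,eqtlLogpNullRange \eqn{-\log_{10}} eQTL
#'   p-value ranges.
#' @param candidatesPerLocus range of candidate eGenes per locus.
#' @param nTissues tissue records per candidate (range).
#' @param targetSamplingDegreeExponent hub bias: genes enter trial
#'   records with probability proportional to degree to this power.
#' @param testedPerTrait range of targets with trial records per
#'   indication.
#' @param testedNearBoost sampling weight multiplier for genes near the
#'   planted signal (drug programs preferentially pursue biologically
#'   plausible targets).
#' @param baselineSuccessProb baseline per-pair success probability.
#' @param plantedSuccessOr odds multiplier for tested genes near the
#'   planted signal; 1 yields a null world.
#' @param successChannel \code{"complex"}: the multiplier applies to
#'   genes sharing a complex with a causal gene; \code{"graph"}: to
#'   genes within \code{neighborhoodRadius} of the causal genes in the
#'   interactome.
#' @param successAnchor \code{"causal"} (causal genes whose
#'   colocalization records pass the hit filters, i.e. the prospective
#'   seeds) or \code{"module"} (the whole planted module) as the
#'   origin of the success neighborhood.
#' @param neighborhoodRadius graph radius defining "near" for the
#'   graph channel.
#' @param degreeFailureExponent failure accumulation at hubs: success
#'   odds are multiplied by (degree / median degree) to the power of
#'   minus this value. Zero disables the effect.
#' @param inProgressProb probability a tested pair is still in
#'   progress (no outcome yet).
#' @param clinicalFailureProb probability a failed asset reached the
#'   clinic (Phase I-III) rather than failing preclinically.
#' @param selectiveProb probability an asset is Selective (single
#'   target).
#' @param variantsPerGene variants per gene window.
#' @param ldRho AR(1) correlation of adjacent variants in [0, 1).
#' @param causalEffectMu mean z-score shift for variants of module
#'   genes.
#' @param geneBodyRange,geneGapRange gene body length and intergenic
#'   gap ranges (bp) along one abstract chromosome.
#' @param windowPad gene-window padding (bp) used for fusion.
#' @param seed integer seed fully determining the world.
#' @return a \code{SimulationConfig} object.
#' @export
SimulationConfig <- function(
        nGenes = 2000, codingFraction = 0.95, hlaFraction = 0.01,
        paEdges = 3, topology = c("pa", "er"),
        nComplexes = 250, complexSizeRange = c(3, 10),
        nLrPairs = 250,
        nPathways = 80, pathwaySizeRange = c(10, 100),
        structureCoherence = 0.7,
        nTraits = 100, lociPerTrait = c(12, 32),
        moduleSize = c(14, 24), moduleGwasFraction = 0.6,
        moduleInPathway = 0.8, subthresholdEvidenceProb = 0.7,
        p12Hit = c(18, 2), p12Mid = c(4, 4), p12Null = c(2, 6),
        gwasLogpHitRange = c(8.5, 20), gwasLogpNullRange = c(1, 6),
        eqtlLogpHitRange = c(4.5, 10), eqtlLogpNullRange = c(0, 3.5),
        candidatesPerLocus = c(2, 4), nTissues = c(1, 3),
        targetSamplingDegreeExponent = 1,
        testedPerTrait = c(80, 140), testedNearBoost = 5,
        baselineSuccessProb = 0.15, plantedSuccessOr = 3,
        successChannel = c("complex", "graph"),
        successAnchor = c("causal", "module"),
        neighborhoodRadius = 1, degreeFailureExponent = 0,
        inProgressProb = 0.1, clinicalFailureProb = 0.5,
        selectiveProb = 0.8,
        variantsPerGene = 10, ldRho = 0.5, causalEffectMu = 1.5,
        geneBodyRange = c(2e4, 2e5), geneGapRange = c(0, 1.5e5),
        windowPad = 5e4, seed = 1) {
    cfg <- list(nGenes = nGenes, codingFraction = codingFraction,
        hlaFraction = hlaFraction, paEdges = paEdges,
        topology = match.arg(topology), nComplexes = nComplexes,
        complexSizeRange = complexSizeRange, nLrPairs = nLrPairs,
        nPathways = nPathways, pathwaySizeRange = pathwaySizeRange,
        structureCoherence = structureCoherence, nTraits = nTraits,
        lociPerTrait = lociPerTrait, moduleSize = moduleSize,
        moduleGwasFraction = moduleGwasFraction,
        moduleInPathway = moduleInPathway,
        subthresholdEvidenceProb = subthresholdEvidenceProb,
        p12Hit = p12Hit,
        p12Mid = p12Mid, p12Null = p12Null,
        gwasLogpHitRange = gwasLogpHitRange,
        gwasLogpNullRange = gwasLogpNullRange,
        eqtlLogpHitRange = eqtlLogpHitRange,
        eqtlLogpNullRange = eqtlLogpNullRange,
        candidatesPerLocus = candidatesPerLocus, nTissues = nTissues,
        targetSamplingDegreeExponent = targetSamplingDegreeExponent,
        testedPerTrait = testedPerTrait,
        testedNearBoost = testedNearBoost,
        baselineSuccessProb = baselineSuccessProb,
        plantedSuccessOr = plantedSuccessOr,
        successChannel = match.arg(successChannel),
        successAnchor = match.arg(successAnchor),
        neighborhoodRadius = neighborhoodRadius,
        degreeFailureExponent = degreeFailureExponent,
        inProgressProb = inProgressProb,
        clinicalFailureProb = clinicalFailureProb,
        selectiveProb = selectiveProb,
        variantsPerGene = variantsPerGene, ldRho = ldRho,
        causalEffectMu = causalEffectMu, geneBodyRange = geneBodyRange,
        geneGapRange = geneGapRange, windowPad = windowPad, seed = seed)
    validateConfig(cfg)
    structure(cfg, class = "SimulationConfig")
}

validateConfig <- function(cfg) {
    props <- c("codingFraction", "hlaFraction", "structureCoherence",
        "baselineSuccessProb", "inProgressProb", "clinicalFailureProb",
        "selectiveProb", "moduleGwasFraction", "moduleInPathway",
        "subthresholdEvidenceProb")
    for (p in props)
        if (cfg[[p]] < 0 || cfg[[p]] > 1)
            stop(p, " must lie in [0, 1]", call. = FALSE)
    for (r in c("complexSizeRange", "pathwaySizeRange", "lociPerTrait",
                "moduleSize", "candidatesPerLocus", "nTissues",
                "testedPerTrait", "geneBodyRange", "geneGapRange"))
        stopifnot_range(cfg[[r]], r)
    if (cfg$plantedSuccessOr <= 0)
        stop("plantedSuccessOr must be positive", call. = FALSE)
    if (cfg$ldRho < 0 || cfg$ldRho >= 1)
        stop("ldRho must lie in [0, 1)", call. = FALSE)
    if (cfg$complexSizeRange[2] > cfg$nGenes ||
        cfg$pathwaySizeRange[2] > cfg$nGenes ||
        cfg$moduleSize[2] > cfg$nGenes)
        stop("sizing error: requested sets larger than the gene universe",
             call. = FALSE)
    invisible(cfg)
}

#' @export
print.SimulationConfig <- function(x, ...) {
    cat("SimulationConfig:", x$nGenes, "genes,", x$nTraits, "traits,",
        "topology", x$topology, ", plantedSuccessOr", x$plantedSuccessOr,
        ", seed", x$seed, "\n")
    invisible(x)
}

# grow a connected subgraph of `size` vertices by frontier sampling,
# optionally continuing from an initial connected set
growModule <- function(g, size, prefer = NULL, init = NULL) {
    n <- igraph::vcount(g)
    mod <- if (!is.null(init)) init else if (is.null(prefer))
        sample.int(n, 1) else sampleVec(prefer, 1)
    frontier <- setdiff(unique(unlist(lapply(mod, function(v)
        as.integer(igraph::neighbors(g, v))))), mod)
    while (length(mod) < size && length(frontier)) {
        nxt <- sampleVec(frontier, 1)
        mod <- c(mod, nxt)
        frontier <- setdiff(unique(c(frontier,
            as.integer(igraph::neighbors(g, nxt)))), mod)
    }
    mod
}

# grow a connected module, preferring to stay inside a host vertex set
# (e.g. a pathway); extends outside only when the host is exhausted
growModuleHosted <- function(g, hostIdx, size) {
    sub <- igraph::induced_subgraph(g, hostIdx)
    inner <- growModule(sub, size)
    mod <- match(igraph::V(sub)$name[inner], igraph::V(g)$name)
    if (length(mod) < size)
        mod <- growModule(g, size, init = mod)
    mod
}

# sample a gene set either as a graph neighborhood (coherent) or
# uniformly
sampleGeneSet <- function(g, genesAll, size, coherent) {
    out <- if (coherent && size <= igraph::vcount(g))
        igraph::V(g)$name[growModule(g, size)] else character()
    if (length(out) < size)  # frontier exhausted (or incoherent draw)
        out <- c(out, sampleVec(setdiff(genesAll, out),
            size - length(out)))
    out
}

# AR(1) correlation matrix
ar1Matrix <- function(m, rho) {
    if (m == 1) return(matrix(1, 1, 1))
    rho^abs(outer(seq_len(m), seq_len(m), "-"))
}

#' Generate a synthetic world
#'
#' Deterministic for a fixed \code{config$seed}. See
#' [SimulationConfig()] for what is planted and where.
#'
#' @param config a [SimulationConfig()].
#' @return a [SyntheticWorld-class].
#' @export
generateWorld <- function(config = SimulationConfig()) {
    validateConfig(config)
    withSeed(config$seed, .generateWorld(config))
}

.generateWorld <- function(cfg) {
    n <- cfg$nGenes
    gene <- sprintf("G%05d", seq_len(n))

    coding <- rep(FALSE, n)
    coding[sample.int(n, round(n * cfg$codingFraction))] <- TRUE
    hla <- rep(FALSE, n)
    hla[sampleVec(which(coding), round(n * cfg$hlaFraction))] <- TRUE
    uni <- GeneUniverse(gene, coding, hla)

    g <- if (cfg$topology == "pa") {
        igraph::sample_pa(n, m = cfg$paEdges, directed = FALSE)
    } else {
        igraph::sample_gnm(n, m = n * cfg$paEdges)
    }
    igraph::V(g)$name <- gene
    g <- igraph::simplify(g)
    net <- new("Interactome", graph = g, name = cfg$topology)
    deg <- igraph::degree(g)

    coh <- function() runif(1) < cfg$structureCoherence
    cxs <- lapply(seq_len(cfg$nComplexes), function(i)
        sampleGeneSet(g, gene, drawCount(cfg$complexSizeRange), coh()))
    names(cxs) <- sprintf("CPX%04d", seq_along(cxs))
    complexes <- ComplexSet(cxs)

    edgeMat <- igraph::as_edgelist(g)
    lrIdx <- sample.int(nrow(edgeMat), cfg$nLrPairs, replace = TRUE)
    lrCoherent <- runif(cfg$nLrPairs) < cfg$structureCoherence
    lig <- ifelse(lrCoherent, edgeMat[lrIdx, 1], sampleVec(gene,
        cfg$nLrPairs, replace = TRUE))
    rec <- ifelse(lrCoherent, edgeMat[lrIdx, 2], sampleVec(gene,
        cfg$nLrPairs, replace = TRUE))
    keep <- lig != rec
    lr <- LigandReceptorMap(data.frame(ligand = lig[keep],
        receptor = rec[keep]))

    pwCoherent <- runif(cfg$nPathways) < cfg$structureCoherence
    pws <- lapply(seq_len(cfg$nPathways), function(i)
        sampleGeneSet(g, gene, drawCount(cfg$pathwaySizeRange),
            pwCoherent[i]))
    names(pws) <- sprintf("PWY%04d", seq_along(pws))
    pwEdges <- do.call(rbind, lapply(names(pws), function(pw) {
        mem <- pws[[pw]]
        # internal topology: graph edges among members plus a chain so
        # every member has at least one interaction
        sub <- igraph::induced_subgraph(g, mem)
        e <- igraph::as_edgelist(sub)
        chain <- cbind(mem[-length(mem)], mem[-1])
        e <- unique(rbind(e, chain))
        flip <- runif(nrow(e)) < 0.5
        data.frame(pathway = pw,
            source = ifelse(flip, e[, 2], e[, 1]),
            target = ifelse(flip, e[, 1], e[, 2]),
            stringsAsFactors = FALSE)
    }))
    pathways <- PathwaySet(pws, pwEdges)

    kb <- KnowledgeBase(uni, net, complexes, lr, pathways)

    # gene windows on one abstract chromosome
    body <- runif(n, cfg$geneBodyRange[1], cfg$geneBodyRange[2])
    gap <- runif(n, cfg$geneGapRange[1], cfg$geneGapRange[2])
    start <- cumsum(c(0, body[-n] + gap[-n]))
    windows <- data.frame(gene_id = gene, start = round(start),
        end = round(start + body))

    traits <- sprintf("T%03d", seq_len(cfg$nTraits))
    indications <- sprintf("IND%03d", seq_len(cfg$nTraits))
    traitIndication <- data.frame(trait_id = traits,
        indication_id = indications, stringsAsFactors = FALSE)

    codingIdx <- which(coding)
    tissuePool <- sprintf("TIS%02d", 1:5)
    colocRows <- list()
    truthRows <- list()
    assetRows <- list()
    assetCounter <- 0L
    medDeg <- median(pmax(deg, 1))
    relDeg <- pmax(deg, 1) / medDeg
    names(relDeg) <- gene

    # complex membership index for the "complex" success channel
    geneComplex <- new.env(hash = TRUE, parent = emptyenv())
    for (cx in cxs) for (gg in cx)
        assign(gg, c(get0(gg, geneComplex, ifnotfound = NULL),
            list(cx)), geneComplex)

    moduleUnion <- character()
    hostPathways <- which(pwCoherent & lengths(pws) >= 6)
    for (ti in seq_along(traits)) {
        tr <- traits[ti]
        msize <- drawCount(cfg$moduleSize)
        # disease modules preferentially sit inside a coherent pathway,
        # mirroring pathway-level disease biology
        modIdx <- if (length(hostPathways) &&
                      runif(1) < cfg$moduleInPathway) {
            host <- match(pws[[sampleVec(hostPathways, 1)]], gene)
            growModuleHosted(g, host, msize)
        } else growModule(g, msize, prefer = codingIdx)
        module <- gene[modIdx]
        moduleUnion <- union(moduleUnion, module)
        nCausal <- max(1, round(cfg$moduleGwasFraction * length(module)))
        # causal genes form a connected core of the module: GWAS hits
        # cluster where the module is densest
        subM <- igraph::induced_subgraph(g, modIdx)
        causal <- igraph::V(subM)$name[growModule(subM, nCausal)]
        causal <- causal[coding[match(causal, gene)]]
        if (!length(causal)) {
            cm <- module[coding[match(module, gene)]]
            causal <- if (length(cm)) sampleVec(cm, 1) else module[1]
        }
        truthRows[[ti]] <- data.frame(trait_id = tr, gene_id = module,
            is_causal = module %in% causal, stringsAsFactors = FALSE)

        # locus neighborhood: the module and its first graph neighbors
        nbhood <- unique(names(unlist(igraph::ego(g, 1, nodes = modIdx))))

        L <- drawCount(cfg$lociPerTrait)
        nHit <- min(length(causal), L)
        loci <- sprintf("%s_L%02d", tr, seq_len(L))
        locusL <- character(0); geneL <- character(0)
        tisL <- character(0); gwasL <- numeric(0)
        eqtlL <- numeric(0); p12L <- numeric(0)
        if (nHit) {
            gwasLpHit <- runif(nHit, cfg$gwasLogpHitRange[1],
                cfg$gwasLogpHitRange[2])
            nt <- vapply(seq_len(nHit), function(i)
                drawCount(cfg$nTissues), 0L)
            tisHit <- unlist(lapply(nt, sampleVec, x = tissuePool))
            # the shared GWAS signal at a hit locus also covers 1-3
            # decoy eGenes from the module neighborhood, with
            # intermediate colocalization posteriors
            nDecoy <- vapply(seq_len(nHit), function(i)
                drawCount(cfg$candidatesPerLocus) - 1L, 0L)
            decoys <- lapply(seq_len(nHit), function(i) {
                pool <- setdiff(nbhood, causal[i])
                sampleVec(pool, min(nDecoy[i], length(pool)))
            })
            nd <- lengths(decoys)
            locusL <- c(rep(loci[seq_len(nHit)], nt),
                        rep(loci[seq_len(nHit)], nd))
            geneL <- c(rep(causal[seq_len(nHit)], nt),
                       unlist(decoys, use.names = FALSE))
            tisL <- c(tisHit, sampleVec(tissuePool, sum(nd),
                replace = TRUE))
            gwasL <- c(rep(10^-gwasLpHit, nt), rep(10^-gwasLpHit, nd))
            eqtlL <- 10^-runif(sum(nt) + sum(nd),
                cfg$eqtlLogpHitRange[1], cfg$eqtlLogpHitRange[2])
            p12L <- c(rbeta(sum(nt), cfg$p12Hit[1], cfg$p12Hit[2]),
                      rbeta(sum(nd), cfg$p12Mid[1], cfg$p12Mid[2]))
        }
        # non-causal module genes carry sub-threshold evidence: real
        # colocalization (intermediate p12, genuine eQTL) at loci whose
        # GWAS signal never reaches genome-wide significance, so they
        # fail the HCGH filters but are visible to heat diffusion
        warm <- setdiff(module, causal)
        warm <- warm[runif(length(warm)) < cfg$subthresholdEvidenceProb]
        if (length(warm)) {
            nw <- length(warm)
            locusL <- c(locusL, sprintf("%s_Lw%02d", tr, seq_len(nw)))
            geneL <- c(geneL, warm)
            tisL <- c(tisL, sampleVec(tissuePool, nw, replace = TRUE))
            gwasL <- c(gwasL, 10^-runif(nw, cfg$gwasLogpNullRange[1],
                cfg$gwasLogpNullRange[2]))
            eqtlL <- c(eqtlL, 10^-runif(nw, cfg$eqtlLogpHitRange[1],
                cfg$eqtlLogpHitRange[2]))
            p12L <- c(p12L, rbeta(nw, cfg$p12Mid[1], cfg$p12Mid[2]))
        }
        if (L > nHit) {
            nullLoci <- loci[(nHit + 1):L]
            nc <- vapply(nullLoci, function(l)
                drawCount(cfg$candidatesPerLocus), 0L)
            cand <- unlist(lapply(nc, sampleVec, x = gene))
            gwasLp0 <- runif(length(nullLoci), cfg$gwasLogpNullRange[1],
                cfg$gwasLogpNullRange[2])
            locusL <- c(locusL, rep(nullLoci, nc))
            geneL <- c(geneL, cand)
            tisL <- c(tisL, sampleVec(tissuePool, sum(nc),
                replace = TRUE))
            gwasL <- c(gwasL, rep(10^-gwasLp0, nc))
            eqtlL <- c(eqtlL, 10^-runif(sum(nc),
                cfg$eqtlLogpNullRange[1], cfg$eqtlLogpNullRange[2]))
            p12L <- c(p12L, rbeta(sum(nc), cfg$p12Null[1],
                cfg$p12Null[2]))
        }
        colocRows[[ti]] <- data.frame(trait_id = tr, locus_id = locusL,
            gene_id = geneL, tissue = tisL, gwas_p = gwasL,
            eqtl_p = eqtlL, p12 = p12L, stringsAsFactors = FALSE)

        # ---- trial records -------------------------------------------
        # the "causal" anchor is the causal genes whose colocalization
        # records actually pass the hit filters (max p12 >= 0.8; their
        # GWAS/eQTL draws pass by construction), i.e. the prospective
        # seeds, so the planted odds multiplier is the estimand of
        # seed-based expansion
        recovered <- if (nHit) {
            best <- tapply(p12L[seq_len(sum(nt))],
                geneL[seq_len(sum(nt))], max)
            names(best)[best >= 0.8]
        } else character()
        anchor <- if (cfg$successAnchor == "causal") recovered else
            module
        anchorIdx <- match(anchor, gene)
        nearGraph <- unique(names(unlist(igraph::ego(g,
            cfg$neighborhoodRadius, nodes = anchorIdx))))
        nearComplex <- unique(c(anchor, unlist(lapply(anchor, function(a)
            unlist(get0(a, geneComplex, ifnotfound = list()))))))
        near <- switch(cfg$successChannel, complex = nearComplex,
            graph = nearGraph)
        nearAny <- union(nearGraph, nearComplex)

        codingGene <- gene[coding]
        wt <- relDeg[codingGene]^cfg$targetSamplingDegreeExponent
        wt <- wt * ifelse(codingGene %in% nearAny, cfg$testedNearBoost, 1)
        nTested <- min(drawCount(cfg$testedPerTrait), length(codingGene))
        tested <- sampleVec(codingGene, nTested, prob = wt)

        odds0 <- cfg$baselineSuccessProb / (1 - cfg$baselineSuccessProb)
        odds <- odds0 *
            ifelse(tested %in% near, cfg$plantedSuccessOr, 1) *
            relDeg[tested]^(-cfg$degreeFailureExponent)
        pSucc <- odds / (1 + odds)
        prog <- runif(nTested) < cfg$inProgressProb
        succ <- !prog & (runif(nTested) < pSucc)

        # one asset per in-progress or succeeded pair; failed pairs may
        # carry a second failed asset
        nAst <- ifelse(prog | succ, 1L, 1L + rbinom(nTested, 1, 0.3))
        aGene <- rep(tested, nAst)
        aProg <- rep(prog, nAst)
        aSucc <- rep(succ, nAst)
        nA <- length(aGene)
        status <- character(nA)
        phase <- character(nA)
        status[aProg] <- "Phase II Clinical Trial"
        phase[aProg] <- "PhaseII"
        status[aSucc] <- "Launched"
        phase[aSucc] <- "Launched"
        fail <- !aProg & !aSucc
        nF <- sum(fail)
        if (nF) {
            status[fail] <- sampleVec(c("Discontinued",
                "No Development Reported", "Withdrawn", "Suspended"),
                nF, replace = TRUE, prob = c(0.24, 0.75, 0.005, 0.005))
            clin <- runif(nF) < cfg$clinicalFailureProb
            phF <- rep("Preclinical", nF)
            phF[clin] <- sampleVec(c("PhaseI", "PhaseII", "PhaseIII"),
                sum(clin), replace = TRUE, prob = c(0.4, 0.4, 0.2))
            phase[fail] <- phF
        }
        ids <- sprintf("A%06d", assetCounter + seq_len(nA))
        assetCounter <- assetCounter + nA
        # Non-Selective assets carry one extra target, drawn from
        # tested genes whose own outcome draw falls in the same class,
        # so every (gene, indication) pair's success still follows its
        # own odds model
        nonsel <- runif(nA) >= cfg$selectiveProb
        extra <- rep(NA_character_, nA)
        aCls <- ifelse(aProg, "prog", ifelse(aSucc, "succ", "fail"))
        pairCls <- ifelse(prog, "prog", ifelse(succ, "succ", "fail"))
        for (cl in c("prog", "succ", "fail")) {
            pool <- tested[pairCls == cl]
            k <- which(nonsel & aCls == cl)
            if (length(pool) >= 2 && length(k))
                extra[k] <- sampleVec(pool, length(k), replace = TRUE)
        }
        nonsel <- nonsel & !is.na(extra) & extra != aGene
        assetRows[[ti]] <- data.frame(
            asset_id = c(ids, ids[nonsel]),
            gene_id = c(aGene, extra[nonsel]),
            indication_id = indications[ti],
            status_text = c(status, status[nonsel]),
            phase_reached = c(phase, phase[nonsel]),
            stringsAsFactors = FALSE)
    }

    coloc <- do.call(rbind, colocRows)
    rownames(coloc) <- NULL
    truth <- do.call(rbind, truthRows)
    assets <- do.call(rbind, assetRows)
    rownames(assets) <- NULL

    # variant statistics: z ~ MVN(mu, R) per gene, AR(1) LD; variants
    # of module genes (any trait) are mean-shifted
    m <- cfg$variantsPerGene
    R <- ar1Matrix(m, cfg$ldRho)
    U <- chol(R)
    shifted <- gene %in% moduleUnion
    variants <- vector("list", n)
    names(variants) <- gene
    for (i in seq_len(n)) {
        mu <- if (shifted[i]) cfg$causalEffectMu else 0
        variants[[i]] <- list(
            z = as.numeric(crossprod(U, rnorm(m))) + mu, R = R)
    }

    new("SyntheticWorld", kb = kb, coloc = coloc, truth = truth,
        assets = assets, traitIndication = traitIndication,
        variants = variants, windows = windows, config = cfg)
}
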