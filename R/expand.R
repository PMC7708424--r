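## Naive guilt-by-association proxy gene expansion.
##
## Every method maps a seed gene set (the high-confidence genetic hits
## of one trait) to a proxy set with the seeds removed. Expansions are
## purely topological: non-coding genes may be returned; the enrichment
## stage later restricts to the coding universe.

#' Complex co-membership expansion
#'
#' All genes sharing a protein complex with a seed. Each complex is a
#' fully connected clique, so co-members are first neighbors.
#'
#' @param seeds character vector of seed genes.
#' @param complexes a [ComplexSet-class].
#' @param traitId trait label carried into the result.
#' @return a [ProxySet-class] (seeds removed; possibly empty).
#' @examples
#' cs <- ComplexSet(list(c("g1", "g2", "g3"), c("g4", "g5")))
#' proxyGenes(complexProxies("g1", cs))
#' @export
complexProxies <- function(seeds, complexes, traitId = "trait") {
    hit <- vapply(complexes@sets, function(s) any(seeds %in% s), logical(1))
    ProxySet(traitId, "complex", seeds,
        unlist(complexes@sets[hit], use.names = FALSE))
}

#' Ligand-receptor partner expansion
#'
#' All genes in a ligand-receptor pair with a seed, in either role.
#' Strictly first-neighbor: a seed ligand's receptors are returned but
#' not those receptors' other ligands, so genetic evidence is never
#' propagated ligand -> receptor -> other ligand.
#'
#' @param seeds seed genes.
#' @param lr a [LigandReceptorMap-class].
#' @param traitId trait label.
#' @return a [ProxySet-class].
#' @export
ligandReceptorProxies <- function(seeds, lr, traitId = "trait") {
    p <- lr@pairs
    partners <- c(p$receptor[p$ligand %in% seeds],
                  p$ligand[p$receptor %in% seeds])
    ProxySet(traitId, "ligand_receptor", seeds, partners)
}

#' Interactome neighborhood expansion
#'
#' First-degree (order 1) or first-and-second-degree (order 2)
#' interactors of the seeds within a protein-protein interaction
#' network; edge weights are ignored. Seeds absent from the network are
#' skipped with a warning (treated as isolated).
#'
#' @param seeds seed genes.
#' @param net an [Interactome-class].
#' @param order 1 or 2.
#' @param traitId trait label.
#' @return a [ProxySet-class].
#' @export
networkNeighbors <- function(seeds, net, order = 1, traitId = "trait") {
    stopifnot(order %in% c(1, 2))
    present <- intersect(seeds, genes(net))
    if (length(present) < length(unique(seeds)))
        warning(length(unique(seeds)) - length(present),
            " seed(s) absent from network '", net@name, "'; skipped")
    nb <- if (length(present))
        unique(names(unlist(igraph::ego(net@graph, order = order,
            nodes = present))))
    else character()
    ProxySet(traitId, paste0("net_neighbor", order), seeds, nb)
}

#' Pathway co-membership (clique) expansion
#'
#' All genes in the same pathway as a seed: every pathway map is
#' modelled as a clique.
#'
#' @param seeds seed genes.
#' @param pathways a [PathwaySet-class].
#' @param traitId trait label.
#' @return a [ProxySet-class].
#' @export
pathwayCliqueProxies <- function(seeds, pathways, traitId = "trait") {
    hit <- vapply(pathways@sets, function(s) any(seeds %in% s), logical(1))
    ProxySet(traitId, "pathway_clique", seeds,
        unlist(pathways@sets[hit], use.names = FALSE))
}

#' Pathway topology neighborhood expansion
#'
#' First interactors of a gene are all upstream and downstream direct
#' interactors across all pathways; second interactors repeat the
#' process starting from the first interactors. Edge direction is not
#' respected for reachability (both upstream and downstream partners
#' count at every step).
#'
#' @param seeds seed genes.
#' @param pathways a [PathwaySet-class].
#' @param order 1 or 2.
#' @param traitId trait label.
#' @return a [ProxySet-class].
#' @export
pathwayNeighbors <- function(seeds, pathways, order = 1, traitId = "trait") {
    stopifnot(order %in% c(1, 2))
    e <- pathways@edges
    step <- function(from) unique(c(e$target[e$source %in% from],
                                    e$source[e$target %in% from]))
    first <- step(seeds)
    res <- if (order == 1) first else unique(c(first, step(first)))
    ProxySet(traitId, paste0("pathway_neighbor", order), seeds, res)
}

#' Random proxy baseline
#'
#' A uniform sample without replacement from the protein-coding
#' universe; the negative control for all enrichment comparisons. The
#' default size preserves the sampling fraction of 10,000 genes out of
#' a 22,758-gene coding background.
#'
#' @param universe a [GeneUniverse-class].
#' @param n sample size; default \code{round(10000/22758 * #coding)}.
#' @param seed RNG seed making the draw reproducible.
#' @param seeds seed genes (removed from the returned set).
#' @param traitId trait label.
#' @return a [ProxySet-class].
#' @export
randomProxies <- function(universe, n = NULL, seed = 1,
                          seeds = character(), traitId = "trait") {
    cg <- codingGenes(universe)
    if (is.null(n)) n <- round(10000 / 22758 * length(cg))
    if (n > length(cg))
        stop("requested ", n, " genes but coding universe has only ",
             length(cg))
    draw <- withSeed(seed, sampleVec(cg, n))
    ProxySet(traitId, "random", seeds, draw)
}
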