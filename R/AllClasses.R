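#' @import methods
#' @importFrom stats median quantile rnorm runif rbeta rbinom setNames
#'   pchisq integrate p.adjust ks.test wilcox.test cor
#' @importFrom utils read.delim write.table head
NULL

setOldClass("igraph")

#' Gene universe with coding and HLA annotation
#'
#' The background gene universe against which all expansions and
#' enrichment calculations are performed. Enrichment is restricted to
#' the protein-coding subset; HLA-flagged genes are excluded from
#' gene-score based proxy selection.
#'
#' @slot genes character vector of unique gene identifiers.
#' @slot coding logical flag per gene, protein-coding status.
#' @slot hla logical flag per gene, membership of the curated HLA list.
#'
#' @export
setClass("GeneUniverse",
    representation(genes = "character", coding = "logical", hla = "logical"))

setValidity("GeneUniverse", function(object) {
    msg <- NULL
    if (anyDuplicated(object@genes))
        msg <- c(msg, "gene identifiers must be unique")
    if (length(object@coding) != length(object@genes) ||
        length(object@hla) != length(object@genes))
        msg <- c(msg, "coding/hla flags must match gene vector length")
    if (any(object@hla & !object@coding))
        msg <- c(msg, "HLA genes must be protein coding")
    if (is.null(msg)) TRUE else msg
})

#' Undirected interactome over the gene universe
#'
#' @slot graph an undirected \pkg{igraph} graph whose vertex names are
#'   gene identifiers; no self loops; duplicate edges collapsed.
#' @slot name source label for the network.
#'
#' @export
setClass("Interactome",
    representation(graph = "igraph", name = "character"))

setValidity("Interactome", function(object) {
    g <- object@graph
    msg <- NULL
    if (igraph::is_directed(g))
        msg <- c(msg, "interactome graph must be undirected")
    if (any(igraph::which_loop(g)))
        msg <- c(msg, "interactome graph must not contain self-loops")
    if (is.null(igraph::V(g)$name))
        msg <- c(msg, "vertices must be named with gene identifiers")
    if (is.null(msg)) TRUE else msg
})

#' Protein complex membership
#'
#' Each complex is modelled as a fully connected clique: every member is
#' a first neighbor of every other member.
#'
#' @slot sets named list of character vectors (complex members).
#'
#' @export
setClass("ComplexSet", representation(sets = "list"))

setValidity("ComplexSet", function(object) {
    sizes <- lengths(object@sets)
    if (length(sizes) && any(sizes < 2))
        "every complex must have at least 2 members" else TRUE
})

#' Ligand-receptor pair map
#'
#' A many-to-many map: each ligand is connected to all subunits of its
#' receptors and each receptor subunit to all its possible ligands.
#'
#' @slot pairs data.frame with columns \code{ligand} and \code{receptor}.
#'
#' @export
setClass("LigandReceptorMap", representation(pairs = "data.frame"))

setValidity("LigandReceptorMap", function(object) {
    if (!all(c("ligand", "receptor") %in% names(object@pairs)))
        "pairs must have columns 'ligand' and 'receptor'" else TRUE
})

#' Pathway collection with internal topology
#'
#' @slot sets named list of character vectors (pathway members).
#' @slot edges data.frame with columns \code{pathway}, \code{source},
#'   \code{target}: directed interactions internal to each pathway.
#'
#' @export
setClass("PathwaySet", representation(sets = "list", edges = "data.frame"))

setValidity("PathwaySet", function(object) {
    msg <- NULL
    if (!all(c("pathway", "source", "target") %in% names(object@edges)))
        msg <- c(msg, "edges must have columns pathway/source/target")
    else if (nrow(object@edges)) {
        e <- object@edges
        known <- vapply(seq_len(nrow(e)), function(i) {
            m <- object@sets[[e$pathway[i]]]
            !is.null(m) && all(c(e$source[i], e$target[i]) %in% m)
        }, logical(1))
        if (!all(known))
            msg <- c(msg, "pathway edges must connect members of the pathway")
    }
    if (is.null(msg)) TRUE else msg
})

#' Prior-knowledge bundle
#'
#' Container for everything the expansion methods consume: the gene
#' universe, an interactome, protein complexes, ligand-receptor pairs
#' and pathways with topology.
#'
#' @slot universe a [GeneUniverse-class].
#' @slot interactome an [Interactome-class].
#' @slot complexes a [ComplexSet-class].
#' @slot lrPairs a [LigandReceptorMap-class].
#' @slot pathways a [PathwaySet-class].
#'
#' @export
setClass("KnowledgeBase",
    representation(universe = "GeneUniverse", interactome = "Interactome",
        complexes = "ComplexSet", lrPairs = "LigandReceptorMap",
        pathways = "PathwaySet"))

setValidity("KnowledgeBase", function(object) {
    uni <- object@universe@genes
    msg <- NULL
    if (!all(igraph::V(object@interactome@graph)$name %in% uni))
        msg <- c(msg, "interactome vertices must be in the universe")
    if (!all(unlist(object@complexes@sets) %in% uni))
        msg <- c(msg, "complex members must be in the universe")
    if (!all(unlist(object@pathways@sets) %in% uni))
        msg <- c(msg, "pathway members must be in the universe")
    if (nrow(object@lrPairs@pairs) &&
        !all(unlist(object@lrPairs@pairs[c("ligand", "receptor")]) %in% uni))
        msg <- c(msg, "ligand-receptor genes must be in the universe")
    if (is.null(msg)) TRUE else msg
})

#' Expanded proxy gene set for one trait and method
#'
#' Proxy genes are genes without a direct genetic hit, implicated by
#' their relation to the seed hits. Seeds are always excluded from the
#' proxy set.
#'
#' @slot traitId trait identifier.
#' @slot method method label, e.g. \code{"complex"}.
#' @slot seeds character vector of seed genes (the high-confidence hits).
#' @slot proxies character vector of proxy genes, disjoint from seeds.
#'
#' @export
setClass("ProxySet",
    representation(traitId = "character", method = "character",
        seeds = "character", proxies = "character"))

setValidity("ProxySet", function(object) {
    if (length(intersect(object@seeds, object@proxies)))
        "proxies must be disjoint from seeds" else TRUE
})

#' High-confidence genetic hits for one trait
#'
#' At most one hit per disease-associated locus; each gene appears once
#' with its best (maximum p12) surviving colocalization record.
#'
#' @slot traitId trait identifier.
#' @slot hits data.frame with columns \code{gene_id}, \code{locus_id},
#'   \code{tissue}, \code{gwas_p}, \code{eqtl_p}, \code{p12}.
#'
#' @export
setClass("HcghSet",
    representation(traitId = "character", hits = "data.frame"))

setValidity("HcghSet", function(object) {
    h <- object@hits
    msg <- NULL
    need <- c("gene_id", "locus_id", "tissue", "gwas_p", "eqtl_p", "p12")
    if (!all(need %in% names(h)))
        msg <- c(msg, paste("hits must have columns:",
            paste(need, collapse = ", ")))
    else {
        if (anyDuplicated(h$locus_id))
            msg <- c(msg, "at most one hit per locus")
        if (anyDuplicated(h$gene_id))
            msg <- c(msg, "each gene may appear at most once")
    }
    if (is.null(msg)) TRUE else msg
})

#' Insulated heat diffusion operator
#'
#' Holds the random-walk-with-restart diffusion operator
#' \eqn{F = \beta (I - (1-\beta) W)^{-1}} for one network, where
#' \eqn{W} is the column-normalized adjacency matrix of the largest
#' connected component. Every column of \eqn{F} sums to one (heat
#' conservation).
#'
#' @slot genes gene identifiers indexing rows/columns of the operator.
#' @slot W column-normalized adjacency matrix.
#' @slot F diffusion matrix.
#' @slot beta restart probability in (0, 1).
#'
#' @export
setClass("DiffusionResult",
    representation(genes = "character", W = "matrix", F = "matrix",
        beta = "numeric"))

setValidity("DiffusionResult", function(object) {
    msg <- NULL
    if (object@beta <= 0 || object@beta >= 1)
        msg <- c(msg, "beta must lie strictly between 0 and 1")
    n <- length(object@genes)
    if (!all(dim(object@W) == n) || !all(dim(object@F) == n))
        msg <- c(msg, "W and F must be square over the gene vector")
    if (n && max(abs(colSums(object@F) - 1)) > 1e-6)
        msg <- c(msg, "columns of F must sum to 1 (heat conservation)")
    if (is.null(msg)) TRUE else msg
})

#' Synthetic world bundling all pipeline inputs
#'
#' @slot kb a [KnowledgeBase-class].
#' @slot coloc data.frame of colocalization records (trait_id, locus_id,
#'   gene_id, tissue, gwas_p, eqtl_p, p12).
#' @slot truth data.frame of planted disease modules (trait_id, gene_id,
#'   is_causal): the ground-truth module per trait and which of its
#'   genes carry direct GWAS support.
#' @slot assets data.frame of trial records (asset_id, gene_id,
#'   indication_id, status_text, phase_reached), one row per
#'   asset-target-indication triple.
#' @slot traitIndication data.frame mapping trait_id to indication_id.
#' @slot variants named list per gene with elements \code{z} (variant
#'   z-scores) and \code{R} (LD correlation matrix).
#' @slot windows data.frame of synthetic gene windows (gene_id, start,
#'   end) on one abstract chromosome.
#' @slot config the [SimulationConfig-class] used to generate the world.
#'
#' @export
setClass("SyntheticWorld",
    representation(kb = "KnowledgeBase", coloc = "data.frame",
        truth = "data.frame", assets = "data.frame",
        traitIndication = "data.frame", variants = "list",
        windows = "data.frame", config = "ANY"))

setValidity("SyntheticWorld", function(object) {
    uni <- object@kb@universe@genes
    msg <- NULL
    refd <- unique(c(object@coloc$gene_id, object@truth$gene_id,
        object@assets$gene_id, names(object@variants),
        object@windows$gene_id))
    if (!all(refd %in% uni))
        msg <- c(msg, "every referenced gene must be in the universe")
    if (anyDuplicated(object@traitIndication$trait_id))
        msg <- c(msg, "each trait maps to exactly one indication")
    if (is.null(msg)) TRUE else msg
})
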