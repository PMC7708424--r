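#' Construct a gene universe
#'
#' @param genes character vector of unique gene identifiers.
#' @param coding logical vector, protein-coding flag per gene.
#' @param hla logical vector, HLA flag per gene.
#' @return a [GeneUniverse-class].
#' @examples
#' u <- GeneUniverse(c("A", "B", "C"), coding = c(TRUE, TRUE, FALSE))
#' codingGenes(u)
#' @export
GeneUniverse <- function(genes, coding = rep(TRUE, length(genes)),
                         hla = rep(FALSE, length(genes))) {
    new("GeneUniverse", genes = as.character(genes), coding = coding,
        hla = hla)
}

#' Construct an interactome from an edge list or igraph
#'
#' Self-loops are dropped and duplicate edges collapsed. An optional
#' minimum edge weight mimics confidence filtering of weighted networks
#' such as STRING.
#'
#' @param edges two-column data.frame (or matrix) of gene pairs, with an
#'   optional third \code{weight} column; alternatively an igraph.
#' @param name source label.
#' @param minWeight drop edges with weight below this value before
#'   simplification (default \code{NULL}: keep all).
#' @return an [Interactome-class].
#' @export
Interactome <- function(edges, name = "network", minWeight = NULL) {
    if (inherits(edges, "igraph")) {
        g <- igraph::as_undirected(edges, mode = "collapse")
    } else {
        edges <- as.data.frame(edges)
        w <- if (ncol(edges) >= 3) as.numeric(edges[[3]]) else
            rep(1, nrow(edges))
        if (!is.null(minWeight)) {
            keep <- w >= minWeight
            edges <- edges[keep, , drop = FALSE]
            w <- w[keep]
        }
        g <- igraph::graph_from_data_frame(
            data.frame(from = as.character(edges[[1]]),
                       to = as.character(edges[[2]]), weight = w),
            directed = FALSE)
    }
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
        edge.attr.comb = "max")
    new("Interactome", graph = g, name = name)
}

#' @rdname ComplexSet-class
#' @param sets named list of character vectors.
#' @export
ComplexSet <- function(sets = list()) {
    if (length(sets) && is.null(names(sets)))
        names(sets) <- sprintf("CPX%04d", seq_along(sets))
    new("ComplexSet", sets = lapply(sets, function(s) unique(as.character(s))))
}

#' @rdname LigandReceptorMap-class
#' @param pairs data.frame with columns \code{ligand}, \code{receptor}.
#' @export
LigandReceptorMap <- function(pairs = data.frame(ligand = character(),
                                                 receptor = character())) {
    pairs <- unique(data.frame(ligand = as.character(pairs$ligand),
        receptor = as.character(pairs$receptor),
        stringsAsFactors = FALSE))
    new("LigandReceptorMap", pairs = pairs)
}

#' @rdname PathwaySet-class
#' @param sets named list of character vectors (members per pathway).
#' @param edges data.frame with columns \code{pathway}, \code{source},
#'   \code{target} (directed internal interactions).
#' @export
PathwaySet <- function(sets = list(),
                       edges = data.frame(pathway = character(),
                           source = character(), target = character())) {
    if (length(sets) && is.null(names(sets)))
        names(sets) <- sprintf("PWY%04d", seq_along(sets))
    new("PathwaySet",
        sets = lapply(sets, function(s) unique(as.character(s))),
        edges = as.data.frame(edges))
}

#' @rdname KnowledgeBase-class
#' @param universe a [GeneUniverse-class].
#' @param interactome an [Interactome-class].
#' @param complexes a [ComplexSet-class].
#' @param lrPairs a [LigandReceptorMap-class].
#' @param pathways a [PathwaySet-class].
#' @export
KnowledgeBase <- function(universe, interactome,
                          complexes = ComplexSet(),
                          lrPairs = LigandReceptorMap(),
                          pathways = PathwaySet()) {
    new("KnowledgeBase", universe = universe, interactome = interactome,
        complexes = complexes, lrPairs = lrPairs, pathways = pathways)
}

#' @rdname ProxySet-class
#' @param traitId trait identifier.
#' @param method method label.
#' @param seeds seed genes.
#' @param proxies proxy genes (seeds are removed automatically).
#' @export
ProxySet <- function(traitId, method, seeds, proxies) {
    new("ProxySet", traitId = as.character(traitId),
        method = as.character(method),
        seeds = sort(unique(as.character(seeds))),
        proxies = sort(setdiff(unique(as.character(proxies)), seeds)))
}

## ---- generics and accessors -------------------------------------------

#' @rdname GeneUniverse-class
#' @param x object with gene content.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @export
setMethod("genes", "GeneUniverse", function(x) x@genes)

#' @export
setMethod("genes", "Interactome", function(x) igraph::V(x@graph)$name)

#' @export
setMethod("genes", "KnowledgeBase", function(x) x@universe@genes)

#' Protein-coding subset of a universe
#' @param x a [GeneUniverse-class].
#' @return character vector of coding gene identifiers.
#' @export
codingGenes <- function(x) x@genes[x@coding]

#' HLA-flagged genes of a universe
#' @param x a [GeneUniverse-class].
#' @export
hlaGenes <- function(x) x@genes[x@hla]

#' @rdname ProxySet-class
#' @export
setGeneric("proxyGenes", function(x) standardGeneric("proxyGenes"))

#' @export
setMethod("proxyGenes", "ProxySet", function(x) x@proxies)

#' @rdname ProxySet-class
#' @export
setGeneric("seedGenes", function(x) standardGeneric("seedGenes"))

#' @export
setMethod("seedGenes", "ProxySet", function(x) x@seeds)

#' @rdname HcghSet-class
#' @param x an [HcghSet-class].
#' @export
hcghGenes <- function(x) x@hits$gene_id

#' @rdname KnowledgeBase-class
#' @param x a [KnowledgeBase-class].
#' @export
universe <- function(x) x@universe

#' @rdname SyntheticWorld-class
#' @param x a [SyntheticWorld-class].
#' @export
knowledgeBase <- function(x) x@kb

## ---- show methods ------------------------------------------------------

setMethod("show", "GeneUniverse", function(object) {
    cat("GeneUniverse with", length(object@genes), "genes (",
        sum(object@coding), "coding,", sum(object@hla), "HLA )\n")
})

setMethod("show", "Interactome", function(object) {
    cat("Interactome '", object@name, "': ",
        igraph::vcount(object@graph), " genes, ",
        igraph::ecount(object@graph), " edges\n", sep = "")
})

setMethod("show", "ComplexSet", function(object) {
    cat("ComplexSet with", length(object@sets), "complexes (sizes",
        if (length(object@sets)) paste(range(lengths(object@sets)),
            collapse = "-") else "NA", ")\n")
})

setMethod("show", "LigandReceptorMap", function(object) {
    cat("LigandReceptorMap with", nrow(object@pairs), "pairs\n")
})

setMethod("show", "PathwaySet", function(object) {
    cat("PathwaySet with", length(object@sets), "pathways,",
        nrow(object@edges), "internal edges\n")
})

setMethod("show", "KnowledgeBase", function(object) {
    cat("KnowledgeBase\n")
    show(object@universe); show(object@interactome)
    show(object@complexes); show(object@lrPairs); show(object@pathways)
})

setMethod("show", "ProxySet", function(object) {
    cat("ProxySet [", object@method, "] trait ", object@traitId, ": ",
        length(object@seeds), " seeds -> ", length(object@proxies),
        " proxies\n", sep = "")
})

setMethod("show", "HcghSet", function(object) {
    cat("HcghSet trait ", object@traitId, ": ", nrow(object@hits),
        " high-confidence hits\n", sep = "")
})

setMethod("show", "DiffusionResult", function(object) {
    cat("DiffusionResult: ", length(object@genes), " genes, beta = ",
        object@beta, "\n", sep = "")
})

setMethod("show", "SyntheticWorld", function(object) {
    cat("SyntheticWorld:", length(object@kb@universe@genes), "genes,",
        nrow(object@traitIndication), "traits,",
        nrow(object@coloc), "coloc records,",
        nrow(object@assets), "asset rows\n")
})
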