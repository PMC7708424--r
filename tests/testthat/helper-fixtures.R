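# Shared fixtures, all built in code.

# tiny hand-checkable knowledge base: path graph a-b-c-d plus a star
toyUniverse <- function() {
    GeneUniverse(c(letters[1:10], "hla1"),
        coding = c(rep(TRUE, 9), FALSE, TRUE),
        hla = c(rep(FALSE, 10), TRUE))
}

toyNet <- function() {
    Interactome(data.frame(from = c("a", "b", "c"),
                           to = c("b", "c", "d")), name = "toy")
}

toyKb <- function() {
    KnowledgeBase(toyUniverse(), toyNet(),
        ComplexSet(list(C1 = c("a", "b", "e"), C2 = c("f", "g"))),
        LigandReceptorMap(data.frame(
            ligand = c("a", "a", "h"), receptor = c("b", "c", "b"))),
        PathwaySet(list(P1 = c("a", "b", "c", "d")),
            data.frame(pathway = "P1",
                source = c("a", "b", "c"), target = c("b", "c", "d"))))
}

# small world cache so several test files can share one generation
.worldCache <- new.env(parent = emptyenv())

smallWorld <- function(seed = 7, ...) {
    key <- paste0("w", seed, "_", paste(c(...), collapse = "_"))
    if (is.null(.worldCache[[key]]))
        .worldCache[[key]] <- generateWorld(SimulationConfig(
            nGenes = 500, nTraits = 8, nComplexes = 80, nPathways = 30,
            pathwaySizeRange = c(8, 40), lociPerTrait = c(8, 16),
            moduleSize = c(8, 14), testedPerTrait = c(40, 70),
            variantsPerGene = 6, seed = seed, ...))
    .worldCache[[key]]
}

# brute-force breadth-first search oracle for neighborhood expansion
bfsWithin <- function(edges, seeds, order) {
    adj <- list()
    for (i in seq_len(nrow(edges))) {
        a <- edges[i, 1]; b <- edges[i, 2]
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
    }
    reached <- seeds
    frontier <- seeds
    for (k in seq_len(order)) {
        frontier <- setdiff(unique(unlist(adj[frontier])), reached)
        reached <- c(reached, frontier)
    }
    sort(setdiff(reached, seeds))
}
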