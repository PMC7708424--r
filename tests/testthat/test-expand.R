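test_that("complex and pathway clique expansion apply set rules", {
    cs <- ComplexSet(list(c("g1", "g2", "g3"), c("g4", "g5")))
    expect_setequal(proxyGenes(complexProxies("g1", cs)), c("g2", "g3"))
    expect_length(proxyGenes(complexProxies("g9", cs)), 0)
    expect_setequal(proxyGenes(complexProxies(c("g1", "g4"), cs)),
        c("g2", "g3", "g5"))

    pw <- PathwaySet(list(P1 = paste0("g", 1:10)))
    expect_setequal(proxyGenes(pathwayCliqueProxies("g1", pw)),
        paste0("g", 2:10))
    ov <- PathwaySet(list(P1 = c("g1", "g2"), P2 = c("g1", "g3")))
    expect_setequal(proxyGenes(pathwayCliqueProxies("g1", ov)),
        c("g2", "g3"))
    expect_length(proxyGenes(pathwayCliqueProxies("zz", pw)), 0)
})

test_that("ligand-receptor expansion is strictly first-neighbor", {
    lr <- LigandReceptorMap(data.frame(
        ligand = c("L1", "L1", "L2"), receptor = c("R1", "R2", "R1")))
    # a seed ligand reaches its receptors but never their other ligands
    expect_setequal(proxyGenes(ligandReceptorProxies("L1", lr)),
        c("R1", "R2"))
    expect_setequal(proxyGenes(ligandReceptorProxies("R1", lr)),
        c("L1", "L2"))
    expect_length(proxyGenes(ligandReceptorProxies("X", lr)), 0)
})

test_that("network neighborhoods follow graph distance", {
    net <- toyNet()  # path a-b-c-d
    expect_identical(proxyGenes(networkNeighbors("a", net, 1)), "b")
    expect_setequal(proxyGenes(networkNeighbors("a", net, 2)),
        c("b", "c"))
    star <- Interactome(data.frame(from = "hub",
        to = paste0("leaf", 1:50)))
    expect_setequal(proxyGenes(networkNeighbors("hub", star, 1)),
        paste0("leaf", 1:50))
    expect_warning(networkNeighbors(c("a", "nope"), net, 1),
        "absent from network")
})

test_that("pathway neighbors walk upstream and downstream edges", {
    pw <- PathwaySet(list(P1 = c("g1", "g2", "g3", "g4")),
        data.frame(pathway = "P1", source = c("g1", "g2", "g3"),
                   target = c("g2", "g3", "g4")))
    expect_setequal(proxyGenes(pathwayNeighbors("g2", pw, 1)),
        c("g1", "g3"))
    expect_setequal(proxyGenes(pathwayNeighbors("g1", pw, 2)),
        c("g2", "g3"))
    lonely <- PathwaySet(list(P1 = c("g1", "g9")),
        data.frame(pathway = "P1", source = "g1", target = "g1")[0, ])
    expect_length(proxyGenes(pathwayNeighbors("g9", lonely, 1)), 0)
})

test_that("proxy sets are disjoint from seeds and order-2 contains order-1", {
    w <- smallWorld()
    hs <- defineHcghsByTrait(w@coloc, w@kb@universe)
    for (tr in names(hs)[1:4]) {
        seeds <- hcghGenes(hs[[tr]])
        ps <- expandProxies(seeds, w@kb, tr)
        for (p in ps) {
            expect_length(intersect(seedGenes(p), proxyGenes(p)), 0)
            expect_true(all(proxyGenes(p) %in% genes(w@kb)))
        }
        expect_true(all(proxyGenes(ps$net_neighbor1) %in%
                        proxyGenes(ps$net_neighbor2)))
        expect_true(all(proxyGenes(ps$pathway_neighbor1) %in%
                        proxyGenes(ps$pathway_neighbor2)))
    }
})

test_that("network neighborhoods agree with breadth-first search", {
    set.seed(42)
    for (rep in 1:5) {
        nv <- 100
        edges <- data.frame(
            from = paste0("n", sample.int(nv, 150, replace = TRUE)),
            to = paste0("n", sample.int(nv, 150, replace = TRUE)))
        edges <- edges[edges$from != edges$to, ]
        net <- Interactome(edges)
        seeds <- sample(unique(c(edges$from, edges$to)), 3)
        for (ord in 1:2) {
            got <- sort(proxyGenes(networkNeighbors(seeds, net, ord)))
            expect_identical(got, bfsWithin(as.matrix(edges), seeds, ord))
        }
    }
})

test_that("clique expansions are idempotent once a set is covered", {
    cs <- ComplexSet(list(c("g1", "g2", "g3")))
    first <- proxyGenes(complexProxies("g1", cs))
    again <- proxyGenes(complexProxies(c("g1", first), cs))
    expect_length(again, 0)
})

test_that("random baseline is reproducible and approximately uniform", {
    u <- GeneUniverse(sprintf("g%04d", 1:2100),
        coding = c(rep(TRUE, 2000), rep(FALSE, 100)))
    a <- proxyGenes(randomProxies(u, 100, seed = 5))
    b <- proxyGenes(randomProxies(u, 100, seed = 5))
    expect_identical(a, b)
    expect_true(all(a %in% codingGenes(u)))
    expect_error(randomProxies(u, 3000), "coding universe")
    full <- proxyGenes(randomProxies(u, 2000, seed = 1))
    expect_setequal(full, codingGenes(u))
    # inclusion frequency of each gene across draws stays within 4
    # binomial standard errors of n/N = 0.05
    counts <- integer(2000)
    for (s in 1:200) {
        idx <- match(proxyGenes(randomProxies(u, 100, seed = s)),
            codingGenes(u))
        counts[idx] <- counts[idx] + 1L
    }
    se <- sqrt(0.05 * 0.95 / 200)
    expect_true(all(abs(counts / 200 - 0.05) < 4 * se))
})
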