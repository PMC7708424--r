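# reachability-closure oracle for strongly connected components
bruteScc <- function(adj, kMin) {
    n <- nrow(adj)
    reach <- adj | diag(n) > 0
    for (k in seq_len(n))
        reach <- reach | (reach %*% reach) > 0
    mutual <- reach & t(reach)
    comp <- rep(NA_integer_, n)
    cid <- 0L
    for (i in seq_len(n)) if (is.na(comp[i])) {
        cid <- cid + 1L
        comp[which(mutual[i, ])] <- cid
    }
    sizes <- table(comp)
    lapply(names(sizes)[sizes >= kMin], function(k)
        sort(rownames(adj)[comp == as.integer(k)]))
}

test_that("heat transform is exact and clips a posterior of one", {
    expect_equal(heatScore(c(0, 0.5, 0.75)), c(0, 1, 2))
    expect_warning(h <- heatScore(1), "clipped")
    expect_equal(h, 20)  # -log2(2^-20)
    expect_true(all(diff(heatScore(seq(0, 0.99, 0.01))) > 0))
})

test_that("two-node diffusion matches the closed-form inversion", {
    net <- Interactome(data.frame(from = "a", to = "b"))
    d <- diffusionOperator(net, beta = 0.5)
    expect_equal(unname(d@F[1, 1]), 2 / 3, tolerance = 1e-12)
    expect_equal(colSums(d@F), setNames(c(1, 1), d@genes),
        tolerance = 1e-12)
})

test_that("heat is conserved on random graphs for several restarts", {
    set.seed(3)
    for (rep in 1:4) {
        g <- igraph::sample_gnp(60, 0.08)
        igraph::V(g)$name <- paste0("n", 1:60)
        net <- new("Interactome", graph = igraph::simplify(g),
            name = "rnd")
        for (beta in c(0.25, 0.4, 0.55)) {
            d <- suppressWarnings(diffusionOperator(net, beta))
            expect_lt(max(abs(colSums(d@F) - 1)), 1e-8)
            h <- setNames(runif(length(d@genes)), d@genes)
            E <- exchangedHeat(d, h)
            expect_equal(sum(E), sum(h), tolerance = 1e-8)
        }
    }
})

test_that("restart probability near one keeps heat at the source", {
    net <- Interactome(data.frame(from = c("a", "b"), to = c("b", "c")))
    d <- diffusionOperator(net, beta = 1 - 1e-9)
    expect_equal(d@F, diag(3), ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("zero heat exchanges nothing", {
    net <- toyNet()
    d <- diffusionOperator(net, 0.4)
    E <- exchangedHeat(d, setNames(numeric(4), genes(net)))
    expect_true(all(E == 0))
})

test_that("module extraction equals brute-force SCCs on toy graphs", {
    set.seed(9)
    for (rep in 1:10) {
        n <- 12
        E <- matrix(runif(n * n) * (runif(n * n) < 0.2), n, n)
        diag(E) <- 0
        gn <- paste0("g", seq_len(n))
        dimnames(E) <- list(gn, gn)
        delta <- 0.05
        mods <- extractModules(E, delta, 2)
        # edge j -> i iff E[i,j] >= delta; oracle adjacency is transpose
        oracle <- bruteScc(t(E >= delta), 2)
        expect_setequal(lapply(mods, paste, collapse = ","),
            lapply(oracle, paste, collapse = ","))
        # modules are disjoint
        expect_false(anyDuplicated(unlist(mods)) > 0)
    }
})

test_that("a single hot 3-cycle is the only module in a toy matrix", {
    gn <- paste0("g", 1:10)
    E <- matrix(0.01, 10, 10, dimnames = list(gn, gn))
    E[2, 1] <- E[3, 2] <- E[1, 3] <- 0.9   # 1 -> 2 -> 3 -> 1
    mods <- extractModules(E, 0.5, 3)
    expect_length(mods, 1)
    expect_setequal(mods[[1]], c("g1", "g2", "g3"))
    expect_length(extractModules(E, 1e6, 3), 0)
})

test_that("threshold selection is deterministic and flags degenerate heat", {
    w <- smallWorld()
    d <- suppressWarnings(diffusionOperator(w@kb@interactome, 0.4))
    heat <- colocHeat(w@coloc[w@coloc$trait_id == "T001", ])
    s1 <- selectDelta(d, heat, nPerm = 12, seed = 4)
    s2 <- selectDelta(d, heat, nPerm = 12, seed = 4)
    expect_identical(s1$delta, s2$delta)
    expect_warning(
        s0 <- selectDelta(d, setNames(numeric(length(d@genes)),
            d@genes), nPerm = 12, seed = 1),
        "degenerate")
    expect_gt(s0$delta, 0)
})

test_that("a planted hot clique is recovered as a module", {
    set.seed(31)
    g <- igraph::sample_pa(300, m = 2, directed = FALSE)
    igraph::V(g)$name <- sprintf("n%03d", 1:300)
    clique <- sample(igraph::V(g)$name, 6)
    extra <- t(utils::combn(clique, 2))
    g <- igraph::simplify(igraph::add_edges(g,
        as.vector(t(extra))))
    net <- new("Interactome", graph = g, name = "toy")
    d <- diffusionOperator(net, 0.4)
    heat <- setNames(rep(heatScore(0.95), 6), clique)
    hp <- hotnetProxies(d, heat, seeds = character(), nPerm = 20,
        seed = 2)
    best <- 0
    for (m in hp$modules) {
        jac <- length(intersect(m, clique)) /
            length(union(m, clique))
        best <- max(best, jac)
    }
    expect_gte(best, 0.8)
})

test_that("hotnet proxies respect proxy-set invariants", {
    w <- smallWorld()
    d <- suppressWarnings(diffusionOperator(w@kb@interactome, 0.4))
    hs <- defineHcghsByTrait(w@coloc, w@kb@universe)
    tr <- names(hs)[2]
    heat <- colocHeat(w@coloc[w@coloc$trait_id == tr, ])
    hp <- hotnetProxies(d, heat, hcghGenes(hs[[tr]]), tr, nPerm = 12,
        seed = 3)
    expect_s4_class(hp$proxies, "ProxySet")
    expect_length(intersect(proxyGenes(hp$proxies),
        seedGenes(hp$proxies)), 0)
})
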