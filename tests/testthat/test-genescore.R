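# Monte-Carlo oracle for the weighted chi-squared tail
mcTail <- function(q, lambda, n = 1e5) {
    draws <- colSums(lambda * matrix(stats::rchisq(n * length(lambda),
        df = 1), nrow = length(lambda)))
    mean(draws > q)
}

test_that("sum score reduces to chi-squared tails in simple cases", {
    # one variant: z^2 ~ chisq_1
    expect_equal(sumGeneScore(1.959964, matrix(1))$p, 0.05,
        tolerance = 1e-4)
    # identity LD, two variants: T ~ chisq_2
    p2 <- sumGeneScore(c(sqrt(3), sqrt(2.991)), diag(2))$p
    expect_equal(p2, pchisq(5.991, 2, lower.tail = FALSE),
        tolerance = 1e-5)
    # perfect LD over three variants: P(chisq_1 > T / 3)
    R <- matrix(1, 3, 3)
    z <- rep(1.3, 3)
    got <- sumGeneScore(z, R)$p
    expect_equal(got, pchisq(sum(z^2) / 3, 1, lower.tail = FALSE),
        tolerance = 1e-12)
})

test_that("analytic tail agrees with the Monte-Carlo oracle", {
    set.seed(5)
    for (rep in 1:6) {
        m <- sample(5:15, 1)
        A <- matrix(rnorm(m * m), m)
        R <- stats::cov2cor(crossprod(A) + diag(m))
        z <- as.numeric(chol(R) %*% rnorm(m)) + runif(1, 0, 1)
        sc <- sumGeneScore(z, R)
        lambda <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
        pm <- mcTail(sc$T, lambda)
        se <- sqrt(pm * (1 - pm) / 1e5) + 1e-6
        expect_lt(abs(sc$p - pm), 3 * se + 0.003)
    }
})

test_that("degenerate blocks are reported, not mis-scored", {
    expect_warning(out <- sumGeneScore(numeric(0), matrix(0, 0, 0)),
        "empty")
    expect_equal(nrow(out), 0)
    badR <- matrix(c(1, 2, 2, 1), 2)  # indefinite
    expect_error(sumGeneScore(c(1, 1), badR, "geneX"), "geneX")
})

test_that("null gene scores are uniform", {
    set.seed(8)
    m <- 8
    R <- 0.5^abs(outer(1:m, 1:m, "-"))
    U <- chol(R)
    p <- vapply(1:400, function(i)
        sumGeneScore(as.numeric(crossprod(U, rnorm(m))), R)$p,
        numeric(1))
    expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("fusion merges overlapping windows transitively", {
    blocks <- list(
        A = list(z = c(1, 2), R = diag(2)),
        B = list(z = 3, R = matrix(1)),
        C = list(z = c(0.5, 0.1), R = diag(2)),
        D = list(z = 1, R = matrix(1)))
    windows <- data.frame(gene_id = c("A", "B", "C", "D"),
        start = c(0, 120e3, 240e3, 900e3),
        end = c(50e3, 170e3, 290e3, 950e3))
    # with 50 kb padding: A-B overlap, B-C overlap, D isolated
    fused <- fuseGenes(blocks, c("A", "B", "C", "D"), windows)
    expect_setequal(names(fused), c("A|B|C", "D"))
    abc <- fused[["A|B|C"]]
    expect_length(abc$z, 5)
    expect_equal(dim(abc$R), c(5, 5))
    # fused unit is rescored with the same sum method
    expect_equal(sumGeneScore(abc$z, abc$R)$T, sum(c(1, 2, 3, 0.5, 0.1)^2))
    # far-apart genes stay distinct
    far <- fuseGenes(blocks, c("A", "D"), windows)
    expect_setequal(names(far), c("A", "D"))
    # fused universe partitions the input genes
    expect_setequal(unlist(lapply(fused, `[[`, "members")),
        c("A", "B", "C", "D"))
})

test_that("empirical pathway p has add-one bounds and a unit top", {
    geneP <- setNames(runif(50, 0.01, 1), paste0("g", 1:50))
    res <- pathwayEmpiricalP(geneP, names(geneP), nPerm = 200, seed = 1)
    expect_equal(res$p, 1)  # whole universe: no draw can exceed
    strong <- geneP
    strong[1:5] <- 1e-8
    res2 <- pathwayEmpiricalP(strong, paste0("g", 1:5), nPerm = 200,
        seed = 1)
    expect_gte(res2$p, 1 / 201)
    expect_lte(res2$p, 5 / 201)
    expect_warning(pathwayEmpiricalP(geneP, "absent", nPerm = 200),
        "no scored members")
})

test_that("empirical pathway p is uniform under the null", {
    set.seed(12)
    geneP <- setNames(runif(300), paste0("g", 1:300))
    p <- vapply(1:120, function(i)
        pathwayEmpiricalP(geneP, sample(names(geneP), 15),
            nPerm = 400, seed = 1000 + i)$p, numeric(1))
    expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("BH adjustment matches the hand-computed step-up rule", {
    expect_equal(bhAdjust(0.03), 0.03)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
    expect_length(bhAdjust(numeric(0)), 0)
    p <- c(0.001, 0.008, 0.039, 0.041, 0.6)
    manual <- rev(cummin(rev(p * 5 / seq_along(p))))
    expect_equal(bhAdjust(p), pmin(manual, 1))
})

test_that("proxy selection respects pathway, gene, HLA and seed filters", {
    enrich <- list(
        table = data.frame(pathway_id = c("P1", "P2"),
            S = c(10, 5), n_scored = c(3, 3), p = c(0.001, 0.5),
            adj_p = c(0.002, 0.5)),
        memberP = list(
            P1 = c(gA = 0.04, gB = 0.2, gHLA = 0.01, gSeed = 0.001),
            P2 = c(gC = 0.001)))
    ps <- selectPathwayProxies(enrich, hlaGenes = "gHLA",
        seeds = "gSeed")
    expect_identical(proxyGenes(ps), "gA")
    # no pathway passing -> empty
    enrich$table$adj_p <- c(0.5, 0.6)
    expect_length(proxyGenes(selectPathwayProxies(enrich)), 0)
})
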