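# independently coded textbook formulas (explicit loops) used as the
# oracle for the pooled statistics
oracleCmh <- function(tabs) {
    sumR <- 0; sumS <- 0
    sumPR <- 0; sumPSQR <- 0; sumQS <- 0
    sumA <- 0; sumE <- 0; sumV <- 0
    for (i in seq_len(nrow(tabs))) {
        a <- tabs$a[i]; b <- tabs$b[i]; c <- tabs$c[i]; d <- tabs$d[i]
        n <- a + b + c + d
        R <- a * d / n; S <- b * c / n
        P <- (a + d) / n; Q <- (b + c) / n
        sumR <- sumR + R; sumS <- sumS + S
        sumPR <- sumPR + P * R
        sumPSQR <- sumPSQR + P * S + Q * R
        sumQS <- sumQS + Q * S
        sumA <- sumA + a
        sumE <- sumE + (a + b) * (a + c) / n
        sumV <- sumV + (a + b) * (c + d) * (a + c) * (b + d) /
            (n^2 * (n - 1))
    }
    or <- sumR / sumS
    v <- sumPR / (2 * sumR^2) + sumPSQR / (2 * sumR * sumS) +
        sumQS / (2 * sumS^2)
    stat <- (sumA - sumE)^2 / sumV
    list(or = or,
         ci = exp(log(or) + c(-1, 1) * 1.959963984540054 * sqrt(v)),
         stat = stat)
}

outcomesFixture <- function() {
    # 10 outcome targets: 4 successes, 6 clinical failures
    data.frame(gene_id = paste0("G", 1:10), indication_id = "i1",
        outcome = rep(c("Succeeded", "ClinicalFailure"), c(4, 6)),
        furthest_phase = "PhaseII", stringsAsFactors = FALSE)
}

enrUniverse <- GeneUniverse(paste0("G", 1:20))
tiMap <- data.frame(trait_id = "t1", indication_id = "i1")

test_that("contingency tables count the outcome-bearing population", {
    # proxies cover 2 successes and 1 failure
    ps <- ProxySet("t1", "m", seeds = character(),
        proxies = c("G1", "G2", "G5"))
    tab <- buildContingencyTable(ps, outcomesFixture(), tiMap,
        enrUniverse)
    expect_equal(unlist(tab[c("a", "b", "c", "d")]),
        c(a = 2, b = 1, c = 2, d = 5))
    # no overlap -> removed
    none <- ProxySet("t1", "m", character(), c("G15", "G16"))
    expect_null(buildContingencyTable(none, outcomesFixture(), tiMap,
        enrUniverse))
    # full overlap keeps the table: the removal rule tests a and b only
    all10 <- ProxySet("t1", "m", character(), paste0("G", 1:10))
    tabAll <- buildContingencyTable(all10, outcomesFixture(), tiMap,
        enrUniverse)
    expect_equal(unlist(tabAll[c("c", "d")]), c(c = 0, d = 0))
    # unmatched trait warns and yields no table
    ps2 <- ProxySet("t9", "m", character(), "G1")
    expect_warning(
        expect_null(buildContingencyTable(ps2, outcomesFixture(),
            tiMap, enrUniverse)), "no matched indication")
})

test_that("seeds are excluded from the counted population", {
    ps <- ProxySet("t1", "m", seeds = c("G1", "G5"),
        proxies = c("G2", "G6"))
    tab <- buildContingencyTable(ps, outcomesFixture(), tiMap,
        enrUniverse)
    # population is G2..G4 (successes) G6..G10 (failures) minus seeds
    expect_equal(unlist(tab[c("a", "b", "c", "d")]),
        c(a = 1, b = 1, c = 2, d = 4))
})

test_that("the Haldane correction fires only on a zero in a or b", {
    t1 <- data.frame(trait_id = "t", method = "m", a = 0, b = 5,
        c = 10, d = 100, corrected = FALSE)
    expect_equal(unlist(haldaneCorrect(t1)[c("a", "b", "c", "d")]),
        c(a = 0.5, b = 5.5, c = 10.5, d = 100.5))
    t2 <- t1; t2[c("a", "b", "c", "d")] <- c(3, 4, 5, 6)
    expect_equal(unlist(haldaneCorrect(t2)[c("a", "b", "c", "d")]),
        c(a = 3, b = 4, c = 5, d = 6))
    t3 <- t1; t3[c("a", "b", "c", "d")] <- c(7, 0, 2, 9)
    expect_equal(unlist(haldaneCorrect(t3)[c("a", "b", "c", "d")]),
        c(a = 7.5, b = 0.5, c = 2.5, d = 9.5))
    expect_true(haldaneCorrect(t3)$corrected)
})

test_that("a single stratum reduces to the plain odds ratio", {
    tab <- data.frame(a = 2, b = 1, c = 1, d = 2)
    res <- cmhPool(tab)
    expect_equal(res$or, 4)
    k <- tab[rep(1, 7), ]
    expect_equal(cmhPool(k)$or, 4)
})

test_that("pooled statistics match the brute-force textbook oracle", {
    set.seed(2)
    for (rep in 1:10) {
        k <- sample(2:12, 1)
        tabs <- data.frame(
            a = stats::rpois(k, 3), b = stats::rpois(k, 4),
            c = stats::rpois(k, 8), d = stats::rpois(k, 20))
        tabs <- haldaneCorrect(cbind(
            data.frame(trait_id = paste0("t", seq_len(k)), method = "m"),
            tabs, corrected = FALSE))
        res <- cmhPool(tabs)
        orc <- oracleCmh(tabs)
        expect_equal(res$or, orc$or, tolerance = 1e-10)
        expect_equal(res$ci_low, orc$ci[1], tolerance = 1e-10)
        expect_equal(res$ci_high, orc$ci[2], tolerance = 1e-10)
        expect_equal(res$statistic, orc$stat, tolerance = 1e-10)
    }
})

test_that("pooled statistics agree with mantelhaen.test on integer strata", {
    set.seed(4)
    k <- 6
    tabs <- data.frame(a = stats::rpois(k, 5) + 1,
        b = stats::rpois(k, 5) + 1, c = stats::rpois(k, 9) + 1,
        d = stats::rpois(k, 15) + 1)
    arr <- array(0, c(2, 2, k))
    for (i in seq_len(k))
        arr[, , i] <- matrix(c(tabs$a[i], tabs$c[i], tabs$b[i],
            tabs$d[i]), 2)
    mh <- stats::mantelhaen.test(arr, correct = FALSE)
    res <- cmhPool(tabs)
    expect_equal(res$or, unname(mh$estimate), tolerance = 1e-8)
    expect_equal(res$statistic, unname(mh$statistic), tolerance = 1e-8)
    expect_equal(c(res$ci_low, res$ci_high),
        as.numeric(mh$conf.int), tolerance = 1e-8)
})

test_that("MH pooling is invariant to stratum order and duplication", {
    set.seed(6)
    tabs <- data.frame(a = c(2, 1, 4), b = c(1, 3, 2), c = c(5, 4, 7),
        d = c(9, 12, 6))
    base <- cmhPool(tabs)$or
    expect_equal(cmhPool(tabs[c(3, 1, 2), ])$or, base)
    expect_equal(cmhPool(tabs[rep(1:3, 2), ])$or, base)
})

test_that("degenerate stratum sets return a diagnostic row", {
    tabs <- data.frame(a = c(0, 0), b = c(2, 3), c = c(4, 5),
        d = c(6, 7))
    res <- cmhPool(tabs)
    expect_true(is.na(res$or))
    expect_match(res$note, "undefined")
})

test_that("method summaries aggregate sizes and flag missing data", {
    w <- smallWorld()
    out <- classifyTargetIndication(w@assets)
    hs <- defineHcghsByTrait(w@coloc, w@kb@universe)
    traits <- retainTraits(hs, out, w@traitIndication)[1:4]
    proxySets <- list()
    for (tr in traits) {
        seeds <- hcghGenes(hs[[tr]])
        ps <- expandProxies(seeds, w@kb, tr, c("complex", "random"))
        proxySets$complex[[tr]] <- ps$complex
        proxySets$empty[[tr]] <- ProxySet(tr, "empty", seeds,
            character())
        proxySets$complex2[[tr]] <- ps$complex
    }
    results <- lapply(proxySets, methodEnrichment, outcomes = out,
        traitIndication = w@traitIndication, universe = w@kb@universe)
    summ <- summarizeMethods(results, proxySets)
    expect_match(summ$note[summ$method == "empty"], "no data")
    # identical proxy sets under two labels give identical statistics
    expect_equal(summ$or[summ$method == "complex"],
        summ$or[summ$method == "complex2"])
    expect_equal(summ$mean_new_targets[summ$method == "complex"],
        mean(vapply(proxySets$complex, function(p)
            length(proxyGenes(p)), 0L)))
})
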