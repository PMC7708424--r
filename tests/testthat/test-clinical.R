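mkAsset <- function(asset, gene, status, phase, ind = "i1") {
    data.frame(asset_id = asset, gene_id = gene, indication_id = ind,
        status_text = status, phase_reached = phase,
        stringsAsFactors = FALSE)
}

test_that("raw status mapping matches the three-way rule", {
    expect_identical(
        classifyAssetStatus(c("Launched", "Discontinued",
            "No Development Reported", "Withdrawn", "Suspended",
            "Phase II Clinical Trial", "Preregistration")),
        c("Succeeded", "Failed", "Failed", "Failed", "Failed",
          "InProgress", "InProgress"))
})

test_that("precedence resolves every rule level", {
    sel <- function(a, st, ph) mkAsset(a, "G1", st, ph)
    nonsel <- function(a, st, ph)
        rbind(mkAsset(a, "G1", st, ph), mkAsset(a, "G9", st, ph))
    cases <- list(
        # 1: selective success dominates selective clinical failures
        list(rbind(sel("a1", "Launched", "Launched"),
                   sel("a2", "Discontinued", "PhaseII"),
                   sel("a3", "Discontinued", "PhaseIII")),
             "Succeeded"),
        # 2: selective clinical failure precedes non-selective success
        list(rbind(nonsel("a1", "Launched", "Launched"),
                   sel("a2", "Discontinued", "PhaseII")),
             "ClinicalFailure"),
        # 3: non-selective success beats non-selective clinical failure
        list(rbind(nonsel("a1", "Launched", "Launched"),
                   nonsel("a2", "Discontinued", "PhaseII")),
             "Succeeded"),
        # 4: non-selective clinical failure beats preclinical failures
        list(rbind(nonsel("a1", "Withdrawn", "PhaseI"),
                   sel("a2", "Discontinued", "Preclinical")),
             "ClinicalFailure"),
        # 5: selective preclinical failure alone
        list(sel("a1", "Discontinued", "Preclinical"),
             "PreclinicalFailure"),
        # 6: non-selective preclinical failure alone
        list(nonsel("a1", "Suspended", "Preclinical"),
             "PreclinicalFailure"),
        # 7: nothing decisive
        list(sel("a1", "Phase II Clinical Trial", "PhaseII"),
             "InProgress"))
    for (cs in cases) {
        out <- classifyTargetIndication(cs[[1]])
        expect_identical(
            out$outcome[out$gene_id == "G1"], cs[[2]])
    }
})

test_that("classification ignores row order and records furthest phase", {
    assets <- rbind(
        mkAsset("a1", "G1", "Discontinued", "PhaseII"),
        mkAsset("a2", "G1", "Launched", "Launched"),
        mkAsset("a3", "G1", "Discontinued", "Preclinical"))
    base <- classifyTargetIndication(assets)
    set.seed(1)
    for (i in 1:5) {
        shuf <- classifyTargetIndication(assets[sample.int(3), ])
        expect_identical(shuf, base)
    }
    expect_identical(base$furthest_phase, "Launched")
})

test_that("adding a selective launched asset only upgrades to Succeeded", {
    set.seed(11)
    statuses <- c("Launched", "Discontinued", "No Development Reported",
        "Phase II Clinical Trial")
    phases <- c("Preclinical", "PhaseI", "PhaseII", "Launched")
    for (i in 1:20) {
        n <- sample(1:4, 1)
        assets <- do.call(rbind, lapply(seq_len(n), function(k)
            mkAsset(paste0("a", k), "G1", sample(statuses, 1),
                sample(phases, 1))))
        before <- classifyTargetIndication(assets)
        after <- classifyTargetIndication(rbind(assets,
            mkAsset("anew", "G1", "Launched", "Launched")))
        expect_identical(
            after$outcome[after$gene_id == "G1"], "Succeeded")
        expect_true(before$outcome[before$gene_id == "G1"] %in%
            c("Succeeded", "ClinicalFailure", "PreclinicalFailure",
              "InProgress"))
    }
})

test_that("every asset-bearing pair receives exactly one outcome", {
    w <- smallWorld()
    out <- classifyTargetIndication(w@assets)
    pairs <- unique(w@assets[c("gene_id", "indication_id")])
    expect_equal(nrow(out), nrow(pairs))
    expect_false(anyDuplicated(out[c("gene_id", "indication_id")]) > 0)
    counts <- table(out$outcome)
    expect_equal(sum(counts), nrow(pairs))
})

test_that("blacklisted indications are dropped and empty targets rejected", {
    assets <- rbind(
        mkAsset("a1", "G1", "Launched", "Launched", ind = "Undisclosed"),
        mkAsset("a2", "G2", "Launched", "Launched"))
    out <- classifyTargetIndication(assets)
    expect_identical(out$gene_id, "G2")
    bad <- mkAsset("a1", "", "Launched", "Launched")
    expect_error(classifyTargetIndication(bad), "zero targets")
})

test_that("positive and negative sets partition the decisive outcomes", {
    outcomes <- data.frame(
        gene_id = paste0("G", 1:4), indication_id = "i1",
        outcome = c("Succeeded", "ClinicalFailure",
            "PreclinicalFailure", "InProgress"),
        furthest_phase = "PhaseII", stringsAsFactors = FALSE)
    sets <- outcomeSets(outcomes)
    expect_identical(sets$positive$gene_id, "G1")
    expect_identical(sets$negative$gene_id, "G2")
    empty <- outcomeSets(outcomes[0, ])
    expect_equal(nrow(empty$positive), 0)
    expect_equal(nrow(empty$negative), 0)
    allProg <- outcomes; allProg$outcome <- "InProgress"
    sets2 <- outcomeSets(allProg)
    expect_equal(nrow(sets2$positive) + nrow(sets2$negative), 0)
})
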