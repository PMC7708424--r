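## Stratified enrichment of proxy genes among clinically succeeded
## versus clinically failed drug targets: per-trait 2x2 tables, the
## Haldane correction, and Cochran-Mantel-Haenszel pooling with a
## Robins-Breslow-Greenland confidence interval.

#' Build the 2x2 success/failure table for one trait and method
#'
#' The counted population is the protein-coding genes that carry a
#' Succeeded (success) or ClinicalFailure (failure) outcome for an
#' indication matched to the trait, with the seed hits excluded so the
#' comparison is proxies versus non-proxy, non-seed genes. A gene with
#' outcomes for several matched indications counts once: as a success
#' if any matched indication succeeded, else as a failure. Cells:
#' \code{a} proxies-and-success, \code{b} proxies-and-failure,
#' \code{c}/\code{d} the complements. Tables with both \code{a} and
#' \code{b} equal to zero (no overlap between proxies and any
#' outcome-bearing target) are removed: \code{NULL} is returned.
#'
#' @param proxies a [ProxySet-class].
#' @param outcomes classified outcomes from
#'   [classifyTargetIndication()].
#' @param traitIndication trait-to-indication map.
#' @param universe a [GeneUniverse-class].
#' @param excludeSeeds drop seed genes from the counted population
#'   (default TRUE).
#' @return one-row data.frame (trait_id, method, a, b, c, d,
#'   corrected) or \code{NULL} when the table is removed or the trait
#'   has no matched indication.
#' @export
buildContingencyTable <- function(proxies, outcomes, traitIndication,
                                  universe, excludeSeeds = TRUE) {
    tr <- proxies@traitId
    inds <- traitIndication$indication_id[traitIndication$trait_id == tr]
    if (!length(inds)) {
        warning("trait ", tr, " has no matched indication; no table")
        return(NULL)
    }
    oc <- outcomes[outcomes$indication_id %in% inds &
                   outcomes$outcome %in% c("Succeeded",
                       "ClinicalFailure"), , drop = FALSE]
    oc <- oc[oc$gene_id %in% codingGenes(universe), , drop = FALSE]
    if (excludeSeeds)
        oc <- oc[!(oc$gene_id %in% proxies@seeds), , drop = FALSE]
    if (!nrow(oc)) return(NULL)
    succ <- tapply(oc$outcome == "Succeeded", oc$gene_id, any)
    gene <- names(succ)
    hit <- gene %in% proxies@proxies
    a <- sum(hit & succ); b <- sum(hit & !succ)
    if (a == 0 && b == 0) return(NULL)
    data.frame(trait_id = tr, method = proxies@method,
        a = a, b = b, c = sum(!hit & succ), d = sum(!hit & !succ),
        corrected = FALSE, stringsAsFactors = FALSE)
}

#' Haldane correction of a sparse 2x2 table
#'
#' Where \code{a} or \code{b} equals zero (but not both: such tables
#' were removed), 0.5 is added to every cell so the odds ratio stays
#' finite and defined; other tables pass through unchanged.
#'
#' @param table one-row table data.frame from
#'   [buildContingencyTable()], or a stack of them.
#' @return the table(s) with corrected cells and flag.
#' @examples
#' t0 <- data.frame(trait_id = "t", method = "m", a = 0, b = 5, c = 10,
#'     d = 100, corrected = FALSE)
#' haldaneCorrect(t0)[, c("a", "b", "c", "d")]  # 0.5 5.5 10.5 100.5
#' @export
haldaneCorrect <- function(table) {
    needs <- table$a == 0 | table$b == 0
    table[needs, c("a", "b", "c", "d")] <-
        table[needs, c("a", "b", "c", "d")] + 0.5
    table$corrected <- needs
    table
}

#' Pool stratified 2x2 tables with the Cochran-Mantel-Haenszel framework
#'
#' The pooled odds ratio is the Mantel-Haenszel estimator
#' \eqn{\sum_i a_i d_i / n_i \; / \; \sum_i b_i c_i / n_i}; its 95\%
#' confidence interval uses the Robins-Breslow-Greenland variance of
#' the log odds ratio; the CMH chi-squared statistic
#' \eqn{(|\sum_i (a_i - E_i)| - cc)^2 / \sum_i V_i} is computed without
#' continuity correction by default. Haldane-corrected (non-integer)
#' cells feed all three quantities.
#'
#' @param tables data.frame of (possibly corrected) stratum tables with
#'   columns \code{a}, \code{b}, \code{c}, \code{d}.
#' @param continuityCorrection subtract 0.5 inside the CMH statistic
#'   (default FALSE).
#' @param confLevel confidence level (default 0.95).
#' @return one-row data.frame: \code{or}, \code{ci_low},
#'   \code{ci_high}, \code{p}, \code{statistic}, \code{n_strata}. When
#'   every stratum has a zero Mantel-Haenszel denominator the odds
#'   ratio is undefined and an NA row with a \code{note} is returned.
#' @export
cmhPool <- function(tables, continuityCorrection = FALSE,
                    confLevel = 0.95) {
    stopifnot(nrow(tables) >= 1)
    a <- tables$a; b <- tables$b; c <- tables$c; d <- tables$d
    n <- a + b + c + d
    R <- a * d / n
    S <- b * c / n
    if (sum(R) == 0 || sum(S) == 0)
        return(data.frame(or = NA_real_, ci_low = NA_real_,
            ci_high = NA_real_, p = NA_real_, statistic = NA_real_,
            n_strata = nrow(tables),
            note = "undefined MH odds ratio: zero numerator or denominator",
            stringsAsFactors = FALSE))
    or <- sum(R) / sum(S)
    # Robins-Breslow-Greenland variance of log(or)
    P <- (a + d) / n
    Q <- (b + c) / n
    varLog <- sum(P * R) / (2 * sum(R)^2) +
        sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
        sum(Q * S) / (2 * sum(S)^2)
    zq <- stats::qnorm(1 - (1 - confLevel) / 2)
    ciLow <- exp(log(or) - zq * sqrt(varLog))
    ciHigh <- exp(log(or) + zq * sqrt(varLog))
    # CMH chi-squared
    E <- (a + b) * (a + c) / n
    V <- (a + b) * (c + d) * (a + c) * (b + d) / (n^2 * (n - 1))
    V[n <= 1] <- 0
    dev <- abs(sum(a) - sum(E))
    if (continuityCorrection) dev <- max(0, dev - 0.5)
    stat <- dev^2 / sum(V)
    data.frame(or = or, ci_low = ciLow, ci_high = ciHigh,
        p = pchisq(stat, df = 1, lower.tail = FALSE), statistic = stat,
        n_strata = nrow(tables), note = "", stringsAsFactors = FALSE)
}

#' Per-trait tables and pooled enrichment for one method
#'
#' Builds one 2x2 table per trait from the method's proxy sets, applies
#' the removal rule and the Haldane correction, and pools the surviving
#' strata.
#'
#' @param proxySets list of [ProxySet-class], one per trait (all same
#'   method).
#' @param outcomes,traitIndication,universe as in
#'   [buildContingencyTable()].
#' @param ... passed to [cmhPool()].
#' @return list with \code{tables} (corrected strata) and
#'   \code{result} (pooled row; NA row when no stratum survives).
#' @export
methodEnrichment <- function(proxySets, outcomes, traitIndication,
                             universe, ...) {
    tabs <- lapply(proxySets, buildContingencyTable, outcomes = outcomes,
        traitIndication = traitIndication, universe = universe)
    tabs <- do.call(rbind, tabs[!vapply(tabs, is.null, logical(1))])
    if (is.null(tabs) || !nrow(tabs)) {
        return(list(tables = NULL,
            result = data.frame(or = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, p = NA_real_, statistic = NA_real_,
                n_strata = 0L, note = "no data: all tables removed",
                stringsAsFactors = FALSE)))
    }
    tabs <- haldaneCorrect(tabs)
    list(tables = tabs, result = cmhPool(tabs, ...))
}

#' Summarize enrichment across methods
#'
#' One row per method: pooled odds ratio with confidence interval and
#' CMH p-value, stratum count, and the mean and median number of new
#' targets (proxy genes) implicated per trait.
#'
#' @param results named list of [methodEnrichment()] outputs keyed by
#'   method.
#' @param proxySets named list (by method) of lists of
#'   [ProxySet-class].
#' @return data.frame summary table.
#' @export
summarizeMethods <- function(results, proxySets) {
    rows <- lapply(names(results), function(m) {
        r <- results[[m]]$result
        sizes <- vapply(proxySets[[m]], function(p)
            length(p@proxies), 0L)
        cbind(data.frame(method = m, stringsAsFactors = FALSE), r,
            data.frame(mean_new_targets = mean(sizes),
                median_new_targets = median(sizes)))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
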