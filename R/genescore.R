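## Sum-of-chi-squared gene scores with a weighted chi-squared null
## driven by the eigenvalues of the local LD matrix, gene fusion for
## neighboring genes sharing a gene set, and empirical (permutation)
## pathway enrichment with Benjamini-Hochberg adjustment.

# Imhof-type numerical inversion for P(sum_j lambda_j chisq_1 > q).
# Integrand of the characteristic-function inversion formula; finite at
# u = 0 with limit (sum(lambda) - q) / 2.
imhofTail <- function(q, lambda) {
    f <- function(u) {
        theta <- 0.5 * colSums(atan(outer(lambda, u))) - q * u / 2
        logRho <- 0.25 * colSums(log1p(outer(lambda^2, u^2)))
        ifelse(u == 0, (sum(lambda) - q) / 2, sin(theta) / u) *
            exp(-logRho)
    }
    val <- integrate(f, 0, Inf, rel.tol = 1e-6, abs.tol = 1e-9,
        subdivisions = 600L, stop.on.error = FALSE)
    ok <- val$message == "OK" ||
        (val$message == "maximum number of subdivisions reached" &&
         val$abs.error < 1e-6)
    if (!ok) stop("Imhof integration failed: ", val$message)
    0.5 + val$value / pi
}

# Satterthwaite moment-matching fallback: Q ~ c * chisq_nu with
# c = sum(lambda^2)/sum(lambda), nu = sum(lambda)^2/sum(lambda^2).
satterthwaiteTail <- function(q, lambda) {
    cc <- sum(lambda^2) / sum(lambda)
    nu <- sum(lambda)^2 / sum(lambda^2)
    pchisq(q / cc, df = nu, lower.tail = FALSE)
}

#' Tail probability of a weighted sum of one-df chi-squares
#'
#' \eqn{P(\sum_j \lambda_j \chi^2_1 > q)} computed by numerical
#' inversion of the characteristic function (Imhof's method), with a
#' Satterthwaite moment-matching approximation as fallback when the
#' inversion fails or leaves the unit interval. With a single non-zero
#' weight the exact scaled chi-squared tail is used.
#'
#' @param q non-negative quantile.
#' @param lambda non-negative weights; zeros are dropped.
#' @return tail probability in (0, 1].
#' @export
weightedChisqTail <- function(q, lambda) {
    lambda <- lambda[lambda > max(lambda) * 1e-12]
    if (length(lambda) == 1)
        return(pchisq(q / lambda, df = 1, lower.tail = FALSE))
    p <- tryCatch(imhofTail(q, lambda), error = function(e) NA_real_)
    if (is.na(p) || p <= 0 || p > 1) p <- satterthwaiteTail(q, lambda)
    min(max(p, 1e-300), 1)
}

#' Sum gene score from a variant block
#'
#' The sum statistic \eqn{T = \sum_i z_i^2} over the variants in the
#' gene window, with p-value from the null
#' \eqn{Q = \sum_j \lambda_j \chi^2_1} where \eqn{\lambda_j} are the
#' eigenvalues of the LD correlation matrix \eqn{R}.
#'
#' @param z numeric vector of variant z-scores.
#' @param R square LD correlation matrix matching \code{z}; must be
#'   positive semi-definite within tolerance.
#' @param geneId label used in error messages and the result.
#' @param tol relative tolerance on negative eigenvalues.
#' @return data.frame row with \code{gene_id}, \code{T}, \code{p}.
#' @examples
#' sumGeneScore(1.959964, matrix(1))$p  # ~0.05
#' @export
sumGeneScore <- function(z, R, geneId = "gene", tol = 1e-6) {
    z <- as.numeric(z)
    R <- as.matrix(R)
    if (!length(z)) {
        warning("empty variant block for ", geneId, "; gene skipped")
        return(data.frame(gene_id = character(), T = numeric(),
            p = numeric()))
    }
    stopifnot(length(z) == nrow(R), nrow(R) == ncol(R))
    lambda <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(lambda) < -tol * max(abs(lambda)))
        stop("LD matrix for ", geneId, " is not positive semi-definite")
    lambda <- pmax(lambda, 0)
    T <- sum(z^2)
    data.frame(gene_id = geneId, T = T,
        p = weightedChisqTail(T, lambda), stringsAsFactors = FALSE)
}

#' Score a list of variant blocks
#'
#' @param blocks named list, each element a list with \code{z} and
#'   \code{R}.
#' @return data.frame with one row per gene: \code{gene_id}, \code{T},
#'   \code{p}.
#' @export
scoreGenes <- function(blocks) {
    rows <- lapply(names(blocks), function(g)
        sumGeneScore(blocks[[g]]$z, blocks[[g]]$R, g))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Fuse neighboring genes sharing a gene set
#'
#' Genes belonging to the same set whose windows (gene body plus
#' \code{pad} on each side) overlap are merged transitively, so a chain
#' A-overlaps-B, B-overlaps-C yields one fused unit A|B|C. The fused
#' block concatenates the member variant blocks with block-diagonal LD
#' (cross-gene LD is not observed in per-gene LD files) and is rescored
#' with the same sum method as individual genes. This guards the
#' pathway statistic against double-counting one association signal
#' spread over several neighboring members.
#'
#' @param blocks named list of variant blocks (\code{z}, \code{R}).
#' @param geneSet character vector of set members to consider.
#' @param windows data.frame with \code{gene_id}, \code{start},
#'   \code{end} (gene body coordinates).
#' @param pad window padding in base pairs (default 50000, i.e. the
#'   gene body plus/minus 50 kb).
#' @return named list of fused blocks; each element carries \code{z},
#'   \code{R} and \code{members}. Units are named by their sorted
#'   members joined with \code{"|"}.
#' @export
fuseGenes <- function(blocks, geneSet, windows, pad = 50000) {
    geneSet <- intersect(geneSet, names(blocks))
    geneSet <- intersect(geneSet, windows$gene_id)
    if (!length(geneSet)) return(list())
    w <- windows[match(geneSet, windows$gene_id), , drop = FALSE]
    lo <- w$start - pad
    hi <- w$end + pad
    n <- length(geneSet)
    # connected components of the window-overlap graph
    comp <- seq_len(n)
    if (n > 1) {
        ord <- order(lo)
        reach <- hi[ord[1]]
        grp <- 1L
        gid <- integer(n)
        gid[ord[1]] <- grp
        for (k in seq_len(n)[-1]) {
            i <- ord[k]
            if (lo[i] > reach) grp <- grp + 1L
            reach <- max(reach, hi[i])
            gid[i] <- grp
        }
        comp <- gid
    }
    out <- lapply(split(geneSet, comp), function(members) {
        members <- sort(members)
        zs <- lapply(members, function(g) blocks[[g]]$z)
        Rs <- lapply(members, function(g) as.matrix(blocks[[g]]$R))
        m <- vapply(Rs, nrow, 0L)
        R <- matrix(0, sum(m), sum(m))
        at <- cumsum(c(0L, m))
        for (i in seq_along(Rs))
            R[(at[i] + 1):at[i + 1], (at[i] + 1):at[i + 1]] <- Rs[[i]]
        list(z = unlist(zs, use.names = FALSE), R = R, members = members)
    })
    names(out) <- vapply(out, function(b)
        paste(b$members, collapse = "|"), "")
    out
}

#' Empirical pathway enrichment p-value
#'
#' The pathway statistic is the Fisher-style sum
#' \eqn{S = \sum_{g} -\ln p_g} over the scored members (after fusion).
#' Its null is built by drawing size-matched gene sets without
#' replacement from the scored universe; the add-one estimator
#' \eqn{p = (1 + \#\{S^* \ge S\}) / (n_{perm} + 1)} never returns zero.
#'
#' @param geneP named numeric vector of gene (or fused-unit) p-values:
#'   the scored universe.
#' @param members character vector of pathway member identifiers.
#' @param nPerm number of random sets (at least 100; default 1000).
#' @param seed RNG seed; deterministic per seed.
#' @return list with \code{p}, the observed statistic \code{S} and the
#'   number of scored members used, or \code{NULL} (with a warning)
#'   when no member is scored.
#' @export
pathwayEmpiricalP <- function(geneP, members, nPerm = 1000, seed = 1) {
    stopifnot(nPerm >= 100)
    scored <- intersect(members, names(geneP))
    if (!length(scored)) {
        warning("pathway has no scored members; skipped")
        return(NULL)
    }
    S <- sum(-log(geneP[scored]))
    k <- length(scored)
    logp <- -log(as.numeric(geneP))
    exceed <- withSeed(seed, {
        sum(vapply(seq_len(nPerm), function(i)
            sum(logp[sample.int(length(logp), k)]) >= S, logical(1)))
    })
    list(p = (1 + exceed) / (nPerm + 1), S = S, nScored = k)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false discovery rate adjustment with monotonicity
#' enforcement (wraps \code{stats::p.adjust}).
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) p.adjust(p, method = "BH")

#' Pathway enrichment over a collection
#'
#' Fuses neighboring member genes per pathway, scores fused units with
#' the sum method, computes empirical enrichment p-values and adjusts
#' them across the collection with Benjamini-Hochberg. The empirical
#' null draws size-matched sets from the individual-gene scored
#' universe (no expression or size matching beyond set size).
#'
#' @param blocks named list of per-gene variant blocks.
#' @param geneScores data.frame from [scoreGenes()] over all genes.
#' @param pathways a [PathwaySet-class] (or any named list of gene
#'   sets via \code{pathways@sets}).
#' @param windows gene window data.frame for fusion.
#' @param nPerm,seed empirical null controls.
#' @param pad fusion window padding.
#' @return list with \code{table} (pathway_id, S, n_scored, p, adj_p)
#'   and \code{memberP}: per pathway, the named vector of member
#'   p-values at fused-unit resolution mapped back to genes.
#' @export
pathwayEnrichment <- function(blocks, geneScores, pathways, windows,
                              nPerm = 1000, seed = 1, pad = 50000) {
    sets <- pathways@sets
    geneP <- setNames(geneScores$p, geneScores$gene_id)
    rows <- vector("list", length(sets))
    memberP <- vector("list", length(sets))
    unitCache <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_along(sets)) {
        fused <- fuseGenes(blocks, sets[[i]], windows, pad)
        if (!length(fused)) next
        # singleton units keep their individual gene score; multi-gene
        # fused units are rescored once and cached across pathways
        fp <- vapply(names(fused), function(id) {
            b <- fused[[id]]
            if (length(b$members) == 1) return(geneP[[b$members]])
            hit <- get0(id, unitCache)
            if (!is.null(hit)) return(hit)
            p <- sumGeneScore(b$z, b$R, id)$p
            assign(id, p, unitCache)
            p
        }, numeric(1))
        # fused units enter the statistic through their own rescored p;
        # the null draws size-matched sets from the individual-gene
        # scored universe (unit p-values are uniform under the null
        # either way)
        S <- sum(-log(fp))
        k <- length(fp)
        logp <- -log(as.numeric(geneP))
        exceed <- withSeed(seed + i, {
            sum(vapply(seq_len(nPerm), function(j)
                sum(logp[sample.int(length(logp), k)]) >= S, logical(1)))
        })
        rows[[i]] <- data.frame(pathway_id = names(sets)[i], S = S,
            n_scored = k, p = (1 + exceed) / (nPerm + 1),
            stringsAsFactors = FALSE)
        # map fused-unit p back to each member gene
        gp <- unlist(lapply(seq_along(fused), function(j)
            setNames(rep(fp[j], length(fused[[j]]$members)),
                     fused[[j]]$members)))
        memberP[[i]] <- gp
    }
    keep <- !vapply(rows, is.null, logical(1))
    tab <- do.call(rbind, rows[keep])
    if (is.null(tab))
        return(list(table = data.frame(pathway_id = character(),
            S = numeric(), n_scored = integer(), p = numeric(),
            adj_p = numeric()), memberP = list()))
    tab$adj_p <- bhAdjust(tab$p)
    rownames(tab) <- NULL
    names(memberP) <- names(sets)
    list(table = tab, memberP = memberP[keep])
}

#' Select proxy genes from enriched pathways
#'
#' Proxies are the genes that (a) belong to a pathway whose
#' BH-adjusted empirical enrichment p-value is below \code{alpha},
#' (b) carry a nominally significant gene score (p below
#' \code{geneAlpha}, at fused-unit resolution), (c) are not HLA-flagged
#' and (d) are not seeds.
#'
#' @param enrich result of [pathwayEnrichment()].
#' @param hlaGenes character vector of HLA-flagged genes to exclude.
#' @param seeds seed genes.
#' @param traitId trait label.
#' @param alpha adjusted pathway threshold (default 0.05).
#' @param geneAlpha nominal gene-score threshold (default 0.05).
#' @return a [ProxySet-class] with method \code{"pascal"}.
#' @export
selectPathwayProxies <- function(enrich, hlaGenes = character(),
                                 seeds = character(), traitId = "trait",
                                 alpha = 0.05, geneAlpha = 0.05) {
    tab <- enrich$table
    sig <- tab$pathway_id[tab$adj_p < alpha]
    picks <- unlist(lapply(sig, function(pw) {
        gp <- enrich$memberP[[pw]]
        names(gp)[gp < geneAlpha]
    }))
    picks <- setdiff(unique(picks), hlaGenes)
    ProxySet(traitId, "pascal", seeds, picks)
}
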