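## Insulated heat diffusion (random walk with restart) over an
## interactome, with permutation-calibrated module extraction. Modules
## are strongly connected components of the thresholded exchanged-heat
## graph; module genes minus the seed hits form the propagation proxy
## set.

#' Colocalization heat transform
#'
#' Converts a colocalization posterior probability into diffusion heat:
#' \eqn{h = -\log_2(1 - p12)}, non-negative and strictly increasing in
#' p12. A posterior of exactly 1 would give infinite heat and is
#' clipped to \code{p12Max} with a warning.
#'
#' @param p12 numeric vector of posteriors in [0, 1].
#' @param p12Max clipping bound (default \code{1 - 2^-20}).
#' @return numeric heat vector.
#' @examples
#' heatScore(c(0, 0.5, 0.75))  # 0, 1, 2
#' @export
heatScore <- function(p12, p12Max = 1 - 2^-20) {
    stopifnot(all(p12 >= 0 & p12 <= 1))
    if (any(p12 > p12Max)) {
        warning("p12 values above ", format(p12Max),
                " clipped to keep heat finite")
        p12 <- pmin(p12, p12Max)
    }
    -log2(1 - p12)
}

#' Build the insulated diffusion operator for a network
#'
#' Works on the largest connected component; isolated nodes (and any
#' smaller components) are removed with a warning. \eqn{W} is the
#' column-normalized adjacency matrix and
#' \eqn{F = \beta (I - (1 - \beta) W)^{-1}}; every column of \eqn{F}
#' sums to one, so heat is conserved.
#'
#' @param net an [Interactome-class].
#' @param beta restart probability in (0, 1); 0.4 is the usual choice
#'   for protein-protein interaction networks.
#' @return a [DiffusionResult-class].
#' @export
diffusionOperator <- function(net, beta = 0.4) {
    stopifnot(beta > 0, beta < 1)
    g <- net@graph
    comp <- igraph::components(g)
    if (comp$no > 1) {
        keep <- which(comp$membership ==
            which.max(tabulate(comp$membership)))
        warning(igraph::vcount(g) - length(keep), " gene(s) outside the ",
            "largest connected component removed before diffusion")
        g <- igraph::induced_subgraph(g, keep)
    }
    A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
    deg <- colSums(A)
    W <- sweep(A, 2, deg, "/")
    n <- nrow(W)
    Fm <- beta * solve(diag(n) - (1 - beta) * W)
    new("DiffusionResult", genes = igraph::V(g)$name, W = W, F = Fm,
        beta = beta)
}

#' Exchanged heat matrix
#'
#' \eqn{E = F \,\mathrm{diag}(h)}: entry \eqn{E_{ij}} is the heat gene
#' j passes to gene i. Genes missing from the heat vector carry zero
#' heat. The total exchanged heat equals the total input heat over the
#' diffused component.
#'
#' @param diff a [DiffusionResult-class].
#' @param heat named numeric vector of non-negative gene heats.
#' @return dense matrix with rows/columns named by gene.
#' @export
exchangedHeat <- function(diff, heat) {
    stopifnot(all(heat >= 0))
    h <- setNames(numeric(length(diff@genes)), diff@genes)
    shared <- intersect(names(heat), diff@genes)
    h[shared] <- heat[shared]
    E <- diff@F * rep(h, each = length(h))
    dimnames(E) <- list(diff@genes, diff@genes)
    E
}

#' Diffuse heat over a network
#'
#' Convenience wrapper combining [diffusionOperator()] and
#' [exchangedHeat()].
#'
#' @inheritParams diffusionOperator
#' @inheritParams exchangedHeat
#' @return list with elements \code{W}, \code{F}, \code{E},
#'   \code{genes}, \code{beta}.
#' @export
diffuseHeat <- function(net, heat, beta = 0.4) {
    d <- diffusionOperator(net, beta)
    list(W = d@W, F = d@F, E = exchangedHeat(d, heat), genes = d@genes,
         beta = beta)
}

# fast count of strongly connected components of size >= kMin in the
# delta-thresholded exchanged-heat graph (integer-indexed, no names)
moduleCount <- function(E, delta, kMin) {
    n <- nrow(E)
    idx <- which(E >= delta)
    if (!length(idx)) return(0L)
    ri <- (idx - 1L) %% n + 1L
    ci <- (idx - 1L) %/% n + 1L
    keep <- ri != ci
    if (!any(keep)) return(0L)
    g <- igraph::make_graph(rbind(ci[keep], ri[keep]), n = n,
        directed = TRUE)
    sum(igraph::components(g, mode = "strong")$csize >= kMin)
}

#' Extract network modules from an exchanged-heat matrix
#'
#' Builds the directed graph with an edge j -> i whenever
#' \eqn{E_{ij} \ge \delta} (i received at least \eqn{\delta} heat from
#' j) and returns its strongly connected components of size at least
#' \code{kMin}. A threshold above \code{max(E)} yields an empty list.
#'
#' @param E exchanged-heat matrix with gene dimnames.
#' @param delta positive edge threshold.
#' @param kMin minimum module size (at least 2; default 3).
#' @return list of character vectors, one per module.
#' @export
extractModules <- function(E, delta, kMin = 3) {
    stopifnot(delta > 0, kMin >= 2)
    n <- nrow(E)
    idx <- which(E >= delta)
    if (!length(idx)) return(list())
    ri <- (idx - 1L) %% n + 1L
    ci <- (idx - 1L) %/% n + 1L
    keep <- ri != ci
    if (!any(keep)) return(list())
    gn <- rownames(E)
    gd <- igraph::graph_from_data_frame(
        data.frame(from = gn[ci[keep]], to = gn[ri[keep]]),
        directed = TRUE)
    comp <- igraph::components(gd, mode = "strong")
    big <- which(comp$csize >= kMin)
    lapply(big, function(k)
        sort(names(comp$membership)[comp$membership == k]))
}

#' Permutation selection of the module edge threshold
#'
#' Chooses the smallest threshold \eqn{\delta} such that, when the heat
#' vector is randomly permuted over the network genes, the expected
#' number of modules of size \eqn{\ge} \code{kMin} per permutation
#' stays below \code{level}. Candidate thresholds are taken from the
#' positive exchanged-heat values observed under permutation. With
#' degenerate heat (all equal, e.g. all zero) no finite threshold
#' separates signal from noise and \code{max(E) + 1} is returned as a
#' sentinel, with a warning.
#'
#' @param diff a [DiffusionResult-class].
#' @param heat named non-negative heat vector.
#' @param nPerm number of heat permutations (at least 10; default 30).
#' @param seed RNG seed; the selection is deterministic per seed.
#' @param kMin minimum module size.
#' @param level tolerated expected module count per permutation.
#' @return list with \code{delta}, the per-candidate expected module
#'   counts (\code{expected}), and the candidate grid.
#' @export
selectDelta <- function(diff, heat, nPerm = 30, seed = 1, kMin = 3,
                        level = 0.05) {
    stopifnot(nPerm >= 10)
    gn <- diff@genes
    h <- setNames(numeric(length(gn)), gn)
    shared <- intersect(names(heat), gn)
    h[shared] <- heat[shared]
    E <- exchangedHeat(diff, h)
    Emax <- max(E)
    if (length(unique(round(h, 12))) <= 1) {
        warning("degenerate heat vector (all equal); returning sentinel")
        return(list(delta = Emax + 1, expected = numeric(),
                    candidates = numeric()))
    }
    withSeed(seed, {
        # per permutation: the largest threshold at which any module of
        # size >= kMin still exists (binary search over the observed
        # exchanged-heat edge values among heated genes)
        permE <- lapply(seq_len(nPerm), function(i) {
            hp <- sample(h)
            ih <- which(hp > 0)
            Ep <- diff@F[ih, ih, drop = FALSE] *
                rep(hp[ih], each = length(ih))
            Ep
        })
        dstar <- vapply(permE, function(Ep) {
            n <- nrow(Ep)
            off <- Ep[(seq_along(Ep) - 1L) %% n != (seq_along(Ep) - 1L) %/% n]
            vals <- sort(unique(off[off > 0]))
            if (!length(vals)) return(0)
            lo <- 1L; hi <- length(vals)
            if (!moduleCount(Ep, vals[lo], kMin)) return(0)
            while (lo < hi) {   # invariant: module at vals[lo], none above hi
                mid <- (lo + hi + 1L) %/% 2L
                if (moduleCount(Ep, vals[mid], kMin))
                    lo <- mid else hi <- mid - 1L
            }
            vals[lo]
        }, numeric(1))
        # a permutation with survival point below a candidate threshold
        # contributes no modules there, so only candidates above the
        # ceiling(level * nPerm)-th largest survival point can satisfy
        # the level rule; the expected count is evaluated only on the
        # permutations still alive
        cand <- sort(unique(dstar)) * (1 + 1e-9)
        expected <- vapply(cand, function(dl) {
            alive <- which(dstar >= dl)
            if (length(alive) > ceiling(level * nPerm) + 1L)
                return(length(alive) / nPerm)  # lower bound, >= level
            sum(vapply(permE[alive], function(Ep)
                moduleCount(Ep, dl, kMin), 0L)) / nPerm
        }, numeric(1))
        ok <- which(expected < level)
        delta <- if (length(ok)) cand[min(ok)] else Emax + 1
        list(delta = delta, expected = expected, candidates = cand)
    })
}

#' Heat-diffusion proxy genes for one trait
#'
#' Runs the full propagation route: heats the network with
#' \code{-log2(1 - p12)} scores, selects the edge threshold by
#' permutation, extracts strongly connected modules and returns all
#' module genes minus the seeds. Only genes inside the diffused
#' component can ever be module members. Because strongly connected
#' components require reciprocated heat exchange, genes with zero heat
#' can never enter a module; sub-threshold colocalization records
#' (candidate eGenes that failed the HCGH filters) therefore supply the
#' low-grade heat that lets non-seed genes be pulled into modules.
#'
#' @param diff a [DiffusionResult-class] for the network.
#' @param heat named heat vector (see [colocHeat()]).
#' @param seeds seed genes to exclude from the proxies.
#' @param traitId trait label.
#' @param kMin minimum module size.
#' @param nPerm,seed,level passed to [selectDelta()].
#' @param delta fixed threshold overriding permutation selection.
#' @return list with the [ProxySet-class] (\code{proxies}), the module
#'   list and the threshold used.
#' @export
hotnetProxies <- function(diff, heat, seeds, traitId = "trait", kMin = 3,
                          nPerm = 30, seed = 1, level = 0.05,
                          delta = NULL) {
    gn <- diff@genes
    h <- setNames(numeric(length(gn)), gn)
    shared <- intersect(names(heat), gn)
    h[shared] <- heat[shared]
    if (is.null(delta))
        delta <- selectDelta(diff, heat, nPerm = nPerm, seed = seed,
            kMin = kMin, level = level)$delta
    # cold genes have no outgoing exchanged heat, so strongly connected
    # modules live entirely inside the heated subgraph
    ih <- which(h > 0)
    E <- diff@F[ih, ih, drop = FALSE] * rep(h[ih], each = length(ih))
    dimnames(E) <- list(gn[ih], gn[ih])
    mods <- extractModules(E, delta, kMin)
    ps <- ProxySet(traitId, "hotnet", seeds,
        unlist(mods, use.names = FALSE))
    list(proxies = ps, modules = mods, delta = delta)
}

#' Heat vector from colocalization records
#'
#' Every gene with at least one colocalization record receives heat
#' from its maximum p12 across records, on the \code{-log2(1 - p12)}
#' scale; genes without records stay cold.
#'
#' @param records colocalization data.frame for one trait.
#' @param p12Max clipping bound passed to [heatScore()].
#' @return named heat vector.
#' @export
colocHeat <- function(records, p12Max = 1 - 2^-20) {
    if (!nrow(records)) return(setNames(numeric(), character()))
    best <- tapply(records$p12, records$gene_id, max)
    setNames(heatScore(as.numeric(best), p12Max), names(best))
}
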