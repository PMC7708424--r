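## Definition of high-confidence genetic hits (HCGHs) from GWAS/eQTL
## colocalization records.

#' Define high-confidence genetic hits for one trait
#'
#' A colocalization record survives when all four filters hold
#' (thresholds inclusive): the eGene is protein coding, the GWAS
#' p-value is at most \code{gwasP}, the eQTL p-value is at most
#' \code{eqtlP}, and the colocalization posterior p12 is at least
#' \code{p12Min}. Filtering is applied per tissue record first; then,
#' per locus, the surviving eGene with the highest p12 across all
#' tissues is selected, giving 1 or 0 hits per disease-associated
#' locus. p12 ties are broken lexicographically by gene identifier. A
#' gene winning at several loci is kept once, with its maximum-p12
#' record.
#'
#' @param records data.frame with columns \code{trait_id},
#'   \code{locus_id}, \code{gene_id}, \code{tissue}, \code{gwas_p},
#'   \code{eqtl_p}, \code{p12}; all rows must share one trait.
#' @param universe a [GeneUniverse-class]; records naming unknown genes
#'   are rejected with a warning.
#' @param gwasP,eqtlP,p12Min filter thresholds (defaults 5e-8, 1e-4, 0.8).
#' @return an [HcghSet-class].
#' @examples
#' u <- GeneUniverse(c("A", "B"))
#' rec <- data.frame(trait_id = "t", locus_id = "L1", gene_id = c("A", "B"),
#'     tissue = "T1", gwas_p = 1e-9, eqtl_p = 1e-5, p12 = c(0.85, 0.95))
#' hcghGenes(defineHcghs(rec, u))   # "B": argmax p12 at the locus
#' @export
defineHcghs <- function(records, universe, gwasP = 5e-8, eqtlP = 1e-4,
                        p12Min = 0.8) {
    traitId <- if (nrow(records)) {
        tid <- unique(records$trait_id)
        if (length(tid) != 1)
            stop("records must share a single trait_id")
        tid
    } else ""
    known <- records$gene_id %in% genes(universe)
    if (!all(known)) {
        warning(sum(!known), " record(s) reference unknown genes; rejected")
        records <- records[known, , drop = FALSE]
    }
    coding <- setNames(universe@coding, universe@genes)
    pass <- coding[records$gene_id] &
        records$gwas_p <= gwasP &
        records$eqtl_p <= eqtlP &
        records$p12 >= p12Min
    rec <- records[pass, , drop = FALSE]
    empty <- data.frame(gene_id = character(), locus_id = character(),
        tissue = character(), gwas_p = numeric(), eqtl_p = numeric(),
        p12 = numeric(), stringsAsFactors = FALSE)
    if (!nrow(rec))
        return(new("HcghSet", traitId = traitId, hits = empty))
    # deterministic argmax: max p12, ties broken by gene_id then tissue
    rec <- rec[order(rec$locus_id, -rec$p12, rec$gene_id, rec$tissue), ,
               drop = FALSE]
    win <- rec[!duplicated(rec$locus_id), , drop = FALSE]
    # a gene winning several loci counts once, keeping its max-p12 record
    win <- win[order(-win$p12, win$gene_id, win$locus_id), , drop = FALSE]
    win <- win[!duplicated(win$gene_id), , drop = FALSE]
    hits <- win[order(win$locus_id),
        c("gene_id", "locus_id", "tissue", "gwas_p", "eqtl_p", "p12")]
    rownames(hits) <- NULL
    new("HcghSet", traitId = traitId, hits = hits)
}

#' Split colocalization records by trait and define hits for each
#'
#' @param coloc data.frame of colocalization records for many traits.
#' @param universe a [GeneUniverse-class].
#' @param blacklist optional character vector of trait identifiers to
#'   drop (e.g. surgical traits captured by fuzzy phenotype matching).
#' @param ... passed to [defineHcghs()].
#' @return named list of [HcghSet-class], one per retained trait.
#' @export
defineHcghsByTrait <- function(coloc, universe, blacklist = character(),
                               ...) {
    coloc <- coloc[!(coloc$trait_id %in% blacklist), , drop = FALSE]
    recs <- split(coloc, coloc$trait_id)
    lapply(recs, defineHcghs, universe = universe, ...)
}

#' Trait retention rule
#'
#' Keep only traits with at least one high-confidence hit and at least
#' one drug target with success/failure data (a Succeeded or Clinical
#' Failure outcome) for an indication matched to the trait.
#'
#' @param hcghSets named list of [HcghSet-class] keyed by trait.
#' @param outcomes data.frame of classified target-indication outcomes
#'   (see [classifyTargetIndication()]).
#' @param traitIndication data.frame mapping \code{trait_id} to
#'   \code{indication_id} (possibly many-to-many).
#' @return character vector of retained trait identifiers.
#' @export
retainTraits <- function(hcghSets, outcomes, traitIndication) {
    keep <- vapply(names(hcghSets), function(tr) {
        hs <- hcghSets[[tr]]
        if (!nrow(hs@hits)) return(FALSE)
        inds <- traitIndication$indication_id[
            traitIndication$trait_id == tr]
        any(outcomes$indication_id %in% inds &
            outcomes$outcome %in% c("Succeeded", "ClinicalFailure"))
    }, logical(1))
    names(hcghSets)[keep]
}
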