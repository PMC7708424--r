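## Classification of clinical trial records into target-indication
## outcomes, following the Selective / Non-Selective precedence rules.

.failStatuses <- c("Discontinued", "No Development Reported",
                   "Withdrawn", "Suspended")
.phaseLevels <- c("Preclinical", "PhaseI", "PhaseII", "PhaseIII",
                  "Launched")
.clinicalPhases <- c("PhaseI", "PhaseII", "PhaseIII")

#' Classify a raw asset-indication status
#'
#' \code{Launched} maps to Succeeded; \code{Discontinued},
#' \code{No Development Reported}, \code{Withdrawn} and
#' \code{Suspended} map to Failed; everything else (typically an
#' individual clinical or preclinical phase) falls through to
#' InProgress.
#'
#' @param statusText character vector of status strings.
#' @return character vector in \code{c("Succeeded", "Failed",
#'   "InProgress")}.
#' @examples
#' classifyAssetStatus(c("Launched", "Discontinued", "Phase II Clinical Trial"))
#' @export
classifyAssetStatus <- function(statusText) {
    stopifnot(all(nzchar(statusText)))
    out <- rep("InProgress", length(statusText))
    out[statusText == "Launched"] <- "Succeeded"
    out[statusText %in% .failStatuses] <- "Failed"
    out
}

#' Default list of indication labels dropped on load
#'
#' Unspecified or diagnostic indications carry no therapeutic outcome
#' information and are excluded before classification.
#' @export
defaultIndicationBlacklist <- function() {
    c("Ideopathic disease, unspecified", "Not applicable",
      "Undisclosed", "Unspecified")
}

#' Classify target-indication outcomes from asset records
#'
#' Assets are first classified by status; failed assets are split into
#' clinical failures (furthest phase reached Phase I-III) and
#' preclinical failures. An asset is Selective when it interacts with
#' exactly one target gene. Each (gene, indication) pair then receives
#' exactly one outcome by precedence: (1) any Selective successful
#' asset makes it Succeeded; (2) otherwise any Selective clinical
#' failure makes it ClinicalFailure; (3, 4) the same two steps are
#' repeated for Non-Selective assets; (5, 6) then for preclinical
#' failures (Selective before Non-Selective); (7) anything left is
#' InProgress. The furthest clinical phase achieved by any past or
#' current asset is recorded alongside.
#'
#' The placement of Non-Selective successes after Selective clinical
#' failures (step order above) follows the sequential reading of the
#' classification procedure; \code{ruleOrder} makes the precedence
#' explicit and overridable.
#'
#' @param assets data.frame with columns \code{asset_id},
#'   \code{gene_id}, \code{indication_id}, \code{status_text},
#'   \code{phase_reached}; one row per asset-target-indication triple.
#' @param indicationBlacklist indication labels dropped on load.
#' @param ruleOrder character vector permuting the six decisive rules.
#' @return data.frame with one row per (gene, indication):
#'   \code{gene_id}, \code{indication_id}, \code{outcome},
#'   \code{furthest_phase}.
#' @export
classifyTargetIndication <- function(assets,
        indicationBlacklist = defaultIndicationBlacklist(),
        ruleOrder = c("sel_succ", "sel_clin", "nonsel_succ",
                      "nonsel_clin", "sel_preclin", "nonsel_preclin")) {
    stopifnot(all(c("asset_id", "gene_id", "indication_id",
        "status_text", "phase_reached") %in% names(assets)))
    if (any(is.na(assets$gene_id) | !nzchar(assets$gene_id)))
        stop("asset with zero targets rejected on load")
    assets <- assets[!(assets$indication_id %in% indicationBlacklist), ,
                     drop = FALSE]
    if (!nrow(assets))
        return(data.frame(gene_id = character(),
            indication_id = character(), outcome = character(),
            furthest_phase = character(), stringsAsFactors = FALSE))

    nTargets <- tapply(assets$gene_id, assets$asset_id,
        function(g) length(unique(g)))
    selective <- assets$asset_id %in%
        names(nTargets)[nTargets == 1]
    status <- classifyAssetStatus(assets$status_text)
    clinical <- status == "Failed" &
        assets$phase_reached %in% .clinicalPhases
    preclin <- status == "Failed" & !clinical

    evt <- rep(NA_character_, nrow(assets))
    evt[status == "Succeeded" & selective] <- "sel_succ"
    evt[status == "Succeeded" & !selective] <- "nonsel_succ"
    evt[clinical & selective] <- "sel_clin"
    evt[clinical & !selective] <- "nonsel_clin"
    evt[preclin & selective] <- "sel_preclin"
    evt[preclin & !selective] <- "nonsel_preclin"

    rank <- setNames(seq_along(ruleOrder), ruleOrder)
    evtRank <- ifelse(is.na(evt), length(ruleOrder) + 1L, rank[evt])
    outcomeOf <- c(sel_succ = "Succeeded", nonsel_succ = "Succeeded",
        sel_clin = "ClinicalFailure", nonsel_clin = "ClinicalFailure",
        sel_preclin = "PreclinicalFailure",
        nonsel_preclin = "PreclinicalFailure")

    key <- paste(assets$gene_id, assets$indication_id, sep = "\r")
    phaseIdx <- match(assets$phase_reached, .phaseLevels)
    phaseIdx[is.na(phaseIdx)] <- 1L  # unknown phases count as preclinical

    best <- tapply(evtRank, key, min)
    furthest <- tapply(phaseIdx, key, max)
    keys <- names(best)
    parts <- strsplit(keys, "\r", fixed = TRUE)
    out <- data.frame(
        gene_id = vapply(parts, `[`, "", 1L),
        indication_id = vapply(parts, `[`, "", 2L),
        outcome = ifelse(best <= length(ruleOrder),
            outcomeOf[ruleOrder[best]], "InProgress"),
        furthest_phase = .phaseLevels[furthest],
        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out[order(out$gene_id, out$indication_id), , drop = FALSE]
}

#' Positive and negative target-indication sets
#'
#' Succeeded pairs form the positive set, Clinical Failure pairs the
#' negative set; preclinical failures and in-progress pairs belong to
#' neither.
#'
#' @param outcomes data.frame from [classifyTargetIndication()].
#' @return list with data.frames \code{positive} and \code{negative}.
#' @export
outcomeSets <- function(outcomes) {
    list(positive = outcomes[outcomes$outcome == "Succeeded", ,
             drop = FALSE],
         negative = outcomes[outcomes$outcome == "ClinicalFailure", ,
             drop = FALSE])
}
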