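## Plain-text serialization of worlds and knowledge bases. All tables
## are tab-separated with header lines; gene sets use the standard GMT
## format (set id, description, members).

writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

readTsv <- function(path, required = character()) {
    if (!file.exists(path))
        stop("missing file: ", path, call. = FALSE)
    df <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
        error = function(e) stop("parse error in ", path, ": ",
            conditionMessage(e), call. = FALSE))
    miss <- setdiff(required, names(df))
    if (length(miss))
        stop("parse error in ", path, ": missing column(s) ",
             paste(miss, collapse = ", "), call. = FALSE)
    df
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated set id, description,
#' then members. Duplicate members within a line are deduplicated with
#' a warning naming the file and line.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
    if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    out <- list()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3)
            stop("parse error in ", path, " line ", i,
                 ": expected at least 3 fields", call. = FALSE)
        members <- f[-(1:2)]
        if (anyDuplicated(members)) {
            warning("duplicate gene(s) in ", basename(path), " line ", i,
                    " (set ", f[1], "); deduplicated")
            members <- unique(members)
        }
        out[[f[1]]] <- members
    }
    out
}

#' Write a GMT gene-set file
#' @param sets named list of character vectors.
#' @param path file path.
#' @export
writeGmt <- function(sets, path) {
    lines <- vapply(names(sets), function(nm)
        paste(c(nm, nm, sets[[nm]]), collapse = "\t"), "")
    writeLines(lines, path)
}

#' Write a synthetic world to a directory of plain-text files
#'
#' Emits \code{universe.tsv}, \code{network.tsv}, \code{complexes.gmt},
#' \code{pathways.gmt}, \code{pathway_edges.tsv}, \code{lr_pairs.tsv},
#' \code{coloc.tsv}, \code{assets.tsv}, \code{trait_indication.tsv},
#' \code{truth_modules.tsv} (the synthetic ground-truth labels),
#' \code{gene_windows.tsv}, \code{world_config.yaml} and per-gene
#' \code{variants/<gene>.tsv} / \code{ld/<gene>.tsv} files.
#'
#' @param world a [SyntheticWorld-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeWorld <- function(world, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    u <- world@kb@universe
    writeTsv(data.frame(gene_id = u@genes,
        is_coding = as.integer(u@coding),
        is_hla = as.integer(u@hla)), file.path(dir, "universe.tsv"))
    el <- igraph::as_edgelist(world@kb@interactome@graph)
    w <- igraph::E(world@kb@interactome@graph)$weight
    if (is.null(w)) w <- rep(1, nrow(el))
    writeTsv(data.frame(gene_a = el[, 1], gene_b = el[, 2], weight = w),
        file.path(dir, "network.tsv"))
    writeGmt(world@kb@complexes@sets, file.path(dir, "complexes.gmt"))
    writeGmt(world@kb@pathways@sets, file.path(dir, "pathways.gmt"))
    writeTsv(setNames(world@kb@pathways@edges,
        c("pathway_id", "source", "target")),
        file.path(dir, "pathway_edges.tsv"))
    writeTsv(setNames(world@kb@lrPairs@pairs,
        c("ligand_gene", "receptor_gene")),
        file.path(dir, "lr_pairs.tsv"))
    writeTsv(world@coloc, file.path(dir, "coloc.tsv"))
    writeTsv(world@assets, file.path(dir, "assets.tsv"))
    writeTsv(world@traitIndication, file.path(dir, "trait_indication.tsv"))
    writeTsv(world@truth, file.path(dir, "truth_modules.tsv"))
    writeTsv(world@windows, file.path(dir, "gene_windows.tsv"))
    yaml::write_yaml(unclass(world@config),
        file.path(dir, "world_config.yaml"))
    dir.create(file.path(dir, "variants"), showWarnings = FALSE)
    dir.create(file.path(dir, "ld"), showWarnings = FALSE)
    for (g in names(world@variants)) {
        v <- world@variants[[g]]
        writeTsv(data.frame(variant_id = seq_along(v$z),
            z = format(v$z, digits = 17)),
            file.path(dir, "variants", paste0(g, ".tsv")))
        write.table(format(v$R, digits = 17),
            file.path(dir, "ld", paste0(g, ".tsv")), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
    invisible(dir)
}

#' Read a synthetic world back from a directory
#'
#' Inverse of [writeWorld()]; a round trip reproduces the world up to
#' numeric formatting. Missing files raise an error listing them.
#'
#' @param dir directory written by [writeWorld()].
#' @return a [SyntheticWorld-class].
#' @export
readWorld <- function(dir) {
    need <- c("universe.tsv", "network.tsv", "complexes.gmt",
        "pathways.gmt", "pathway_edges.tsv", "lr_pairs.tsv",
        "coloc.tsv", "assets.tsv", "trait_indication.tsv",
        "truth_modules.tsv", "gene_windows.tsv", "world_config.yaml")
    miss <- need[!file.exists(file.path(dir, need))]
    if (length(miss))
        stop("missing file(s) in ", dir, ": ",
             paste(miss, collapse = ", "), call. = FALSE)
    kb <- readKnowledgeBase(dir)
    coloc <- readTsv(file.path(dir, "coloc.tsv"), c("trait_id",
        "locus_id", "gene_id", "tissue", "gwas_p", "eqtl_p", "p12"))
    assets <- readTsv(file.path(dir, "assets.tsv"), c("asset_id",
        "gene_id", "indication_id", "status_text", "phase_reached"))
    ti <- readTsv(file.path(dir, "trait_indication.tsv"),
        c("trait_id", "indication_id"))
    truth <- readTsv(file.path(dir, "truth_modules.tsv"),
        c("trait_id", "gene_id", "is_causal"))
    truth$is_causal <- as.logical(truth$is_causal)
    windows <- readTsv(file.path(dir, "gene_windows.tsv"),
        c("gene_id", "start", "end"))
    cfgList <- yaml::read_yaml(file.path(dir, "world_config.yaml"))
    cfg <- do.call(SimulationConfig, cfgList)
    variants <- list()
    vdir <- file.path(dir, "variants")
    if (dir.exists(vdir)) {
        for (f in list.files(vdir, pattern = "\\.tsv$")) {
            g <- sub("\\.tsv$", "", f)
            z <- as.numeric(readTsv(file.path(vdir, f), "z")$z)
            R <- as.matrix(read.delim(file.path(dir, "ld", f),
                header = FALSE))
            dimnames(R) <- NULL
            variants[[g]] <- list(z = z, R = R)
        }
        variants <- variants[order(names(variants))]
        variants <- variants[names(variants)]
    }
    new("SyntheticWorld", kb = kb, coloc = coloc, truth = truth,
        assets = assets, traitIndication = ti, variants = variants,
        windows = windows, config = cfg)
}

#' Read a knowledge base from generic tabular files
#'
#' Accepts the file layout of [writeWorld()]: a gene universe, an
#' undirected edge list, complexes and pathways in GMT, directed
#' pathway edges and ligand-receptor pairs.
#'
#' @param dir directory containing the files.
#' @param minWeight optional confidence threshold on network edges.
#' @return a [KnowledgeBase-class].
#' @export
readKnowledgeBase <- function(dir, minWeight = NULL) {
    udf <- readTsv(file.path(dir, "universe.tsv"),
        c("gene_id", "is_coding", "is_hla"))
    uni <- GeneUniverse(udf$gene_id, as.logical(udf$is_coding),
        as.logical(udf$is_hla))
    ndf <- readTsv(file.path(dir, "network.tsv"), c("gene_a", "gene_b"))
    net <- Interactome(ndf, name = "network", minWeight = minWeight)
    cx <- ComplexSet(readGmt(file.path(dir, "complexes.gmt")))
    pwSets <- readGmt(file.path(dir, "pathways.gmt"))
    pe <- readTsv(file.path(dir, "pathway_edges.tsv"),
        c("pathway_id", "source", "target"))
    pw <- PathwaySet(pwSets, data.frame(pathway = pe$pathway_id,
        source = pe$source, target = pe$target,
        stringsAsFactors = FALSE))
    lrdf <- readTsv(file.path(dir, "lr_pairs.tsv"),
        c("ligand_gene", "receptor_gene"))
    lr <- LigandReceptorMap(data.frame(ligand = lrdf$ligand_gene,
        receptor = lrdf$receptor_gene))
    KnowledgeBase(uni, net, cx, lr, pw)
}

#' Write proxy sets as a long TSV
#' @param proxySets list (possibly nested by method) of
#'   [ProxySet-class].
#' @param path output file.
#' @export
writeProxySets <- function(proxySets, path) {
    flat <- unlist(proxySets)
    rows <- lapply(flat, function(p) {
        if (!length(p@proxies)) return(NULL)
        data.frame(trait_id = p@traitId, method = p@method,
            gene_id = p@proxies, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    if (is.null(df))
        df <- data.frame(trait_id = character(), method = character(),
            gene_id = character())
    writeTsv(df, path)
}
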