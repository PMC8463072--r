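# primary gene symbol for set matching / backgrounds: first token of the
# MaxQuant gene-name field, falling back to the group id when empty
primaryGene <- function(geneName, groupId) {
    g <- vapply(strsplit(geneName, ";", fixed = TRUE),
                function(x) if (length(x)) trimws(x[1]) else "", character(1))
    ifelse(nzchar(g), g, groupId)
}

writeTsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Run the full copy-number analysis pipeline
#'
#' Executes the stages in order: read the protein-group table and channel
#' design; apply the row filters (contaminant / reverse / only-by-site /
#' low-peptide); flag histones; allocate MS1 intensities across channels
#' (dropping unallocatable records with a logged count); estimate copies
#' per cell with the histone ruler; compute protein content; run replicate
#' QC and drop flagged replicates (content is then recomputed); run the
#' moderated-t differential analysis, q-values, star classes and candidate
#' selection per contrast; optional gene-set overrepresentation per
#' contrast; and the landscape summaries (population medians, PCA,
#' correlations). Every intermediate table is written to \code{outDir}
#' together with a run-metadata JSON capturing configuration, input/config
#' hashes and per-stage row counts.
#'
#' @param proteinGroups path to the protein-group TSV.
#' @param channelDesign path to the channel-design TSV.
#' @param outDir output directory (created if needed).
#' @param contrasts list of length-2 character vectors (popA, popB);
#'   default: every other population against the first population in the
#'   design.
#' @param gmt optional path to a GMT file used for overrepresentation per
#'   contrast.
#' @param categoryGmt optional path to a GMT of disjoint proteome categories
#'   (histones, ribosomal proteins, ...); when given, category mass
#'   fractions and gene-set copy sums (first contrast) are also written.
#' @param dnaMassPg,qcThreshold,pseudocount,minPeptides,fdrCut,topFraction
#'   stage parameters (see the stage functions).
#' @param histoneGenes histone symbol list for \code{\link{identifyHistones}}.
#' @return (invisibly) list with \code{cne} (post-QC
#'   \linkS4class{CopyNumberExperiment}), \code{content}, \code{qc},
#'   \code{differential} (per contrast), \code{enrichment}, \code{pca},
#'   \code{correlation}, \code{metadata} and \code{paths}.
#' @export
runPipeline <- function(proteinGroups, channelDesign, outDir,
                        contrasts = NULL, gmt = NULL, categoryGmt = NULL,
                        dnaMassPg = DEFAULT_DNA_MASS_PG,
                        qcThreshold = 0.15, pseudocount = 1,
                        minPeptides = 2L, fdrCut = 0.05,
                        topFraction = 0.5,
                        histoneGenes = defaultHistoneGenes()) {
    if (!file.exists(proteinGroups)) stop("input not found: ", proteinGroups)
    if (!file.exists(channelDesign)) stop("input not found: ", channelDesign)
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    paths <- character(0)
    meta <- list(
        config = list(proteinGroups = proteinGroups,
                      channelDesign = channelDesign,
                      dnaMassPg = dnaMassPg, qcThreshold = qcThreshold,
                      pseudocount = pseudocount, minPeptides = minPeptides,
                      fdrCut = fdrCut, topFraction = topFraction,
                      starThresholds = list(p2 = 0.001, p3 = 0.0001,
                                            sd2 = 1, sd3 = 1.5),
                      candidateThresholds = list(p = 0.001, sd = 1.5)),
        input_hash = unname(tools::md5sum(proteinGroups)),
        counts = list(), warnings = list())

    design <- readChannelDesign(channelDesign)
    pops <- unique(design@channels$population)
    if (is.null(contrasts) && length(pops) > 1)
        contrasts <- lapply(pops[-1], function(p) c(p, pops[1]))
    for (ct in contrasts)
        if (!all(ct %in% pops))
            stop("contrast population not in design: ",
                 paste(setdiff(ct, pops), collapse = ", "))

    message("stage read: ", proteinGroups)
    pg <- readProteinGroups(proteinGroups, design)
    meta$counts$parsed <- nrow(pg)

    message("stage filter")
    fl <- filterProteinGroups(pg, minPeptides = minPeptides)
    pg <- fl$retained
    meta$counts$retained_after_filter <- nrow(pg)
    paths["filter_report"] <- writeTsv(fl$report,
                                       file.path(outDir, "filter_report.tsv"))

    pg <- identifyHistones(pg, histoneGenes)
    meta$counts$histones <- sum(pg$is_histone)

    message("stage allocate")
    allocated <- allocateMS1(pg$ms1_intensity, pg$reporter_intensities)
    unalloc <- attr(allocated, "unallocatable")
    if (any(unalloc)) {
        message(sum(unalloc), " unallocatable record(s) dropped ",
                "(MS1 > 0 with all-zero reporters)")
        allocated <- allocated[!unalloc, , drop = FALSE]
        pg <- pg[!unalloc, , drop = FALSE]
    }
    meta$counts$unallocatable <- sum(unalloc)

    message("stage ruler")
    cne <- estimateCopyNumbers(allocated, pg, design, dnaMassPg)

    message("stage content + replicate QC")
    content <- proteinContent(cne)
    qc <- qcReplicates(stats::setNames(content$samples$content_pg,
                                       content$samples$sample),
                       content$samples$population, qcThreshold)
    paths["qc_report"] <- writeTsv(qc, file.path(outDir, "qc_report.tsv"))
    meta$counts$qc_flagged <- sum(qc$flagged)
    if (any(qc$flagged)) {
        message("dropping flagged replicate(s): ",
                paste(qc$sample[qc$flagged], collapse = ", "))
        cne <- cne[, !qc$flagged]
        content <- proteinContent(cne)
    }
    paths["content_samples"] <- writeTsv(
        content$samples, file.path(outDir, "content_samples.tsv"))
    paths["content_populations"] <- writeTsv(
        content$populations, file.path(outDir, "content_populations.tsv"))
    cn <- data.frame(as.data.frame(rowData(cne)), copyNumbers(cne),
                     check.names = FALSE)
    paths["copy_numbers"] <- writeTsv(cn, file.path(outDir,
                                                    "copy_numbers.tsv"))

    collection <- if (!is.null(gmt)) readGmt(gmt) else NULL
    genes <- primaryGene(rowData(cne)$gene_name, rowData(cne)$group_id)
    differential <- list(); enrichment <- list()
    for (ct in contrasts) {
        tag <- paste0(ct[1], "_vs_", ct[2])
        message("stage differential: ", tag)
        de <- differentialExpression(cne, ct[1], ct[2],
                                     pseudocount = pseudocount)
        differential[[tag]] <- de
        det <- data.frame(group_id = rownames(de), as.data.frame(de),
                          check.names = FALSE)
        paths[paste0("diffexp_", tag)] <- writeTsv(
            det, file.path(outDir, paste0("diffexp_", tag, ".tsv")))
        meta$counts[[paste0("tested_", tag)]] <- nrow(de)

        if (!is.null(collection)) {
            shared <- de$exclusive == "none"
            cand <- selectEnrichmentCandidates(rownames(de)[shared],
                                               de$log2fc[shared],
                                               de$p_value[shared],
                                               metadata(de)$fc_dist)
            # union exclusives with the significant sets, then map to genes
            upIds <- union(cand$up, rownames(de)[de$exclusive == "a_only"])
            dnIds <- union(cand$down, rownames(de)[de$exclusive == "b_only"])
            inPops <- colData(cne)$population %in% ct
            idented <- rowSums(
                copyNumbers(cne)[, inPops, drop = FALSE] > 0) > 0
            bg <- unique(genes[idented])
            g <- stats::setNames(genes, rowData(cne)$group_id)
            oraSide <- function(idsV, label) {
                if (!length(idsV)) return(NULL)
                r <- overrepresentation(unique(g[idsV]), bg, collection)
                if (!nrow(r)) return(NULL)
                cbind(direction = label, r)
            }
            ora <- rbind(oraSide(upIds, "up"), oraSide(dnIds, "down"))
            enrichment[[tag]] <- ora
            if (!is.null(ora) && nrow(ora))
                paths[paste0("ora_", tag)] <- writeTsv(
                    ora, file.path(outDir, paste0("ora_", tag, ".tsv")))
        }
    }

    message("stage landscape")
    med <- aggregatePopulation(cne, "median")
    paths["population_medians"] <- writeTsv(
        data.frame(group_id = rownames(med), med, check.names = FALSE),
        file.path(outDir, "population_medians.tsv"))
    pca <- pcaSamples(cne)
    paths["pca_scores"] <- writeTsv(
        data.frame(sample = rownames(pca$scores), pca$scores,
                   check.names = FALSE),
        file.path(outDir, "pca_scores.tsv"))
    paths["pca_variance"] <- writeTsv(
        data.frame(component = names(pca$varianceFraction),
                   variance_fraction = as.numeric(pca$varianceFraction)),
        file.path(outDir, "pca_variance.tsv"))
    if (!is.null(categoryGmt)) {
        cats <- readGmt(categoryGmt)
        frac <- categoryMassFractions(cne, cats, topFraction = topFraction)
        paths["category_fractions"] <- writeTsv(
            frac, file.path(outDir, "category_fractions.tsv"))
        if (length(contrasts)) {
            gs <- genesetSums(cne, cats, contrasts[[1]][1], contrasts[[1]][2])
            paths["geneset_sums"] <- writeTsv(
                gs$sums, file.path(outDir, "geneset_sums.tsv"))
            paths["geneset_tests"] <- writeTsv(
                gs$tests, file.path(outDir, "geneset_tests.tsv"))
        }
    }
    corr <- populationCorrelation(med)
    paths["correlation"] <- writeTsv(
        data.frame(population = rownames(corr), corr, check.names = FALSE),
        file.path(outDir, "correlation.tsv"))

    meta$counts$final_proteins <- nrow(cne)
    meta$counts$final_samples <- ncol(cne)
    metaPath <- file.path(outDir, "run_metadata.json")
    jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    paths["metadata"] <- metaPath

    invisible(list(cne = cne, content = content, qc = qc,
                   differential = differential, enrichment = enrichment,
                   pca = pca, correlation = corr, metadata = meta,
                   paths = paths))
}
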