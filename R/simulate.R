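#' Simulate a TMT protein-group table with ground truth
#'
#' Generates a MaxQuant-style protein-group table with the statistical
#' structure the pipeline assumes, plus the matching ground truth. The model
#' mirrors the two-level quantification of an SPS-MS3 TMT experiment:
#'
#' \itemize{
#'   \item per-protein baseline copies per cell are log-normal; histone
#'     anchors are drawn from the high-abundance tail (baseline mean + 1.5
#'     sd on the log10 scale, with tighter spread) so they dominate as in
#'     real cells;
#'   \item planted category effects multiply true copies by
#'     \code{2^log2fc} in the affected populations; a fraction of proteins
#'     is absent (all-zero reporters) in one random population;
#'   \item true copies are rescaled so total histone protein mass per cell
#'     equals \code{dnaMassPg} exactly, making the ruler inversion exact;
#'   \item noise-free channel intensities are \code{copies x MW x c_s} with
#'     a per-sample scale c_s; the MS1 intensity is their (noise-free) sum,
#'     and observed reporter intensities get independent multiplicative
#'     log-normal noise with CV \code{reporterCV}. Noise thus enters only
#'     the MS3 allocation step, not MS1 quantification;
#'   \item decoy rows (contaminant, reverse) and low-peptide rows exercise
#'     the row filters; a planted content-outlier replicate (if configured)
#'     exercises replicate QC. The outlier's non-histone copies are scaled
#'     so that the sample's \emph{total} protein content changes by exactly
#'     the requested multiplier (histone content is anchored by the ruler
#'     and cannot move).
#' }
#'
#' Generation is a pure function of the config: the same seed yields
#' identical output.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return list with \code{table} (protein-group \code{DataFrame} in the
#'   schema of \code{\link{readProteinGroups}}), \code{truth}
#'   (\linkS4class{SyntheticTruth}) and \code{design}
#'   (\linkS4class{ChannelDesign}).
#' @export
simulateProteinGroups <- function(config) {
    validObject(config)
    set.seed(config@seed)

    pops <- names(config@populations)
    reps <- config@populations
    design <- ChannelDesign(
        channel_label = sprintf("ch%02d", seq_len(sum(reps))),
        population = rep(pops, reps),
        replicate = unlist(lapply(reps, seq_len), use.names = FALSE))
    samples <- paste(design@channels$population, design@channels$replicate,
                     sep = "_")
    nS <- length(samples)
    popOf <- design@channels$population

    nP <- as.integer(config@nProteins)
    nH <- as.integer(config@nHistones)
    ids <- sprintf("PG%05d", seq_len(nP))
    histIdx <- seq_len(nH)
    histGenes <- defaultHistoneGenes()
    if (nH > length(histGenes))
        stop("nHistones exceeds the shipped histone symbol list (",
             length(histGenes), ")")
    genes <- c(histGenes[seq_len(nH)],
               sprintf("Gene%05d", seq_len(nP - nH)))
    mw <- c(stats::rlnorm(nH, log(1.5e4), 0.2),
            stats::rlnorm(nP - nH, log(4e4), 0.5))

    m <- config@baselineLog10Mean; s <- config@baselineLog10Sd
    baseline <- c(10^stats::rnorm(nH, m + 1.5 * s, 0.3),
                  10^stats::rnorm(nP - nH, m, s))

    # planted category effects
    planted <- matrix(0, nP, length(pops), dimnames = list(ids, pops))
    membership <- list()
    taken <- rep(FALSE, nP); taken[histIdx] <- TRUE
    for (eff in config@plantedEffects) {
        if (is.character(eff$members)) {
            rows <- which(matchGeneRows(genes, eff$members) & !taken)
        } else {
            nMem <- if (eff$members <= 1) round(eff$members * nP) else
                as.integer(eff$members)
            eligible <- which(!taken)
            if (nMem > length(eligible))
                stop("planted effect ", eff$name,
                     ": not enough unassigned proteins")
            rows <- sample(eligible, nMem)
        }
        if (length(rows) == 0)
            stop("planted effect ", eff$name, " matched no proteins")
        taken[rows] <- TRUE
        planted[rows, eff$populations] <-
            planted[rows, eff$populations] + eff$log2fc
        membership[[eff$name]] <- ids[rows]
    }

    # population-specific absence
    nAbs <- round(config@absenceFraction * nP)
    eligible <- which(!taken)
    nAbs <- min(nAbs, length(eligible))
    absRows <- if (nAbs > 0) sample(eligible, nAbs) else integer(0)
    absPop <- if (nAbs > 0) sample(pops, nAbs, replace = TRUE) else character(0)

    # true copies per cell
    copies <- baseline * 2^planted[, match(popOf, pops), drop = FALSE]
    dimnames(copies) <- list(ids, samples)
    for (i in seq_along(absRows))
        copies[absRows[i], popOf == absPop[i]] <- 0

    # planted content-outlier replicate: solve the non-histone multiplier
    # that shifts this sample's total content by the requested factor
    outlierSamples <- character(0)
    if (!is.null(config@plantedOutlier)) {
        po <- config@plantedOutlier
        lab <- paste(po$population, po$replicate, sep = "_")
        j <- match(lab, samples)
        if (is.na(j)) stop("plantedOutlier sample ", lab, " not in design")
        massH <- sum(copies[histIdx, j] * mw[histIdx])
        massR <- sum(copies[-histIdx, j] * mw[-histIdx])
        mult <- (po$contentMultiplier * (massH + massR) - massH) / massR
        if (mult <= 0)
            stop("plantedOutlier contentMultiplier too extreme for this fixture")
        copies[-histIdx, j] <- copies[-histIdx, j] * mult
        outlierSamples <- lab
    }

    # anchor: rescale so histone protein mass equals dnaMassPg per cell
    # (histone rows are identical across samples, so one global factor)
    histMassPg <- sum(copies[histIdx, 1] * mw[histIdx]) / AVOGADRO * 1e12
    copies <- copies * (config@dnaMassPg / histMassPg)

    # intensities: per-sample scale, noise-free MS1 sum, noisy reporters
    cS <- 1e-5 * exp(stats::rnorm(nS, 0, 0.1))
    iTrue <- sweep(copies * mw, 2, cS, `*`)
    ms1 <- unname(rowSums(iTrue))
    if (config@reporterCV > 0) {
        sdlog <- sqrt(log1p(config@reporterCV^2))
        noise <- matrix(stats::rlnorm(nP * nS, -sdlog^2 / 2, sdlog), nP, nS)
        reporters <- iTrue * noise
    } else {
        reporters <- iTrue
    }
    colnames(reporters) <- design@channels$channel_label

    realTab <- DataFrame(
        group_id = ids,
        protein_ids = paste0("P_", ids),
        gene_name = genes,
        mol_weight_da = mw,
        ms1_intensity = ms1,
        razor_unique_peptides = 2L + stats::rpois(nP, 10),
        is_contaminant = FALSE, is_reverse = FALSE, only_by_site = FALSE,
        is_histone = FALSE)
    realTab$reporter_intensities <- reporters

    decoyRows <- function(n, prefix, gene, contaminant, reverse, peptides) {
        if (n == 0) return(NULL)
        dmw <- stats::rlnorm(n, log(5e4), 0.4)
        dms1 <- stats::rlnorm(n, log(stats::median(ms1)), 1)
        frac <- matrix(stats::rexp(n * nS), n, nS)
        frac <- frac / rowSums(frac)
        drep <- dms1 * frac
        colnames(drep) <- design@channels$channel_label
        d <- DataFrame(
            group_id = sprintf("%s%03d", prefix, seq_len(n)),
            protein_ids = sprintf("%s%03d", prefix, seq_len(n)),
            gene_name = sprintf("%s%03d", gene, seq_len(n)),
            mol_weight_da = dmw,
            ms1_intensity = dms1,
            razor_unique_peptides = peptides,
            is_contaminant = contaminant, is_reverse = reverse,
            only_by_site = FALSE, is_histone = FALSE)
        d$reporter_intensities <- drep
        d
    }
    parts <- list(
        realTab,
        decoyRows(as.integer(config@nContaminants), "CON", "ConGene",
                  TRUE, FALSE,
                  2L + stats::rpois(as.integer(config@nContaminants), 8)),
        decoyRows(as.integer(config@nReverse), "REV", "RevGene",
                  FALSE, TRUE,
                  2L + stats::rpois(as.integer(config@nReverse), 8)),
        decoyRows(as.integer(config@nLowPeptide), "LOW", "LowGene",
                  FALSE, FALSE,
                  sample(0:1, as.integer(config@nLowPeptide), replace = TRUE)))
    tab <- do.call(rbind, Filter(Negate(is.null), parts))
    rownames(tab) <- tab$group_id

    truth <- new("SyntheticTruth",
                 trueCopies = copies, plantedLog2FC = planted,
                 histoneIds = ids[histIdx],
                 outlierSamples = outlierSamples,
                 categoryMembership = membership)
    list(table = tab, truth = truth, design = design)
}

#' Write a synthetic fixture to disk
#'
#' Serialises a simulated protein-group table as a MaxQuant-dialect TSV
#' (\code{proteinGroups.txt}), the channel design, and the ground-truth
#' tables. The protein-group file round-trips losslessly through
#' \code{\link{readProteinGroups}} for every field the reader exposes.
#'
#' @param sim output of \code{\link{simulateProteinGroups}}.
#' @param dir output directory (created if needed).
#' @return named character vector of written file paths.
#' @export
writeFixture <- function(sim, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    tab <- sim$table; design <- sim$design; truth <- sim$truth
    nch <- nrow(design@channels)
    flag <- function(x) ifelse(x, "+", "")
    rep_mat <- tab$reporter_intensities
    out <- data.frame(
        `Protein IDs` = tab$protein_ids,
        `Majority protein IDs` = tab$protein_ids,
        `Gene names` = tab$gene_name,
        `Mol. weight [kDa]` = tab$mol_weight_da / 1000,
        `Razor + unique peptides` = tab$razor_unique_peptides,
        `Unique peptides` = tab$razor_unique_peptides,
        Intensity = tab$ms1_intensity,
        check.names = FALSE, stringsAsFactors = FALSE)
    for (k in seq_len(nch))
        out[[paste("Reporter intensity corrected", k)]] <- rep_mat[, k]
    for (k in seq_len(nch))
        out[[paste("Reporter intensity", k)]] <- rep_mat[, k]
    out[["Only identified by site"]] <- flag(tab$only_by_site)
    out[["Reverse"]] <- flag(tab$is_reverse)
    out[["Potential contaminant"]] <- flag(tab$is_contaminant)
    out[["id"]] <- tab$group_id

    paths <- c(
        protein_groups = file.path(dir, "proteinGroups.txt"),
        channel_design = file.path(dir, "channel_design.txt"),
        true_copies = file.path(dir, "true_copies.tsv"),
        planted_log2fc = file.path(dir, "planted_log2fc.tsv"),
        truth_meta = file.path(dir, "truth_meta.json"))
    utils::write.table(out, paths["protein_groups"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeChannelDesign(design, paths["channel_design"])
    utils::write.table(data.frame(group_id = rownames(truth@trueCopies),
                                  truth@trueCopies, check.names = FALSE),
                       paths["true_copies"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(group_id = rownames(truth@plantedLog2FC),
                                  truth@plantedLog2FC, check.names = FALSE),
                       paths["planted_log2fc"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(
        list(histone_ids = truth@histoneIds,
             outlier_samples = truth@outlierSamples,
             category_membership = truth@categoryMembership),
        paths["truth_meta"], auto_unbox = FALSE, pretty = TRUE)
    message("fixture written to ", dir)
    paths
}

#' Simulate and write a fixture in one call
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param dir output directory.
#' @return list with \code{paths}, \code{truth} and \code{design}.
#' @export
simulateFixture <- function(config, dir) {
    sim <- simulateProteinGroups(config)
    paths <- writeFixture(sim, dir)
    list(paths = paths, truth = sim$truth, design = sim$design)
}
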