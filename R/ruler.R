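#' Allocate summed MS1 intensities across TMT channels
#'
#' Distributes each protein group's summed MS1 precursor intensity over the
#' reporter channels in proportion to its fractional MS3 reporter
#' intensities: \code{allocated[k] = ms1 * reporter[k] / sum(reporter)}.
#' Allocation conserves the MS1 total exactly (up to float round-off) and
#' channels with zero reporter signal receive zero.
#'
#' Rows with positive MS1 intensity but an all-zero reporter vector cannot
#' be allocated; they are flagged in the \code{"unallocatable"} attribute of
#' the result (all-zero allocation) so callers can exclude and report them
#' rather than treat silence as signal.
#'
#' @param ms1 numeric vector of summed MS1 intensities, one per protein
#'   group.
#' @param reporters matrix of reporter intensities (rows = protein groups,
#'   columns = channels), non-negative.
#' @return matrix of allocated intensities with the same dimensions as
#'   \code{reporters}; attribute \code{unallocatable} is a logical vector
#'   marking rows with ms1 > 0 and no reporter signal.
#' @examples
#' allocateMS1(1000, matrix(c(1, 1, 2, 0), 1))
#' @export
allocateMS1 <- function(ms1, reporters) {
    reporters <- as.matrix(reporters)
    if (length(ms1) != nrow(reporters))
        stop("ms1 length must match reporter rows")
    if (any(reporters < 0) || any(ms1 < 0))
        stop("intensities must be non-negative")
    tot <- rowSums(reporters)
    frac <- reporters / ifelse(tot > 0, tot, 1)
    allocated <- frac * ms1
    allocated[tot == 0, ] <- 0
    dimnames(allocated) <- dimnames(reporters)
    attr(allocated, "unallocatable") <- tot == 0 & ms1 > 0
    allocated
}

#' Estimate per-cell protein copy numbers via the histone proteomic ruler
#'
#' Anchors each sample's total histone intensity to the cell's DNA mass:
#' for protein p and sample s,
#' \deqn{copies[p,s] = \frac{I[p,s]}{MW_p} \cdot
#'       \frac{m_{DNA} N_A}{\sum_{h \in histones} I[h,s]}}
#' with \eqn{m_{DNA}} in grams. Histone rows are both anchors and quantified
#' proteins, so summed histone protein mass per cell equals \code{dnaMassPg}
#' in every sample by construction. The estimator is ratio-based: scaling
#' all intensities of a sample by a constant leaves its copy numbers
#' unchanged.
#'
#' @param allocated proteins x samples matrix of allocated intensities.
#' @param rowMeta data.frame/DataFrame with columns \code{group_id},
#'   \code{gene_name}, \code{mol_weight_da} (> 0) and \code{is_histone}
#'   (at least one TRUE).
#' @param design \linkS4class{ChannelDesign} describing the sample columns.
#' @param dnaMassPg DNA mass per cell in picograms (default 5.52, a diploid
#'   mouse genome).
#' @return a \linkS4class{CopyNumberExperiment}.
#' @export
estimateCopyNumbers <- function(allocated, rowMeta, design,
                                dnaMassPg = DEFAULT_DNA_MASS_PG) {
    allocated <- as.matrix(allocated)
    if (nrow(allocated) != nrow(rowMeta))
        stop("rowMeta must have one row per protein")
    if (any(allocated < 0)) stop("negative intensity in allocated matrix")
    if (any(rowMeta$mol_weight_da <= 0))
        stop("mol_weight_da must be positive for all rows")
    hist <- which(rowMeta$is_histone)
    if (length(hist) == 0) stop("no histone rows: ruler undefined")

    samples <- paste(design@channels$population, design@channels$replicate,
                     sep = "_")
    if (ncol(allocated) != length(samples))
        stop("allocated columns must match design channels")

    histSum <- colSums(allocated[hist, , drop = FALSE])
    if (any(histSum <= 0))
        stop("zero histone intensity in sample(s): ",
             paste(samples[histSum <= 0], collapse = ", "))

    scale <- (dnaMassPg * 1e-12) * AVOGADRO / histSum
    copies <- sweep(allocated / rowMeta$mol_weight_da, 2, scale, `*`)
    dimnames(copies) <- list(rowMeta$group_id, samples)

    se <- SummarizedExperiment(
        assays = list(copies = copies),
        rowData = DataFrame(group_id = rowMeta$group_id,
                            gene_name = rowMeta$gene_name,
                            mol_weight_da = rowMeta$mol_weight_da,
                            is_histone = rowMeta$is_histone,
                            row.names = rowMeta$group_id),
        colData = DataFrame(sample = samples,
                            population = design@channels$population,
                            replicate = design@channels$replicate,
                            row.names = samples))
    new("CopyNumberExperiment", se, dnaMassPg = dnaMassPg)
}

#' Per-cell protein content
#'
#' Multiplies each protein's copy number by its molecular weight (Da),
#' divides by Avogadro's number and sums over proteins, giving total protein
#' mass per cell in picograms for every sample, plus per-population mean and
#' standard deviation.
#'
#' @param cne a \linkS4class{CopyNumberExperiment}.
#' @return list with \code{samples} (data.frame: sample, population,
#'   replicate, content_pg) and \code{populations} (data.frame: population,
#'   mean_pg, sd_pg, n).
#' @export
proteinContent <- function(cne) {
    copies <- copyNumbers(cne)
    mw <- rowData(cne)$mol_weight_da
    content <- colSums(copies * mw) / AVOGADRO * 1e12
    cd <- as.data.frame(colData(cne))
    samples <- data.frame(sample = cd$sample, population = cd$population,
                          replicate = cd$replicate,
                          content_pg = as.numeric(content),
                          stringsAsFactors = FALSE)
    agg <- do.call(rbind, lapply(split(samples, samples$population), function(d)
        data.frame(population = d$population[1],
                   mean_pg = mean(d$content_pg),
                   sd_pg = stats::sd(d$content_pg), n = nrow(d))))
    rownames(agg) <- NULL
    list(samples = samples, populations = agg)
}

#' Aggregate copy numbers per population
#'
#' @param cne a \linkS4class{CopyNumberExperiment}.
#' @param statistic \code{"median"} (default) or \code{"mean"}, applied
#'   per protein over each population's sample columns.
#' @return proteins x populations matrix.
#' @export
aggregatePopulation <- function(cne, statistic = c("median", "mean")) {
    statistic <- match.arg(statistic)
    fun <- if (statistic == "median") stats::median else mean
    copies <- copyNumbers(cne)
    pops <- unique(colData(cne)$population)
    out <- vapply(pops, function(p) {
        cols <- which(colData(cne)$population == p)
        apply(copies[, cols, drop = FALSE], 1, fun)
    }, numeric(nrow(copies)))
    out <- matrix(out, nrow = nrow(copies),
                  dimnames = list(rownames(copies), pops))
    out
}
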