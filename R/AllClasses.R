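#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#'   assayNames
#' @importFrom jsonlite write_json
#' @importFrom tools md5sum
#' @importFrom utils read.delim write.table
#' @importFrom stats median sd var cor phyper p.adjust pt rnorm rlnorm rpois
#'   rexp runif setNames smooth.spline t.test
NULL

#' Avogadro's constant (per mol)
#'
#' Used throughout to convert between protein copies and mass.
#' @export
AVOGADRO <- 6.02214076e23

#' Default DNA mass per diploid mouse cell, in picograms
#'
#' Approximately 2 x 2.7 Gbp at ~615 g/mol/bp. The absolute scale of every
#' copy number depends on this anchor, so it is exposed as a constant and an
#' argument everywhere the ruler is applied.
#' @export
DEFAULT_DNA_MASS_PG <- 5.52

# ---------------------------------------------------------------------------
# ChannelDesign

#' TMT channel design
#'
#' Ordered mapping of TMT reporter channels to (population, replicate)
#' labels. Channel order must match the order of the reporter-intensity
#' columns in the protein-group table.
#'
#' @slot channels data.frame with columns \code{channel_label},
#'   \code{population}, \code{replicate}, one row per channel, in reporter
#'   column order.
#' @export
setClass("ChannelDesign", representation(channels = "data.frame"))

setValidity("ChannelDesign", function(object) {
    ch <- object@channels
    need <- c("channel_label", "population", "replicate")
    if (!all(need %in% colnames(ch)))
        return(paste("channels must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(ch$channel_label))
        return("channel labels must be unique")
    if (anyDuplicated(paste(ch$population, ch$replicate)))
        return("(population, replicate) pairs must be unique")
    if (nrow(ch) < 1L)
        return("design must contain at least one channel")
    TRUE
})

#' Construct a ChannelDesign
#'
#' @param channel_label character vector of channel labels (e.g. "126",
#'   "127N"), in reporter column order.
#' @param population character vector of population labels, one per channel.
#' @param replicate replicate identifiers, one per channel.
#' @return A \linkS4class{ChannelDesign}.
#' @examples
#' ChannelDesign(c("126", "127N"), c("LN_WT", "LN_WT"), c(1, 2))
#' @export
ChannelDesign <- function(channel_label, population, replicate) {
    new("ChannelDesign", channels = data.frame(
        channel_label = as.character(channel_label),
        population = as.character(population),
        replicate = as.character(replicate),
        stringsAsFactors = FALSE))
}

#' @describeIn ChannelDesign Read a channel design from a tab-delimited file
#'   with columns channel_label, population, replicate.
#' @param path path to a TSV file.
#' @export
readChannelDesign <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    need <- c("channel_label", "population", "replicate")
    miss <- setdiff(need, colnames(d))
    if (length(miss))
        stop("channel design file missing column(s): ",
             paste(miss, collapse = ", "))
    ChannelDesign(d$channel_label, d$population, d$replicate)
}

#' @describeIn ChannelDesign Write the design as TSV.
#' @param design a ChannelDesign.
#' @export
writeChannelDesign <- function(design, path) {
    utils::write.table(design@channels, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

setMethod("show", "ChannelDesign", function(object) {
    ch <- object@channels
    cat("ChannelDesign with", nrow(ch), "channels over",
        length(unique(ch$population)), "populations\n")
    tab <- table(ch$population)[unique(ch$population)]
    cat(paste0("  ", names(tab), ": ", as.integer(tab), " replicate(s)",
               collapse = "\n"), "\n")
})

# ---------------------------------------------------------------------------
# CopyNumberExperiment

#' Per-cell protein copy numbers
#'
#' A \linkS4class{SummarizedExperiment} holding the estimated copies-per-cell
#' matrix in assay \code{"copies"}. \code{rowData} carries \code{group_id},
#' \code{gene_name}, \code{mol_weight_da} and \code{is_histone};
#' \code{colData} carries \code{sample}, \code{population} and
#' \code{replicate}. The DNA mass used to anchor the ruler is stored in the
#' \code{dnaMassPg} slot.
#'
#' @slot dnaMassPg DNA mass per cell (pg) used when the ruler was inverted.
#' @export
setClass("CopyNumberExperiment",
         contains = "SummarizedExperiment",
         representation(dnaMassPg = "numeric"))

setValidity("CopyNumberExperiment", function(object) {
    if (!"copies" %in% SummarizedExperiment::assayNames(object))
        return("assay 'copies' is required")
    v <- SummarizedExperiment::assay(object, "copies")
    if (any(v < 0, na.rm = TRUE))
        return("copy numbers must be non-negative")
    rd <- rowData(object)
    need <- c("group_id", "gene_name", "mol_weight_da", "is_histone")
    if (!all(need %in% colnames(rd)))
        return(paste("rowData must contain:", paste(need, collapse = ", ")))
    if (any(rd$mol_weight_da <= 0))
        return("mol_weight_da must be positive")
    cd <- colData(object)
    if (!all(c("population", "replicate") %in% colnames(cd)))
        return("colData must contain population and replicate")
    if (length(object@dnaMassPg) != 1L || object@dnaMassPg <= 0)
        return("dnaMassPg must be a single positive number")
    TRUE
})

#' @describeIn CopyNumberExperiment DNA mass per cell (pg) used by the ruler.
#' @param object a CopyNumberExperiment.
#' @export
setGeneric("dnaMassPg", function(object) standardGeneric("dnaMassPg"))

#' @rdname CopyNumberExperiment
#' @export
setMethod("dnaMassPg", "CopyNumberExperiment", function(object) object@dnaMassPg)

#' @describeIn CopyNumberExperiment Extract the copies-per-cell matrix.
#' @export
setGeneric("copyNumbers", function(object) standardGeneric("copyNumbers"))

#' @rdname CopyNumberExperiment
#' @export
setMethod("copyNumbers", "CopyNumberExperiment",
          function(object) SummarizedExperiment::assay(object, "copies"))

setMethod("show", "CopyNumberExperiment", function(object) {
    callNextMethod()
    cat("dnaMassPg:", object@dnaMassPg, "pg;",
        sum(rowData(object)$is_histone), "histone anchor rows\n")
})

# ---------------------------------------------------------------------------
# ModerationPrior

#' Empirical-Bayes variance prior
#'
#' The scaled inverse-chi-square prior for per-protein residual variances,
#' estimated by moment matching of log residual variances against a scaled
#' F distribution.
#'
#' @slot d0 prior degrees of freedom (> 0, may be \code{Inf}).
#' @slot s0sq prior variance (> 0, finite).
#' @slot residualDf per-protein residual degrees of freedom used in the fit.
#' @export
setClass("ModerationPrior",
         representation(d0 = "numeric", s0sq = "numeric",
                        residualDf = "numeric"))

setValidity("ModerationPrior", function(object) {
    if (length(object@d0) != 1L || is.na(object@d0) || object@d0 < 0)
        return("d0 must be a single non-negative number (Inf allowed)")
    if (length(object@s0sq) != 1L || !is.finite(object@s0sq) ||
        object@s0sq <= 0)
        return("s0sq must be a single finite positive number")
    TRUE
})

setMethod("show", "ModerationPrior", function(object) {
    cat("ModerationPrior: d0 =", format(object@d0), ", s0^2 =",
        format(object@s0sq), "\n")
})

# ---------------------------------------------------------------------------
# SyntheticConfig / SyntheticTruth

#' Configuration for the synthetic TMT protein-group generator
#'
#' Defaults emulate the study design the pipeline targets: five T-cell
#' populations (two lymph-node naive CD8 populations with 6 replicates, three
#' intestinal intraepithelial T-cell subsets with 4) quantified in a single
#' multiplexed TMT set, roughly 8000 quantified protein groups, a block of
#' high-abundance histones anchoring the ruler, and multiplicative reporter
#' noise.
#'
#' @slot nProteins number of real (non-decoy) protein groups.
#' @slot populations named integer vector: replicate count per population, in
#'   channel order.
#' @slot nHistones number of histone anchor proteins (>= 1).
#' @slot baselineLog10Mean,baselineLog10Sd mean and sd of per-protein
#'   baseline abundance on the log10 copies scale.
#' @slot plantedEffects list of planted category effects; each element is a
#'   list with \code{name}, \code{members} (a member fraction in [0,1] or an
#'   explicit count), \code{populations} (character), \code{log2fc}.
#' @slot reporterCV coefficient of variation of the multiplicative
#'   (log-normal) reporter noise.
#' @slot nContaminants,nReverse,nLowPeptide decoy/edge-row counts.
#' @slot absenceFraction fraction of real proteins absent (all-zero
#'   reporters) in one random population.
#' @slot plantedOutlier NULL, or list(population, replicate,
#'   contentMultiplier) planting a protein-content outlier replicate.
#' @slot dnaMassPg DNA mass per cell (pg) used to invert the ruler.
#' @slot seed integer seed; the generator is a pure function of the config.
#' @export
setClass("SyntheticConfig", representation(
    nProteins = "numeric", populations = "integer", nHistones = "numeric",
    baselineLog10Mean = "numeric", baselineLog10Sd = "numeric",
    plantedEffects = "list", reporterCV = "numeric",
    nContaminants = "numeric", nReverse = "numeric", nLowPeptide = "numeric",
    absenceFraction = "numeric", plantedOutlier = "ANY",
    dnaMassPg = "numeric", seed = "numeric"))

setValidity("SyntheticConfig", function(object) {
    cnt <- c(nProteins = object@nProteins, nHistones = object@nHistones,
             nContaminants = object@nContaminants, nReverse = object@nReverse,
             nLowPeptide = object@nLowPeptide)
    bad <- names(cnt)[cnt < 0]
    if (length(bad)) return(paste("negative count in field:", bad[1]))
    if (object@nHistones == 0)
        return("nHistones = 0: the proteomic ruler is undefined without anchors")
    if (object@nHistones > object@nProteins)
        return("nHistones cannot exceed nProteins")
    if (object@reporterCV < 0) return("reporterCV must be >= 0")
    if (object@absenceFraction < 0 || object@absenceFraction > 1)
        return("absenceFraction must be in [0, 1]")
    if (is.null(names(object@populations)) || any(names(object@populations) == ""))
        return("populations must be a named vector of replicate counts")
    if (any(object@populations < 2))
        return("each population needs >= 2 replicates")
    if (object@dnaMassPg <= 0) return("dnaMassPg must be positive")
    for (eff in object@plantedEffects) {
        if (!all(c("name", "members", "populations", "log2fc") %in% names(eff)))
            return("each planted effect needs name, members, populations, log2fc")
        if (is.numeric(eff$members) && length(eff$members) == 1L &&
            eff$members < 0)
            return("member fraction/count must be non-negative")
        if (!all(eff$populations %in% names(object@populations)))
            return(paste("planted effect", eff$name,
                         "references unknown population"))
    }
    if (!is.null(object@plantedOutlier)) {
        po <- object@plantedOutlier
        if (!all(c("population", "replicate", "contentMultiplier") %in% names(po)))
            return("plantedOutlier needs population, replicate, contentMultiplier")
        if (!po$population %in% names(object@populations))
            return("plantedOutlier references unknown population")
    }
    TRUE
})

#' @describeIn SyntheticConfig Constructor with study-design defaults.
#' @param nProteins,populations,nHistones,baselineLog10Mean,baselineLog10Sd
#'   see slots.
#' @param plantedEffects,reporterCV,nContaminants,nReverse,nLowPeptide see
#'   slots.
#' @param absenceFraction,plantedOutlier,dnaMassPg,seed see slots.
#' @export
SyntheticConfig <- function(nProteins = 8000,
                            populations = c(LN_WT = 6L, LN_P14 = 6L,
                                            IEL_ab_ab = 4L, IEL_ab_aa = 4L,
                                            IEL_gd_aa = 4L),
                            nHistones = 30,
                            baselineLog10Mean = 4.0, baselineLog10Sd = 1.0,
                            plantedEffects = list(),
                            reporterCV = 0.10,
                            nContaminants = 40, nReverse = 40,
                            nLowPeptide = 60,
                            absenceFraction = 0.05,
                            plantedOutlier = NULL,
                            dnaMassPg = DEFAULT_DNA_MASS_PG,
                            seed = 1L) {
    storage.mode(populations) <- "integer"
    new("SyntheticConfig", nProteins = nProteins, populations = populations,
        nHistones = nHistones, baselineLog10Mean = baselineLog10Mean,
        baselineLog10Sd = baselineLog10Sd, plantedEffects = plantedEffects,
        reporterCV = reporterCV, nContaminants = nContaminants,
        nReverse = nReverse, nLowPeptide = nLowPeptide,
        absenceFraction = absenceFraction, plantedOutlier = plantedOutlier,
        dnaMassPg = dnaMassPg, seed = seed)
}

setMethod("show", "SyntheticConfig", function(object) {
    cat("SyntheticConfig:", object@nProteins, "proteins,",
        sum(object@populations), "channels over",
        length(object@populations), "populations, reporter CV",
        object@reporterCV, ", seed", object@seed, "\n")
})

#' Ground truth for a synthetic protein-group table
#'
#' @slot trueCopies proteins x samples matrix of noise-free copies per cell.
#' @slot plantedLog2FC proteins x populations matrix of planted log2 fold
#'   changes (0 where unaffected).
#' @slot histoneIds group ids of the histone anchor rows.
#' @slot outlierSamples sample labels of planted content-outlier replicates.
#' @slot categoryMembership named list mapping planted category name to the
#'   member group ids.
#' @export
setClass("SyntheticTruth", representation(
    trueCopies = "matrix", plantedLog2FC = "matrix", histoneIds = "character",
    outlierSamples = "character", categoryMembership = "list"))

setValidity("SyntheticTruth", function(object) {
    if (any(object@trueCopies < 0)) return("trueCopies must be >= 0")
    if (!all(object@histoneIds %in% rownames(object@trueCopies)))
        return("histoneIds must be a subset of protein ids")
    planted <- unique(unlist(object@categoryMembership))
    nz <- rownames(object@plantedLog2FC)[rowSums(object@plantedLog2FC != 0) > 0]
    if (!all(nz %in% planted))
        return("plantedLog2FC must be zero outside planted category members")
    TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", nrow(object@trueCopies), "proteins x",
        ncol(object@trueCopies), "samples;",
        length(object@histoneIds), "histones;",
        length(object@categoryMembership), "planted categories;",
        length(object@outlierSamples), "outlier sample(s)\n")
})
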