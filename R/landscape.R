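# match a gene-symbol set against (possibly semicolon-separated) gene names;
# returns logical row membership, case-insensitive
matchGeneRows <- function(geneNames, set) {
    s <- tolower(set)
    vapply(strsplit(tolower(geneNames), ";", fixed = TRUE),
           function(g) any(trimws(g) %in% s), logical(1))
}

#' Principal component analysis of samples
#'
#' PCA of samples on (optionally log2-transformed) copy numbers, restricted
#' by default to proteins detected (nonzero) in every sample so that absent
#' proteins do not dominate. Features are mean-centred per protein and
#' decomposed by SVD. A deterministic sign convention is applied: each
#' component is flipped so its largest-magnitude loading is positive.
#'
#' @param cne a \linkS4class{CopyNumberExperiment}.
#' @param transform \code{"log2"} (default; log2(copies + 1)) or
#'   \code{"none"}.
#' @param completeOnly restrict to proteins with nonzero copies in all
#'   samples (default TRUE).
#' @return list with \code{scores} (samples x components),
#'   \code{varianceFraction}, \code{loadings} (proteins x components) and
#'   \code{transform}.
#' @export
pcaSamples <- function(cne, transform = c("log2", "none"),
                       completeOnly = TRUE) {
    transform <- match.arg(transform)
    copies <- copyNumbers(cne)
    if (ncol(copies) < 3) stop("PCA needs >= 3 samples")
    if (completeOnly) copies <- copies[rowSums(copies > 0) == ncol(copies), ,
                                       drop = FALSE]
    if (nrow(copies) < 2) stop("fewer than 2 proteins in PCA scope")
    x <- if (transform == "log2") log2(copies + 1) else copies
    x <- t(x - rowMeans(x))            # samples x proteins, centred
    sv <- svd(x)
    ncomp <- sum(sv$d > max(sv$d) * 1e-12)
    d <- sv$d[seq_len(ncomp)]
    scores <- sv$u[, seq_len(ncomp), drop = FALSE] %*% diag(d, ncomp)
    loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
    for (j in seq_len(ncomp)) {            # deterministic sign
        i <- which.max(abs(loadings[, j]))
        if (loadings[i, j] < 0) {
            loadings[, j] <- -loadings[, j]
            scores[, j] <- -scores[, j]
        }
    }
    dimnames(scores) <- list(colnames(copies), paste0("PC", seq_len(ncomp)))
    dimnames(loadings) <- list(rownames(copies),
                               paste0("PC", seq_len(ncomp)))
    list(scores = scores,
         varianceFraction = stats::setNames(sv$d^2 / sum(sv$d^2),
                                            paste0("PC", seq_along(sv$d)))[
                                                seq_len(ncomp)],
         loadings = loadings, transform = transform)
}

#' Pairwise population correlations of copy numbers
#'
#' Pearson correlation of log10(median copies + pseudocount) between every
#' pair of populations, computed over the proteins detected (nonzero) in
#' both populations of the pair. Degenerate (zero-variance) vectors give NA
#' rather than 0.
#'
#' @param popMatrix proteins x populations matrix (e.g. from
#'   \code{\link{aggregatePopulation}}).
#' @param pseudocount offset before log10 (default 1).
#' @param minShared minimum proteins detected in both populations
#'   (default 10).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
populationCorrelation <- function(popMatrix, pseudocount = 1,
                                  minShared = 10) {
    k <- ncol(popMatrix)
    out <- diag(1, k)
    dimnames(out) <- list(colnames(popMatrix), colnames(popMatrix))
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
        shared <- popMatrix[, i] > 0 & popMatrix[, j] > 0
        if (sum(shared) < minShared)
            stop("fewer than ", minShared, " proteins detected in both ",
                 colnames(popMatrix)[i], " and ", colnames(popMatrix)[j])
        x <- log10(popMatrix[shared, i] + pseudocount)
        y <- log10(popMatrix[shared, j] + pseudocount)
        r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
            stats::cor(x, y)
        out[i, j] <- out[j, i] <- r
    }
    out
}

#' Mass fractions of protein categories within the most abundant proteome
#'
#' Ranks proteins by per-sample mass (copies x MW / N_A; or raw copies),
#' keeps the top of the ranking until the cumulative basis reaches
#' \code{topFraction} of the sample total (the protein crossing the
#' threshold is included), and reports each category's share of the
#' selected amount plus an "other" remainder. Categories must be mutually
#' disjoint.
#'
#' @param cne a \linkS4class{CopyNumberExperiment}.
#' @param categories named list of gene-symbol sets (e.g. histones,
#'   ribosomal proteins, glycolytic enzymes, chaperones, granzymes).
#' @param basis \code{"mass"} (default) or \code{"copies"}.
#' @param topFraction fraction of the per-sample total to keep, in (0, 1]
#'   (default 0.5: the top half of the proteome by mass).
#' @return data.frame with columns sample, category, amount, proportion;
#'   per sample, proportions (including "other") sum to 1.
#' @export
categoryMassFractions <- function(cne, categories, basis = c("mass", "copies"),
                                  topFraction = 0.5) {
    basis <- match.arg(basis)
    if (topFraction <= 0 || topFraction > 1)
        stop("topFraction must be in (0, 1]")
    genes <- rowData(cne)$gene_name
    member <- vapply(categories, function(s) matchGeneRows(genes, s),
                     logical(nrow(cne)))
    if (any(rowSums(member) > 1)) {
        bad <- which(rowSums(member) > 1)[1]
        stop("categories overlap (e.g. row ", rownames(cne)[bad], ")")
    }
    label <- rep("other", nrow(cne))
    for (nm in colnames(member)) label[member[, nm]] <- nm

    copies <- copyNumbers(cne)
    values <- if (basis == "mass")
        copies * rowData(cne)$mol_weight_da / AVOGADRO * 1e12 else copies
    out <- lapply(colnames(values), function(s) {
        v <- values[, s]
        o <- order(v, decreasing = TRUE)
        cum <- cumsum(v[o])
        ncut <- which(cum >= topFraction * sum(v))[1]
        sel <- o[seq_len(ncut)]
        amt <- tapply(v[sel], factor(label[sel],
                                     levels = c(names(categories), "other")),
                      sum, default = 0)
        data.frame(sample = s, category = names(amt),
                   amount = as.numeric(amt),
                   proportion = as.numeric(amt) / sum(v[sel]),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Gene-set copy-number sums with Welch tests
#'
#' For each gene set, sums copies per cell over the member proteins in every
#' sample (e.g. total cytoplasmic ribosomal protein copies) and compares two
#' populations with Welch's t-test. Sets resolving to no protein rows are
#' skipped with a warning.
#'
#' @param cne a \linkS4class{CopyNumberExperiment}.
#' @param sets named list of gene-symbol sets.
#' @param popA,popB population labels for the Welch contrast.
#' @return list with \code{sums} (data.frame: set, sample, population, sum)
#'   and \code{tests} (data.frame: set, n_proteins, t, df, p).
#' @export
genesetSums <- function(cne, sets, popA, popB) {
    copies <- copyNumbers(cne)
    genes <- rowData(cne)$gene_name
    pops <- colData(cne)$population
    sums <- NULL; tests <- NULL
    for (nm in names(sets)) {
        rows <- matchGeneRows(genes, sets[[nm]])
        if (!any(rows)) {
            warning("gene set ", nm, " resolves to no protein rows; skipped")
            next
        }
        s <- colSums(copies[rows, , drop = FALSE])
        sums <- rbind(sums, data.frame(set = nm, sample = colnames(copies),
                                       population = pops,
                                       sum = as.numeric(s),
                                       stringsAsFactors = FALSE))
        wt <- welchT(s[pops == popA], s[pops == popB])
        tests <- rbind(tests, data.frame(set = nm, n_proteins = sum(rows),
                                         t = wt$t, df = wt$df, p = wt$p,
                                         stringsAsFactors = FALSE))
    }
    rownames(sums) <- rownames(tests) <- NULL
    list(sums = sums, tests = tests)
}
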