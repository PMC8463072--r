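#' Log2-transform a copy-number matrix
#'
#' Variance-stabilising transform applied before linear modelling:
#' \code{log2(copies + pseudocount)}. Zeros (absent proteins) map to
#' \code{log2(pseudocount)}.
#'
#' @param x a \linkS4class{CopyNumberExperiment} or a non-negative matrix.
#' @param pseudocount non-negative offset (default 1, so zeros map to 0).
#' @return matrix of log2-transformed values.
#' @export
logTransform <- function(x, pseudocount = 1) {
    if (is(x, "CopyNumberExperiment")) x <- copyNumbers(x)
    x <- as.matrix(x)
    if (pseudocount < 0) stop("pseudocount must be >= 0")
    if (any(x < 0, na.rm = TRUE)) stop("negative entries cannot be log-transformed")
    log2(x + pseudocount)
}

# Newton inversion of the trigamma function, used when matching the spread
# of log residual variances to the prior degrees of freedom.
trigammaInverse <- function(x) {
    out <- x
    hi <- !is.na(x) & x > 1e7
    lo <- !is.na(x) & x < 1e-6
    out[hi] <- 1 / sqrt(x[hi])
    out[lo] <- 1 / x[lo]
    mid <- !is.na(x) & !hi & !lo
    y <- 0.5 + 1 / x[mid]
    for (i in seq_len(50)) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x[mid]) / psigamma(y, deriv = 2)
        y <- y + dif
        if (max(-dif / y) < 1e-8) break
    }
    out[mid] <- y
    out
}

#' Fit the empirical-Bayes variance prior
#'
#' Estimates the scaled inverse-chi-square prior (d0, s0^2) for per-protein
#' residual variances by moment matching on the log scale: under the model,
#' log(s^2) follows a location-shifted log-F distribution whose mean and
#' variance involve digamma/trigamma terms of the residual and prior degrees
#' of freedom. When the observed spread of log variances does not exceed its
#' expectation under equal true variances, d0 is infinite and s0^2 is the
#' common variance.
#'
#' @param s2 per-protein residual variances (>= 0).
#' @param df residual degrees of freedom (scalar or per-protein vector).
#' @return a \linkS4class{ModerationPrior}.
#' @export
fitModerationPrior <- function(s2, df) {
    df <- rep_len(df, length(s2))
    ok <- is.finite(s2) & s2 > 0 & df > 0
    if (all(s2 == 0)) stop("all residual variances are zero: degenerate input")
    if (sum(ok) < 10)
        stop("need at least 10 proteins with positive variance and df")
    z <- log(s2[ok])
    dfo <- df[ok]
    e <- z - digamma(dfo / 2) + log(dfo / 2)
    emean <- mean(e)
    evar <- stats::var(e) - mean(trigamma(dfo / 2))
    if (is.finite(evar) && evar > 0) {
        d0 <- 2 * trigammaInverse(evar)
        s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
        d0 <- Inf
        s0sq <- exp(emean)
    }
    new("ModerationPrior", d0 = d0, s0sq = s0sq, residualDf = df)
}

#' Moderated two-sample t-test
#'
#' Empirical-Bayes two-group comparison on log2 copy numbers. Per protein,
#' the pooled residual variance s^2 (df = n_a + n_b - 2) is shrunk toward
#' the prior: \code{s2_post = (d0 s0^2 + df s^2) / (d0 + df)}, and
#' \code{t = log2fc / sqrt(s2_post (1/n_a + 1/n_b))} is referred to a t
#' distribution on d0 + df degrees of freedom (normal when d0 is infinite).
#' At d0 = 0 this is the ordinary pooled two-sample t-test.
#'
#' Proteins with fewer than 2 finite values in either group are excluded and
#' listed in \code{metadata(result)$excluded}.
#'
#' @param logmat proteins x samples matrix of log2 values.
#' @param colsA,colsB column indices or names of the two groups (disjoint,
#'   each of size >= 2).
#' @param prior a \linkS4class{ModerationPrior}, or NULL to fit one from the
#'   data.
#' @return \code{DataFrame} with per-protein \code{mean_log2_a},
#'   \code{mean_log2_b}, \code{log2fc} (a - b), \code{s2}, \code{t},
#'   \code{p_value}, \code{df_total}; metadata carries the prior and the
#'   excluded protein ids.
#' @export
moderatedTTest <- function(logmat, colsA, colsB, prior = NULL) {
    logmat <- as.matrix(logmat)
    if (is.character(colsA)) colsA <- match(colsA, colnames(logmat))
    if (is.character(colsB)) colsB <- match(colsB, colnames(logmat))
    if (length(intersect(colsA, colsB)))
        stop("group columns overlap")
    if (length(colsA) < 2 || length(colsB) < 2)
        stop("each group needs >= 2 columns")
    a <- logmat[, colsA, drop = FALSE]
    b <- logmat[, colsB, drop = FALSE]
    nA <- rowSums(is.finite(a))
    nB <- rowSums(is.finite(b))
    keep <- nA >= 2 & nB >= 2
    excluded <- rownames(logmat)[!keep]
    a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
    nA <- nA[keep]; nB <- nB[keep]

    meanA <- rowMeans(a, na.rm = TRUE)
    meanB <- rowMeans(b, na.rm = TRUE)
    ssA <- rowSums((a - meanA)^2, na.rm = TRUE)
    ssB <- rowSums((b - meanB)^2, na.rm = TRUE)
    df <- nA + nB - 2
    s2 <- (ssA + ssB) / df

    if (is.null(prior)) prior <- fitModerationPrior(s2, df)
    d0 <- prior@d0; s0sq <- prior@s0sq
    s2post <- if (is.infinite(d0)) rep(s0sq, length(s2)) else
        (d0 * s0sq + df * s2) / (d0 + df)
    fc <- meanA - meanB
    se <- sqrt(s2post * (1 / nA + 1 / nB))
    tstat <- ifelse(se > 0, fc / se, ifelse(fc == 0, 0, sign(fc) * Inf))
    dfTotal <- d0 + df
    p <- 2 * stats::pt(-abs(tstat), df = dfTotal)
    p[tstat == 0] <- 1

    out <- DataFrame(mean_log2_a = meanA, mean_log2_b = meanB,
                     log2fc = fc, s2 = s2, t = tstat, p_value = p,
                     df_total = dfTotal,
                     row.names = rownames(logmat)[keep])
    metadata(out)$prior <- prior
    metadata(out)$excluded <- excluded
    out
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 from the flat right end of the p-value
#' histogram and converts p-values to q-values (estimated positive FDR).
#' With a single lambda, \code{pi0 = mean(p > lambda) / (1 - lambda)}; with
#' a grid (default 0.05..0.95 by 0.05) the per-lambda estimates are smoothed
#' with a cubic spline and read off at the largest lambda. pi0 is clipped to
#' (0, 1]. With fewer than 20 p-values the grid is unstable, so pi0 falls
#' back to 1 (Benjamini-Hochberg).
#'
#' @param p p-values in [0, 1].
#' @param lambda tuning grid (or scalar) in [0, 1).
#' @return q-values, monotone in p, with attribute \code{pi0}.
#' @export
storeyQvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
    if (length(p) == 0) stop("empty p-value vector")
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    m <- length(p)
    if (length(lambda) == 1) {
        pi0 <- mean(p > lambda) / (1 - lambda)
    } else if (m < 20) {
        pi0 <- 1
    } else {
        lambda <- sort(lambda)
        pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
        fit <- stats::smooth.spline(lambda, pi0l, df = 3)
        pi0 <- stats::predict(fit, x = max(lambda))$y
    }
    pi0 <- min(pi0, 1)
    if (pi0 <= 0) pi0 <- .Machine$double.eps
    r <- rank(p, ties.method = "max")
    q <- pi0 * m * p / r
    o <- order(p, decreasing = TRUE)
    q[o] <- cummin(q[o])
    q <- pmin(q, 1)
    attr(q, "pi0") <- pi0
    q
}

#' Welch's unequal-variance t-test
#'
#' Thin wrapper around \code{stats::t.test} used for aggregate quantities
#' (gene-set copy sums, protein content comparisons).
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return list with \code{t}, \code{df} (Welch-Satterthwaite) and \code{p}
#'   (two-sided).
#' @export
welchT <- function(a, b) {
    if (length(a) < 2 || length(b) < 2)
        stop("Welch's t-test needs >= 2 values per group")
    tt <- stats::t.test(a, b, var.equal = FALSE)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
}

#' Summarise a contrast's fold-change distribution
#'
#' The significance classes and candidate rules are expressed relative to
#' the location and spread of the tested log2 fold changes.
#'
#' @param log2fc log2 fold changes of all proteins tested in the contrast.
#' @return list with \code{median} and \code{sd}.
#' @export
foldChangeDistribution <- function(log2fc) {
    log2fc <- log2fc[is.finite(log2fc)]
    list(median = stats::median(log2fc), sd = stats::sd(log2fc))
}

#' Star significance classes from p-values and the fold-change distribution
#'
#' Assigns \code{***} when p < 1e-4 and |log2fc - median| >= 1.5 sd,
#' otherwise \code{**} when p < 1e-3 and |log2fc - median| >= 1 sd,
#' otherwise \code{ns}. Thresholds are direction-symmetric about the median
#' of the contrast's log2 fold-change distribution.
#'
#' @param log2fc,p per-protein log2 fold changes and p-values.
#' @param fcDist output of \code{\link{foldChangeDistribution}} computed on
#'   this contrast; computed from \code{log2fc} when NULL.
#' @param pStar2,pStar3 p-value gates for ** and *** (defaults 0.001 and
#'   0.0001).
#' @param sdStar2,sdStar3 fold-change gates in sd units (defaults 1 and 1.5).
#' @return character vector in \code{c("ns", "**", "***")}.
#' @export
classifySignificance <- function(log2fc, p, fcDist = NULL,
                                 pStar2 = 0.001, pStar3 = 0.0001,
                                 sdStar2 = 1, sdStar3 = 1.5) {
    if (is.null(fcDist)) fcDist <- foldChangeDistribution(log2fc)
    if (!is.finite(fcDist$sd) || fcDist$sd == 0) {
        warning("fold-change sd is zero; suppressing all non-ns labels")
        return(rep("ns", length(log2fc)))
    }
    dev <- abs(log2fc - fcDist$median)
    out <- rep("ns", length(log2fc))
    out[p < pStar2 & dev >= sdStar2 * fcDist$sd] <- "**"
    out[p < pStar3 & dev >= sdStar3 * fcDist$sd] <- "***"
    out
}

#' Select up/down candidate sets for overrepresentation analysis
#'
#' Candidates are proteins with p < 0.001 and a log2 fold change at least
#' 1.5 sd above (up) or below (down) the median of the contrast's
#' fold-change distribution. The two sets are disjoint whenever sd > 0.
#'
#' @param ids protein/gene identifiers, parallel to \code{log2fc}.
#' @param log2fc,p per-protein statistics.
#' @param fcDist fold-change distribution (computed from \code{log2fc} when
#'   NULL).
#' @param pCut p-value gate (default 0.001).
#' @param sdCut fold-change gate in sd units (default 1.5).
#' @return list with \code{up} and \code{down} identifier vectors.
#' @export
selectEnrichmentCandidates <- function(ids, log2fc, p, fcDist = NULL,
                                       pCut = 0.001, sdCut = 1.5) {
    if (is.null(fcDist)) fcDist <- foldChangeDistribution(log2fc)
    up <- ids[p < pCut & log2fc >= fcDist$median + sdCut * fcDist$sd]
    down <- ids[p < pCut & log2fc <= fcDist$median - sdCut * fcDist$sd]
    list(up = up, down = down)
}

#' Differential expression between two populations
#'
#' End-to-end contrast on a \linkS4class{CopyNumberExperiment}: log2
#' transform, moderated t-test of population A vs B, Storey q-values, star
#' classes against the contrast's fold-change distribution, and an
#' exclusivity class for proteins detected in only one of the populations
#' (detected = nonzero copies in at least half of a population's replicates;
#' absent = zero in all of the other population's replicates). Exclusive
#' proteins keep their (pseudocount-damped) statistics but are reported
#' separately rather than interpreted as finite fold changes.
#'
#' @param cne a \linkS4class{CopyNumberExperiment}.
#' @param popA,popB population labels in \code{colData(cne)$population};
#'   fold changes are A - B on the log2 scale.
#' @param pseudocount offset for the log transform (default 1).
#' @param prior optional \linkS4class{ModerationPrior}.
#' @return \code{DataFrame} with group means, \code{log2fc}, \code{t},
#'   \code{p_value}, \code{q_value}, \code{star}, \code{exclusive}
#'   (none/a_only/b_only); metadata holds the fold-change distribution,
#'   prior, populations and excluded ids.
#' @export
differentialExpression <- function(cne, popA, popB, pseudocount = 1,
                                   prior = NULL) {
    pops <- colData(cne)$population
    if (!popA %in% pops || !popB %in% pops)
        stop("contrast population not present in the experiment")
    colsA <- which(pops == popA)
    colsB <- which(pops == popB)
    logmat <- logTransform(cne, pseudocount)
    res <- moderatedTTest(logmat, colsA, colsB, prior = prior)
    res$q_value <- as.numeric(storeyQvalues(res$p_value))

    copies <- copyNumbers(cne)[rownames(res), , drop = FALSE]
    detA <- rowSums(copies[, colsA, drop = FALSE] > 0) >=
        ceiling(length(colsA) / 2)
    detB <- rowSums(copies[, colsB, drop = FALSE] > 0) >=
        ceiling(length(colsB) / 2)
    absA <- rowSums(copies[, colsA, drop = FALSE] > 0) == 0
    absB <- rowSums(copies[, colsB, drop = FALSE] > 0) == 0
    res$exclusive <- ifelse(detA & absB, "a_only",
                            ifelse(detB & absA, "b_only", "none"))

    # exclusive proteins carry pseudocount-driven extreme fold changes; the
    # fold-change distribution (and hence the star/candidate thresholds) is
    # defined over the genuinely two-sided comparisons only
    shared <- res$exclusive == "none"
    fcDist <- foldChangeDistribution(res$log2fc[shared])
    res$star <- rep("ns", nrow(res))
    res$star[shared] <- classifySignificance(res$log2fc[shared],
                                             res$p_value[shared], fcDist)
    res$gene_name <- rowData(cne)[rownames(res), "gene_name"]
    metadata(res)$fc_dist <- fcDist
    metadata(res)$populations <- c(a = popA, b = popB)
    res
}
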