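test_that("log transform maps zeros to log2(pseudocount) and rejects negatives", {
    expect_equal(logTransform(matrix(0), 1), matrix(0))
    expect_equal(logTransform(matrix(3), 1), matrix(2))
    m <- matrix(c(1000, 2000), 1)
    expect_equal(diff(logTransform(m, 1)[1, ]), 1, tolerance = 1e-3)
    expect_error(logTransform(matrix(-1)), "negative")
})

test_that("moderation prior is recovered from its generating distribution", {
    set.seed(1)
    s2 <- 1 * stats::rf(5000, 4, 4)     # s0^2 = 1, residual df 4, d0 = 4
    prior <- fitModerationPrior(s2, 4)
    expect_lt(abs(prior@d0 - 4) / 4, 0.25)
    expect_lt(abs(prior@s0sq - 1), 0.10)
    expect_error(fitModerationPrior(rep(0, 100), 4), "zero")
    expect_error(fitModerationPrior(c(1, 2), c(4, 4)), "at least 10")
})

test_that("equal variances give an infinite prior df and a constant posterior", {
    prior <- fitModerationPrior(rep(2.5, 100), 4)
    expect_identical(prior@d0, Inf)
    m <- matrix(stats::rnorm(100 * 6), 100, 6,
                dimnames = list(sprintf("g%03d", 1:100), NULL))
    res <- moderatedTTest(m, 1:3, 4:6, prior = prior)
    s2post <- (res$log2fc / res$t)^2 / (1 / 3 + 1 / 3)
    expect_equal(unname(s2post), rep(prior@s0sq, 100), tolerance = 1e-9)
})

test_that("moderated t matches a step-by-step scalar oracle", {
    set.seed(7)
    m <- matrix(stats::rnorm(50 * 7, 10, 1), 50, 7,
                dimnames = list(sprintf("g%02d", 1:50), NULL))
    colsA <- 1:3; colsB <- 4:7
    prior <- new("ModerationPrior", d0 = 4, s0sq = 0.8, residualDf = 5)
    res <- moderatedTTest(m, colsA, colsB, prior = prior)
    for (g in rownames(m)) {
        a <- m[g, colsA]; b <- m[g, colsB]
        s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
            (length(a) + length(b) - 2)
        s2post <- (4 * 0.8 + 5 * s2) / (4 + 5)
        tG <- (mean(a) - mean(b)) / sqrt(s2post * (1 / 3 + 1 / 4))
        pG <- 2 * stats::pt(-abs(tG), df = 9)
        expect_equal(unname(res[g, "t"]), tG, tolerance = 1e-10)
        expect_equal(unname(res[g, "p_value"]), pG, tolerance = 1e-10)
    }
})

test_that("d0 = 0 reduces the moderated t to the ordinary pooled t", {
    set.seed(8)
    m <- matrix(stats::rnorm(30 * 6), 30, 6,
                dimnames = list(sprintf("g%02d", 1:30), NULL))
    prior <- new("ModerationPrior", d0 = 0, s0sq = 1, residualDf = 4)
    res <- moderatedTTest(m, 1:3, 4:6, prior = prior)
    for (g in c("g01", "g15", "g30")) {
        tt <- stats::t.test(m[g, 1:3], m[g, 4:6], var.equal = TRUE)
        expect_equal(unname(res[g, "t"]), unname(tt$statistic), tolerance = 1e-10)
        expect_equal(unname(res[g, "p_value"]), tt$p.value, tolerance = 1e-10)
    }
})

test_that("moderated t agrees with an independent empirical-Bayes implementation", {
    set.seed(42)
    m <- matrix(stats::rnorm(200 * 6), 200, 6,
                dimnames = list(sprintf("g%03d", 1:200), NULL))
    res <- moderatedTTest(m, 1:3, 4:6)
    design <- cbind(Intercept = 1, groupA = c(1, 1, 1, 0, 0, 0))
    fit <- limma::eBayes(limma::lmFit(m, design))
    prior <- S4Vectors::metadata(res)$prior
    expect_equal(prior@d0, fit$df.prior, tolerance = 1e-9)
    expect_equal(prior@s0sq, fit$s2.prior, tolerance = 1e-9)
    expect_equal(unname(res$t), unname(fit$t[, 2]), tolerance = 1e-9)
    expect_equal(unname(res$p_value), unname(fit$p.value[, 2]),
                 tolerance = 1e-9)
})

test_that("posterior variance lies between the observed and prior variance", {
    set.seed(10)
    m <- matrix(stats::rnorm(500 * 6), 500, 6,
                dimnames = list(sprintf("g%03d", 1:500), NULL)) *
        stats::runif(500, 0.5, 2)
    res <- moderatedTTest(m, 1:3, 4:6)
    prior <- S4Vectors::metadata(res)$prior
    s2post <- (prior@d0 * prior@s0sq + 4 * res$s2) / (prior@d0 + 4)
    expect_true(all(s2post >= pmin(res$s2, prior@s0sq) - 1e-12))
    expect_true(all(s2post <= pmax(res$s2, prior@s0sq) + 1e-12))
})

test_that("group handling: overlaps rejected, sparse rows excluded, zero fc gives p = 1", {
    m <- matrix(1, 5, 6, dimnames = list(paste0("g", 1:5), NULL))
    expect_error(moderatedTTest(m, 1:3, 3:6), "overlap")
    m2 <- matrix(stats::rnorm(20 * 6), 20, 6,
                 dimnames = list(sprintf("g%02d", 1:20), NULL))
    m2[1, 1:2] <- NA                      # only 1 finite value in group A
    res <- moderatedTTest(m2, 1:3, 4:6,
                          prior = new("ModerationPrior", d0 = 4, s0sq = 1,
                                      residualDf = 4))
    expect_identical(S4Vectors::metadata(res)$excluded, "g01")
    m3 <- matrix(rep(c(5, 5, 5, 7, 7, 7), each = 3), 3, 6, byrow = FALSE)
    rownames(m3) <- paste0("g", 1:3)
    m3[, 4:6] <- m3[, 1:3]                # identical groups
    res3 <- moderatedTTest(m3, 1:3, 4:6,
                           prior = new("ModerationPrior", d0 = 4, s0sq = 1,
                                       residualDf = 4))
    expect_equal(unname(res3$t), rep(0, 3))
    expect_equal(unname(res3$p_value), rep(1, 3))
})

test_that("Storey q-values follow the estimator's hand-stepped oracle", {
    p <- c(0.001, 0.01, 0.02, 0.8, 0.9)
    q <- storeyQvalues(p, lambda = 0.5)
    # pi0 = mean(p > 0.5)/(1 - 0.5) = 0.8; q = cummin from the largest p of
    # pi0 * m * p / rank
    expect_equal(attr(q, "pi0"), 0.8)
    expect_equal(as.numeric(q), c(0.004, 0.02, 0.08 / 3, 0.72, 0.72),
                 tolerance = 1e-12)
})

test_that("q-value contracts: BH reduction, monotonicity, saturation", {
    set.seed(11)
    p <- stats::runif(200)
    q <- storeyQvalues(p, lambda = 0)          # forces pi0 = 1
    expect_equal(as.numeric(q), stats::p.adjust(p, "BH"), tolerance = 1e-12)
    p2 <- stats::rbeta(500, 0.5, 3)
    q2 <- storeyQvalues(p2)
    expect_true(all(diff(as.numeric(q2)[order(p2)]) >= -1e-12))
    expect_true(all(q2 >= 0 & q2 <= 1))
    expect_equal(as.numeric(storeyQvalues(rep(1, 30))), rep(1, 30))
    expect_error(storeyQvalues(numeric(0)), "empty")
    expect_error(storeyQvalues(c(0.5, 1.2)), "0, 1")
})

test_that("Welch test matches a hand-stepped computation and is antisymmetric", {
    a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5)
    w <- welchT(a, b)
    # hand computation: se^2 = 1/3 + 2.5/5; df by Welch-Satterthwaite
    se2 <- stats::var(a) / 3 + stats::var(b) / 5
    tHand <- (mean(a) - mean(b)) / sqrt(se2)
    dfHand <- se2^2 / ((stats::var(a) / 3)^2 / 2 + (stats::var(b) / 5)^2 / 4)
    expect_equal(w$t, tHand, tolerance = 1e-12)
    expect_equal(w$df, dfHand, tolerance = 1e-12)
    expect_equal(w$p, 2 * stats::pt(-abs(tHand), dfHand), tolerance = 1e-12)
    wRev <- welchT(b, a)
    expect_equal(wRev$t, -w$t)
    expect_equal(wRev$p, w$p)
    same <- welchT(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$t, 0)
    expect_equal(same$p, 1)
    expect_error(welchT(1, c(1, 2)), ">= 2")
})

test_that("star classes follow the fold-change-distribution thresholds", {
    fc <- c(0.1, -0.2, 0.05, 0, -0.1, 0.15, 2, -2)   # med/sd context
    dist <- foldChangeDistribution(fc)
    mk <- function(dev) dist$median + dev * dist$sd
    stars <- classifySignificance(
        log2fc = c(mk(1.2), mk(-1.6), mk(3), mk(0)),
        p = c(5e-4, 5e-5, 1e-2, 1e-9), fcDist = dist)
    expect_equal(stars, c("**", "***", "ns", "ns"))
    expect_warning(
        out <- classifySignificance(c(1, 1), c(1e-9, 1e-9),
                                    list(median = 1, sd = 0)),
        "zero")
    expect_equal(out, c("ns", "ns"))
})

test_that("candidate selection applies the median +/- 1.5 sd rule with disjoint sets", {
    dist <- list(median = 0.2, sd = 0.5)
    ids <- paste0("p", 1:4)
    fc <- c(0.2 + 2 * 0.5, 0.2, 0.2 - 1.6 * 0.5, 0.2 + 1.6 * 0.5)
    p <- c(1e-4, 1e-4, 1e-4, 0.5)
    cand <- selectEnrichmentCandidates(ids, fc, p, dist)
    expect_identical(cand$up, "p1")       # p4 fails the p gate
    expect_identical(cand$down, "p3")     # p2 sits at the median
    expect_length(intersect(cand$up, cand$down), 0)
})

test_that("exclusive proteins are classed separately in a full contrast", {
    cfg <- smallConfig(nProteins = 500, nHistones = 10,
                       populations = c(A = 3L, B = 3L),
                       reporterCV = 0.05, absenceFraction = 0.1, seed = 13)
    run <- syntheticCopyNumbers(cfg)
    de <- differentialExpression(run$cne, "A", "B")
    copies <- copyNumbers(run$cne)
    aCols <- SummarizedExperiment::colData(run$cne)$population == "A"
    absentInA <- rowSums(copies[rownames(de), aCols] > 0) == 0
    presentInB <- rowSums(copies[rownames(de), !aCols] > 0) >= 2
    expect_setequal(rownames(de)[de$exclusive == "b_only"],
                    rownames(de)[absentInA & presentInB])
    expect_true(all(de$q_value >= 0 & de$q_value <= 1))
    expect_true(all(de$star %in% c("ns", "**", "***")))
})
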