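# a minimal CopyNumberExperiment built by hand, for unit tests that need
# full control over copies and molecular weights
manualCNE <- function(copies, mw, histone = rep(FALSE, nrow(copies)),
                      dnaMassPg = 5.52) {
    ids <- sprintf("P%02d", seq_len(nrow(copies)))
    dimnames(copies) <- list(ids, colnames(copies))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(copies = copies),
        rowData = S4Vectors::DataFrame(group_id = ids, gene_name = ids,
                                       mol_weight_da = mw,
                                       is_histone = histone,
                                       row.names = ids),
        colData = S4Vectors::DataFrame(
            sample = colnames(copies),
            population = rep("X", ncol(copies)),
            replicate = seq_len(ncol(copies)),
            row.names = colnames(copies)))
    new("CopyNumberExperiment", se, dnaMassPg = dnaMassPg)
}

test_that("MS1 allocation follows fractional reporter intensities and conserves totals", {
    a <- allocateMS1(1000, matrix(c(1, 1, 2, 0), 1))
    expect_equal(unname(a[1, ]), c(250, 250, 500, 0))
    # single nonzero reporter receives everything
    b <- allocateMS1(777, matrix(c(0, 5, 0), 1))
    expect_equal(unname(b[1, ]), c(0, 777, 0))
    # zero MS1 allocates nothing
    expect_equal(unname(allocateMS1(0, matrix(1:3, 1))[1, ]), c(0, 0, 0))
    # conservation over random records
    set.seed(1)
    reps <- matrix(stats::rexp(200 * 6), 200, 6)
    reps[sample(length(reps), 50)] <- 0
    ms1 <- stats::rexp(200) * 1e6
    al <- allocateMS1(ms1, reps)
    expect_lt(max(abs(rowSums(al) - ms1) / ms1), 1e-12)
    # unallocatable: MS1 > 0 with silent reporters is flagged, not zeroed away
    u <- allocateMS1(c(10, 10), rbind(c(0, 0), c(1, 1)))
    expect_identical(unname(attr(u, "unallocatable")), c(TRUE, FALSE))
})

test_that("ruler formula reproduces the hand-computed worked example", {
    # two histones 3e6 + 1e6; protein X with I = 2e6, MW = 50 kDa
    allocated <- matrix(c(3e6, 1e6, 2e6), 3, 1)
    rowMeta <- data.frame(group_id = c("h1", "h2", "x"),
                          gene_name = c("h1", "h2", "x"),
                          mol_weight_da = c(11000, 14000, 50000),
                          is_histone = c(TRUE, TRUE, FALSE))
    design <- ChannelDesign("126", "pop", 1)
    cne <- estimateCopyNumbers(allocated, rowMeta, design, dnaMassPg = 5.52)
    expected <- (2e6 / 5e4) * (5.52e-12 * 6.02214076e23) / 4e6
    expect_equal(unname(copyNumbers(cne)["x", 1]), expected,
                 tolerance = 1e-12)
    expect_equal(unname(copyNumbers(cne)["x", 1]), 3.3242217e7,
                 tolerance = 1e-7)
})

test_that("histone protein mass per cell equals the DNA mass in every sample", {
    cfg <- smallConfig(nProteins = 600, nHistones = 12, reporterCV = 0.1,
                       absenceFraction = 0.05, seed = 6)
    run <- syntheticCopyNumbers(cfg)
    cne <- run$cne
    rd <- SummarizedExperiment::rowData(cne)
    hm <- colSums(copyNumbers(cne)[rd$is_histone, ] *
                      rd$mol_weight_da[rd$is_histone]) / AVOGADRO * 1e12
    expect_lt(max(abs(hm - dnaMassPg(cne)) / dnaMassPg(cne)), 1e-9)
})

test_that("copy numbers are invariant to per-sample intensity scaling", {
    allocated <- matrix(stats::rexp(40 * 3, 1e-6), 40, 3)
    rowMeta <- data.frame(group_id = sprintf("p%02d", 1:40),
                          gene_name = sprintf("p%02d", 1:40),
                          mol_weight_da = stats::runif(40, 1e4, 1e5),
                          is_histone = c(rep(TRUE, 4), rep(FALSE, 36)))
    design <- ChannelDesign(paste0("ch", 1:3), rep("pop", 3), 1:3)
    base <- estimateCopyNumbers(allocated, rowMeta, design)
    scaled <- sweep(allocated, 2, c(3.7, 0.01, 250), `*`)
    again <- estimateCopyNumbers(scaled, rowMeta, design)
    expect_equal(copyNumbers(base), copyNumbers(again), tolerance = 1e-12)
})

test_that("ruler errors on missing histone signal or negative intensities", {
    allocated <- matrix(c(0, 1e6, 2e6, 2e6), 2, 2)
    rowMeta <- data.frame(group_id = c("h", "x"), gene_name = c("h", "x"),
                          mol_weight_da = c(11000, 50000),
                          is_histone = c(TRUE, FALSE))
    design <- ChannelDesign(c("a", "b"), c("p", "p"), 1:2)
    expect_error(estimateCopyNumbers(allocated, rowMeta, design), "p_1")
    expect_error(estimateCopyNumbers(-allocated, rowMeta, design),
                 "negative")
})

test_that("copy numbers match a brute-force per-protein oracle", {
    set.seed(99)
    n <- 100; k <- 4
    allocated <- matrix(stats::rlnorm(n * k, log(1e6), 1), n, k)
    mw <- stats::runif(n, 8e3, 2e5)
    hist <- seq_len(8)
    rowMeta <- data.frame(group_id = sprintf("p%03d", 1:n),
                          gene_name = sprintf("p%03d", 1:n),
                          mol_weight_da = mw,
                          is_histone = seq_len(n) %in% hist)
    design <- ChannelDesign(paste0("ch", 1:k), rep("pop", k), 1:k)
    cne <- estimateCopyNumbers(allocated, rowMeta, design, dnaMassPg = 5.52)
    oracle <- matrix(NA_real_, n, k)
    for (s in 1:k) {
        histSum <- 0
        for (h in hist) histSum <- histSum + allocated[h, s]
        for (p in 1:n)
            oracle[p, s] <- (allocated[p, s] / mw[p]) *
                (5.52e-12 * 6.02214076e23) / histSum
    }
    expect_lt(max(abs(unname(copyNumbers(cne)) - oracle) / oracle), 1e-12)
})

test_that("protein content applies mass/Avogadro unit conversion", {
    copies <- matrix(1e6, 1, 1, dimnames = list(NULL, "s1"))
    cne <- manualCNE(copies, mw = 50000)
    content <- proteinContent(cne)
    expect_equal(content$samples$content_pg,
                 1e6 * 5e4 / 6.02214076e23 * 1e12, tolerance = 1e-12)
    expect_equal(content$samples$content_pg, 8.302695e-2, tolerance = 1e-6)
    # linearity: doubling copies doubles content
    cne2 <- manualCNE(copies * 2, mw = 50000)
    expect_equal(proteinContent(cne2)$samples$content_pg,
                 2 * content$samples$content_pg)
})

test_that("population aggregation computes the requested statistic", {
    copies <- matrix(c(10, 20, 90), 1, 3,
                     dimnames = list(NULL, c("s1", "s2", "s3")))
    cne <- manualCNE(copies, mw = 50000)
    expect_equal(unname(aggregatePopulation(cne, "median")[1, 1]), 20)
    expect_equal(unname(aggregatePopulation(cne, "mean")[1, 1]), 40)
    expect_error(aggregatePopulation(cne, "mode"))
    single <- manualCNE(matrix(7, 1, 1, dimnames = list(NULL, "s1")),
                        mw = 1000)
    expect_equal(unname(aggregatePopulation(single)[1, 1]), 7)
})
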