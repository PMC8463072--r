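# Small synthetic configs and shortcuts shared across the test files.
# Fixtures are generated in code; nothing is read from disk except what a
# test itself writes to a tempdir.

smallConfig <- function(nProteins = 400, nHistones = 10,
                        populations = c(A = 3L, B = 3L),
                        reporterCV = 0, absenceFraction = 0,
                        nContaminants = 0, nReverse = 0, nLowPeptide = 0,
                        seed = 1L, ...) {
    SyntheticConfig(nProteins = nProteins, nHistones = nHistones,
                    populations = populations, reporterCV = reporterCV,
                    absenceFraction = absenceFraction,
                    nContaminants = nContaminants, nReverse = nReverse,
                    nLowPeptide = nLowPeptide, seed = seed, ...)
}

# simulate -> flag histones -> allocate -> ruler, all in memory
syntheticCopyNumbers <- function(cfg) {
    sim <- simulateProteinGroups(cfg)
    pg <- identifyHistones(sim$table)
    keep <- !pg$is_contaminant & !pg$is_reverse & !pg$only_by_site &
        pg$razor_unique_peptides >= 2
    pg <- pg[keep, , drop = FALSE]
    al <- allocateMS1(pg$ms1_intensity, pg$reporter_intensities)
    cne <- estimateCopyNumbers(al, pg, sim$design, cfg@dnaMassPg)
    list(cne = cne, sim = sim)
}

# the crafted 10-row protein-group table exercising every row filter:
# 2 contaminant, 1 reverse, 1 only-by-site, 2 low-peptide, 4 clean
craftedFilterTable <- function() {
    n <- 10
    pg <- S4Vectors::DataFrame(
        group_id = sprintf("g%02d", 1:n),
        protein_ids = sprintf("p%02d", 1:n),
        gene_name = sprintf("gene%02d", 1:n),
        mol_weight_da = rep(50000, n),
        ms1_intensity = rep(1e6, n),
        razor_unique_peptides = c(5L, 5L, 5L, 5L, 1L, 1L, 5L, 5L, 5L, 5L),
        is_contaminant = c(TRUE, TRUE, rep(FALSE, 8)),
        is_reverse = c(FALSE, FALSE, TRUE, rep(FALSE, 7)),
        only_by_site = c(rep(FALSE, 3), TRUE, rep(FALSE, 6)),
        is_histone = rep(FALSE, n))
    pg$reporter_intensities <- matrix(1, n, 4,
                                      dimnames = list(NULL, paste0("ch", 1:4)))
    rownames(pg) <- pg$group_id
    pg
}

# write a minimal MaxQuant-dialect TSV by hand (independent of writeFixture)
writeCraftedMaxQuant <- function(path, nChannels = 2) {
    header <- c("Protein IDs", "Gene names", "Mol. weight [kDa]",
                "Razor + unique peptides", "Intensity",
                paste("Reporter intensity corrected", seq_len(nChannels)),
                "Only identified by site", "Reverse",
                "Potential contaminant", "id")
    rows <- list(
        c("P1", "Gzma", "50", "5", "1000", "600", "400", "", "", "", "r1"),
        c("P2", "Hist1h1b", "21.5", "8", "2000", "1200", "800", "", "", "", "r2"),
        c("P3", "", "30", "1", "500", "", "500", "", "", "+", "r3"))
    lines <- c(paste(header, collapse = "\t"),
               vapply(rows, paste, character(1), collapse = "\t"))
    writeLines(lines, path)
    path
}

twoChannelDesign <- function() ChannelDesign(c("126", "127N"),
                                             c("popA", "popA"), c(1, 2))
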