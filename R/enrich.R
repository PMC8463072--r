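#' Read a GMT gene-set collection
#'
#' Tab-delimited, one set per line: name, description, then member
#' identifiers.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors; descriptions in attribute
#'   \code{"description"}.
#' @export
readGmt <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) < 3
    if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1])
    nm <- vapply(parts, `[[`, character(1), 1)
    if (anyDuplicated(nm)) stop("duplicate set names in GMT")
    sets <- lapply(parts, function(x) unique(x[-(1:2)][nzchar(x[-(1:2)])]))
    names(sets) <- nm
    attr(sets, "description") <- stats::setNames(
        vapply(parts, `[[`, character(1), 2), nm)
    sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set descriptions.
#' @export
writeGmt <- function(sets, path, description = NULL) {
    if (is.null(description)) description <- rep("na", length(sets))
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Gene-set overrepresentation analysis
#'
#' One-sided hypergeometric test of each gene set against a hit list within
#' a fixed background universe: with N = |background|, K = |set within
#' background|, n = |hits| and k = |overlap|, the p-value is the upper tail
#' P(X >= k). Multiple testing across sets is controlled with
#' Benjamini-Hochberg FDR. Sets are intersected with the background before
#' testing, and hits outside the background are dropped with a warning.
#'
#' @param hits character vector of hit identifiers.
#' @param background character vector: the identifier universe (for the
#'   two-population design, all proteins identified in either population).
#' @param collection named list of gene sets (see \code{\link{readGmt}}).
#' @param minSetSize,maxSetSize size window (after background intersection)
#'   for a set to be tested (defaults 2 and Inf).
#' @return data.frame sorted by p with one row per tested set: set name,
#'   set size in background, background size, number of hits, overlap, fold
#'   enrichment, p, fdr, and the overlapping identifiers
#'   (semicolon-joined).
#' @export
overrepresentation <- function(hits, background, collection,
                               minSetSize = 2, maxSetSize = Inf) {
    background <- unique(background)
    hits <- unique(hits)
    if (length(background) == 0) stop("empty background")
    if (length(hits) == 0) stop("empty hit list")
    outside <- setdiff(hits, background)
    if (length(outside)) {
        warning(length(outside), " hit(s) outside the background dropped")
        hits <- intersect(hits, background)
        if (length(hits) == 0) stop("no hits remain within the background")
    }
    sets <- lapply(collection, intersect, background)
    size <- vapply(sets, length, integer(1))
    keep <- size >= minSetSize & size <= maxSetSize
    if (!any(keep)) {
        warning("no gene set within the size window; empty result")
        return(data.frame(set = character(), set_size = integer(),
                          background_size = integer(), n_hits = integer(),
                          overlap = integer(), fold_enrichment = numeric(),
                          p = numeric(), fdr = numeric(),
                          overlap_ids = character()))
    }
    sets <- sets[keep]
    N <- length(background)
    n <- length(hits)
    rows <- lapply(names(sets), function(nm) {
        K <- length(sets[[nm]])
        ov <- intersect(sets[[nm]], hits)
        k <- length(ov)
        p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(set = nm, set_size = K, background_size = N, n_hits = n,
                   overlap = k,
                   fold_enrichment = (k / n) / (K / N),
                   p = p, fdr = NA_real_,
                   overlap_ids = paste(sort(ov), collapse = ";"),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$fdr <- stats::p.adjust(out$p, method = "BH")
    out <- out[order(out$p, out$set), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Exhaustion-signature overrepresentation
#'
#' Tests a contrast's up- and down-regulated candidate sets against a
#' user-supplied exhaustion signature collection (e.g. literature-derived
#' "up in exhaustion" / "down in exhaustion" sets in GMT format).
#'
#' @param up,down candidate identifier vectors from
#'   \code{\link{selectEnrichmentCandidates}} (optionally unioned with
#'   exclusive proteins).
#' @param collection exhaustion gene-set collection (>= 1 set).
#' @param background identifier universe.
#' @return data.frame as \code{\link{overrepresentation}} with an extra
#'   \code{hit_list} column ("up"/"down"); empty hit lists contribute no
#'   rows (with a warning).
#' @export
exhaustionEnrichment <- function(up, down, collection, background) {
    if (length(collection) == 0)
        stop("exhaustion collection has no sets")
    run <- function(h, label) {
        if (length(h) == 0) {
            warning("empty ", label, " candidate set; skipped")
            return(NULL)
        }
        r <- overrepresentation(h, background, collection, minSetSize = 1)
        if (nrow(r)) r$hit_list <- label
        r
    }
    out <- rbind(run(up, "up"), run(down, "down"))
    if (is.null(out)) {
        warning("no candidates on either side; empty result")
        out <- data.frame()
    }
    out
}

#' Overlap between two protein signatures
#'
#' Exact partition of two identifier sets (e.g. proteins up in exhaustion
#' vs proteins up in a tissue-resident population), as used in Venn-style
#' comparisons.
#'
#' @param setA,setB character vectors.
#' @return list with \code{shared}, \code{a_only}, \code{b_only} (sorted
#'   identifier vectors) and \code{counts} (named integer vector; counts sum
#'   to |A union B|).
#' @export
signatureOverlap <- function(setA, setB) {
    setA <- unique(setA); setB <- unique(setB)
    shared <- sort(intersect(setA, setB))
    aOnly <- sort(setdiff(setA, setB))
    bOnly <- sort(setdiff(setB, setA))
    list(shared = shared, a_only = aOnly, b_only = bOnly,
         counts = c(shared = length(shared), a_only = length(aOnly),
                    b_only = length(bOnly)))
}
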