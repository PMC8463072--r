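#' Default histone gene symbols
#'
#' Mouse core and linker histone gene symbols shipped with the package
#' (old \code{Hist*} and current nomenclature). Used by
#' \code{\link{identifyHistones}} when no custom list is supplied.
#'
#' @param path optional path to a custom one-symbol-per-line file
#'   (\code{#} comments allowed), overriding the shipped list.
#' @return character vector of gene symbols.
#' @export
defaultHistoneGenes <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "mouse_histone_genes.txt",
                            package = "tmtRuler", mustWork = TRUE)
    x <- readLines(path, warn = FALSE)
    x <- trimws(x)
    x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a MaxQuant-style protein-group table
#'
#' Parses a \code{proteinGroups.txt}-dialect TSV into a standardized
#' \code{DataFrame} with one row per protein group. \code{Mol. weight [kDa]}
#' is converted to Daltons, \code{"+"} marks become logical flags, and
#' missing reporter cells become 0. Reporter columns are resolved as
#' \code{Reporter intensity corrected <k>} when present, otherwise
#' \code{Reporter intensity <k>}, with k following channel order in the
#' design; the choice is reported via a message.
#'
#' @param path path to the tab-delimited protein-group table.
#' @param design a \linkS4class{ChannelDesign}; reporter columns must be
#'   resolvable for every channel.
#' @param peptideColumn which peptide-count column feeds the low-peptide
#'   filter; MaxQuant's \code{"Razor + unique peptides"} (default) or
#'   \code{"Unique peptides"}.
#' @return \code{DataFrame} with columns \code{group_id},
#'   \code{protein_ids}, \code{gene_name}, \code{mol_weight_da},
#'   \code{ms1_intensity}, \code{razor_unique_peptides},
#'   \code{is_contaminant}, \code{is_reverse}, \code{only_by_site},
#'   \code{is_histone} (initialised \code{FALSE}) and a matrix column
#'   \code{reporter_intensities} (one column per channel).
#' @export
readProteinGroups <- function(path, design,
                              peptideColumn = c("Razor + unique peptides",
                                                "Unique peptides")) {
    peptideColumn <- match.arg(peptideColumn)
    raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE, quote = "")
    need <- c("Protein IDs", "Gene names", "Mol. weight [kDa]", "Intensity",
              peptideColumn)
    miss <- setdiff(need, colnames(raw))
    if (length(miss))
        stop("protein-group table missing mandatory column(s): ",
             paste(miss, collapse = ", "))

    nch <- nrow(design@channels)
    corrected <- paste("Reporter intensity corrected", seq_len(nch))
    plain <- paste("Reporter intensity", seq_len(nch))
    if (all(corrected %in% colnames(raw))) {
        repCols <- corrected
        message("using corrected reporter intensity columns")
    } else if (all(plain %in% colnames(raw))) {
        repCols <- plain
        message("using uncorrected reporter intensity columns")
    } else {
        stop("cannot resolve reporter intensity columns for ", nch,
             " channels")
    }

    num <- function(col) {
        ch <- as.character(raw[[col]])
        blank <- is.na(ch) | trimws(ch) %in% c("", "NA", "NaN")
        out <- suppressWarnings(as.numeric(ch))
        bad <- which(is.na(out) & !blank)
        if (length(bad))
            stop("non-numeric value in column '", col, "', row ", bad[1])
        out[blank] <- 0
        out
    }
    flag <- function(col) {
        if (!col %in% colnames(raw)) return(rep(FALSE, nrow(raw)))
        v <- as.character(raw[[col]])
        v[is.na(v)] <- ""
        trimws(v) == "+"
    }

    rep_mat <- do.call(cbind, lapply(repCols, num))
    rep_mat[is.na(rep_mat)] <- 0
    colnames(rep_mat) <- design@channels$channel_label

    gid <- if ("id" %in% colnames(raw)) as.character(raw[["id"]]) else
        as.character(raw[["Protein IDs"]])
    if (anyDuplicated(gid))
        stop("duplicate protein-group ids in table: ",
             gid[duplicated(gid)][1])

    pg <- DataFrame(
        group_id = gid,
        protein_ids = as.character(raw[["Protein IDs"]]),
        gene_name = as.character(raw[["Gene names"]]),
        mol_weight_da = num("Mol. weight [kDa]") * 1000,
        ms1_intensity = num("Intensity"),
        razor_unique_peptides = as.integer(num(peptideColumn)),
        is_contaminant = flag("Potential contaminant"),
        is_reverse = flag("Reverse"),
        only_by_site = flag("Only identified by site"),
        is_histone = rep(FALSE, nrow(raw)))
    pg$reporter_intensities <- rep_mat
    rownames(pg) <- gid
    metadata(pg)$reporter_columns <- repCols[1]
    metadata(pg)$peptide_column <- peptideColumn
    pg
}

#' Apply the standard protein-group row filters
#'
#' Removes rows flagged as contaminant, reverse (decoy) or
#' only-identified-by-site, and rows quantified with fewer than
#' \code{minPeptides} razor + unique peptides. A row is counted once per
#' failing reason in the report, so reason counts can exceed the number of
#' unique rows removed.
#'
#' @param pg \code{DataFrame} from \code{\link{readProteinGroups}}.
#' @param minPeptides minimum razor + unique peptides to retain (default 2:
#'   rows with fewer than two are dropped).
#' @return list with \code{retained} (filtered \code{DataFrame}) and
#'   \code{report} (data.frame of per-reason removal counts plus unique rows
#'   removed and retained).
#' @export
filterProteinGroups <- function(pg, minPeptides = 2L) {
    contaminant <- pg$is_contaminant
    reverse <- pg$is_reverse
    site <- pg$only_by_site
    lowpep <- pg$razor_unique_peptides < minPeptides
    drop <- contaminant | reverse | site | lowpep
    report <- data.frame(
        reason = c("contaminant", "reverse", "only_by_site", "low_peptides",
                   "unique_rows_removed", "retained"),
        count = c(sum(contaminant), sum(reverse), sum(site), sum(lowpep),
                  sum(drop), sum(!drop)))
    list(retained = pg[!drop, , drop = FALSE], report = report)
}

#' Flag histone protein groups by gene symbol
#'
#' Sets \code{is_histone} for rows whose gene name matches the supplied
#' histone symbol list (case-insensitive exact match on any of the
#' semicolon-separated MaxQuant gene names).
#'
#' @param pg protein-group \code{DataFrame}.
#' @param histoneGenes character vector of histone gene symbols; defaults to
#'   the shipped mouse list.
#' @return \code{pg} with \code{is_histone} updated.
#' @export
identifyHistones <- function(pg, histoneGenes = defaultHistoneGenes()) {
    if (length(histoneGenes) == 0) stop("histone gene list is empty")
    hs <- tolower(histoneGenes)
    hit <- vapply(strsplit(tolower(pg$gene_name), ";", fixed = TRUE),
                  function(g) any(trimws(g) %in% hs), logical(1))
    hit[is.na(hit)] <- FALSE
    if (!any(hit))
        stop("no histone gene matched: ruler undefined")
    pg$is_histone <- hit
    pg
}

#' Replicate quality control on per-cell protein content
#'
#' Within each population, a replicate is flagged when its protein content
#' deviates from the median of the other replicates by at least
#' \code{threshold} (relative). Populations with fewer than 3 replicates are
#' skipped with a warning, since the leave-one-out median is unstable there.
#'
#' @param content named numeric vector of per-sample protein content
#'   (pg/cell).
#' @param population character vector (same length) of population labels.
#' @param threshold relative deviation at or above which a replicate is
#'   flagged (default 0.15).
#' @return data.frame with columns sample, population, content, deviation,
#'   flagged.
#' @export
qcReplicates <- function(content, population, threshold = 0.15) {
    stopifnot(length(content) == length(population), threshold > 0)
    samples <- names(content)
    if (is.null(samples)) samples <- as.character(seq_along(content))
    out <- data.frame(sample = samples, population = population,
                      content = as.numeric(content), deviation = NA_real_,
                      flagged = FALSE, stringsAsFactors = FALSE)
    for (pop in unique(population)) {
        idx <- which(population == pop)
        if (length(idx) < 3) {
            warning("population ", pop, " has fewer than 3 replicates; ",
                    "replicate QC skipped")
            next
        }
        for (i in idx) {
            med <- stats::median(content[setdiff(idx, i)])
            dev <- abs(content[i] - med) / med
            out$deviation[i] <- dev
            out$flagged[i] <- dev >= threshold
        }
    }
    out
}
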