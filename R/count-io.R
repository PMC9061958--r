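#' Construct a count table
#'
#' @param counts numeric matrix (or coercible) of nonnegative integer
#'   counts, groups in rows, categories in columns.
#' @param groupLabels,categoryLabels optional character vectors; taken
#'   from `dimnames(counts)` when absent, else defaulting to
#'   `group1..h` / `cat1..k`.
#' @param metadata optional list of annotations.
#' @return a validated [CountTable-class].
#' @examples
#' countTable(rbind(g1 = c(5, 5), g2 = c(7, 3)),
#'            categoryLabels = c("yes", "no"))
#' @export
countTable <- function(counts, groupLabels = NULL, categoryLabels = NULL,
                       metadata = list()) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    if (is.null(groupLabels))
        groupLabels <- rownames(counts)
    if (is.null(groupLabels))
        groupLabels <- paste0("group", seq_len(nrow(counts)))
    if (is.null(categoryLabels))
        categoryLabels <- colnames(counts)
    if (is.null(categoryLabels))
        categoryLabels <- paste0("cat", seq_len(ncol(counts)))
    dimnames(counts) <- list(as.character(groupLabels),
                             as.character(categoryLabels))
    new("CountTable", counts = counts, metadata = metadata)
}

#' Pair lower/upper tables into an interval-valued count table
#'
#' @param lower,upper [CountTable-class] objects of identical shape and
#'   labels with `counts(lower) <= counts(upper)` elementwise. Passing
#'   one table for both encodes classical (degenerate-interval) data.
#' @return a [NeutrosophicCountTable-class].
#' @export
neutrosophicCountTable <- function(lower, upper = lower) {
    if (!is(lower, "CountTable") || !is(upper, "CountTable"))
        stop("'lower' and 'upper' must be CountTable objects")
    new("NeutrosophicCountTable", lower = lower, upper = upper)
}

#' @rdname accessors
setMethod("counts", "CountTable", function(x) x@counts)
#' @rdname accessors
setMethod("groupLabels", "CountTable", function(x) rownames(x@counts))
#' @rdname accessors
setMethod("categoryLabels", "CountTable", function(x) colnames(x@counts))
#' @rdname accessors
setMethod("groupTotals", "CountTable", function(x) rowSums(x@counts))
#' @rdname accessors
setMethod("excludedCounts", "CountTable", function(x) {
    ex <- x@metadata$excluded
    if (is.null(ex)) {
        ex <- rep(0, nrow(x@counts))
        names(ex) <- rownames(x@counts)
    }
    ex
})
#' @rdname accessors
setMethod("lowerTable", "NeutrosophicCountTable", function(x) x@lower)
#' @rdname accessors
setMethod("upperTable", "NeutrosophicCountTable", function(x) x@upper)

setMethod("dim", "CountTable", function(x) dim(x@counts))

setMethod("show", "CountTable", function(object) {
    cat(sprintf("CountTable: %d group(s) x %d categories\n",
                nrow(object@counts), ncol(object@counts)))
    print(cbind(object@counts, Total = rowSums(object@counts)))
    ex <- object@metadata$excluded
    if (!is.null(ex) && any(ex > 0))
        cat("excluded (non-category) characters per group:",
            paste(sprintf("%s=%d", names(ex), ex), collapse = ", "), "\n")
})

setMethod("show", "NeutrosophicCountTable", function(object) {
    cat("NeutrosophicCountTable\n-- lower endpoint --\n")
    show(object@lower)
    cat("-- upper endpoint --\n")
    show(object@upper)
})

.sepFor <- function(dialect) {
    dialect <- match.arg(dialect, c("csv", "tsv"))
    if (dialect == "csv") "," else "\t"
}

#' Read a count table from CSV or TSV
#'
#' The expected layout is a header row of category labels (the first
#' field, naming the group column, is ignored) followed by one row per
#' group whose first field is the group label. Thousands separators
#' (commas inside quoted numeric cells) are stripped, so tables printed
#' in the style `38,514` can be used verbatim. Parse failures report
#' the offending cell by group and category.
#'
#' @param path file path.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return a [CountTable-class].
#' @seealso [writeCountTable()], [brca2CountTable()]
#' @examples
#' path <- system.file("extdata", "brca2_nucleotide_counts.csv",
#'                     package = "neutroChisq")
#' groupTotals(readCountTable(path))   # 127079 127173
#' @export
readCountTable <- function(path, dialect = c("csv", "tsv")) {
    sep <- .sepFor(dialect)
    if (!file.exists(path))
        stop("count table file not found: ", path)
    raw <- utils::read.table(path, sep = sep, header = TRUE,
                             row.names = NULL, colClasses = "character",
                             check.names = FALSE, quote = "\"",
                             strip.white = TRUE, comment.char = "")
    if (ncol(raw) < 3L)
        stop("count table must have at least 2 category columns")
    groups <- raw[[1L]]
    cats <- colnames(raw)[-1L]
    m <- matrix(NA_real_, nrow(raw), length(cats),
                dimnames = list(groups, cats))
    for (j in seq_along(cats)) {
        cell <- gsub(",", "", raw[[j + 1L]], fixed = TRUE)
        val <- suppressWarnings(as.numeric(cell))
        bad <- is.na(val) | val < 0 | abs(val - round(val)) > 1e-8
        if (any(bad))
            stop(sprintf(
                "invalid count '%s' at group '%s', category '%s' (%s)",
                raw[[j + 1L]][which(bad)[1L]], groups[which(bad)[1L]],
                cats[j], "cells must be nonnegative integers"))
        m[, j] <- val
    }
    countTable(m)
}

#' Write a count table to CSV or TSV
#'
#' Inverse of [readCountTable()]: the written file round-trips to an
#' identical table.
#'
#' @param x a [CountTable-class].
#' @param path destination file path.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return invisibly, `path`.
#' @export
writeCountTable <- function(x, path, dialect = c("csv", "tsv")) {
    stopifnot(is(x, "CountTable"))
    sep <- .sepFor(dialect)
    m <- x@counts
    lines <- c(paste(c("group", colnames(m)), collapse = sep),
               vapply(seq_len(nrow(m)), function(j)
                   paste(c(rownames(m)[j], format(m[j, ], scientific = FALSE,
                                                  trim = TRUE)),
                         collapse = sep), character(1)))
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) stop("cannot write count table to '",
                                            path, "': ", conditionMessage(e)))
    invisible(path)
}

#' Nucleotide composition of FASTA sequences
#'
#' Reads a (possibly line-wrapped, multi-record) FASTA file and tallies
#' the nucleotides A, C, G, T per record or pooled over all records.
#' Sequences are uppercased first, so soft-masked lowercase bases count
#' normally. Characters outside {A, C, G, T} — ambiguity codes such as
#' N or R, gaps, anything else — are excluded from the counts, and the
#' number excluded per group is stored in the table metadata
#' (see [excludedCounts()]) and reported as a message.
#'
#' @param path FASTA file path.
#' @param grouping `"per-record"` (default; one table row per record,
#'   labelled by the record id) or `"pooled"` (a single row).
#' @return a [CountTable-class] with categories A, C, G, T.
#' @seealso [generateSyntheticFasta()]
#' @export
countNucleotides <- function(path, grouping = c("per-record", "pooled")) {
    grouping <- match.arg(grouping)
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    seqs <- Biostrings::readBStringSet(path)
    if (length(seqs) == 0L)
        stop("FASTA file contains no records: ", path)
    seqs <- Biostrings::BStringSet(toupper(as.character(seqs)))
    m <- Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T"))
    ids <- sub("\\s.*$", "", names(seqs))
    excluded <- Biostrings::width(seqs) - rowSums(m)
    if (grouping == "pooled") {
        m <- matrix(colSums(m), nrow = 1,
                    dimnames = list("pooled", colnames(m)))
        excluded <- sum(excluded)
        names(excluded) <- "pooled"
    } else {
        rownames(m) <- ids
        names(excluded) <- ids
    }
    if (any(rowSums(m) == 0))
        stop("record(s) with no countable A/C/G/T bases: ",
             paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
    if (any(excluded > 0))
        message(sum(excluded), " non-ACGT character(s) excluded from counts")
    countTable(m, metadata = list(excluded = excluded))
}

#' The BRCA2 nucleotide count table
#'
#' The canonical 2 x 4 worked-example data: nucleotide (A, C, G, T)
#' counts for the human tumour-suppressor gene BRCA2 in two counting
#' groups (totals 127079 and 127173). Used throughout the examples and
#' shipped as `extdata/brca2_nucleotide_counts.csv`.
#'
#' @return a [CountTable-class].
#' @examples
#' brca2CountTable()
#' @export
brca2CountTable <- function() {
    countTable(rbind(
        `Count Group 1` = c(38514, 24631, 25685, 38249),
        `Count Group 2` = c(38550, 24635, 25700, 38288)),
        categoryLabels = c("A", "C", "G", "T"))
}
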