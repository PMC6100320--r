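#' Read an expression matrix and its design table
#'
#' Reads a delimited genes-by-samples intensity table (first column gene
#' identifiers, header sample identifiers; tab- or comma-separated by file
#' extension) and a two-column design table mapping each sample to a group,
#' validating both into a \linkS4class{QPExpression}. Gene rows containing
#' missing values are dropped with a message; duplicated identifiers,
#' negative intensities and sample/design mismatches are rejected.
#'
#' @param path expression table path (.tsv/.txt tab-separated, .csv comma).
#' @param designPath design table path: two columns, sample id and group.
#' @return a \linkS4class{QPExpression}.
#' @seealso [QPExpression()]
#' @export
readExpression <- function(path, designPath) {
    tab <- utils::read.delim(path, sep = .sepFor(path), header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
    gid <- as.character(tab[[1L]])
    if (anyDuplicated(gid))
        stop("duplicated gene identifier(s): ",
             paste(unique(gid[duplicated(gid)]), collapse = ", "))
    m <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- gid
    if (any(m < 0, na.rm = TRUE))
        stop("negative intensity value(s) found; intensities must be ",
             "nonnegative linear-scale values")
    des <- utils::read.delim(designPath, sep = .sepFor(designPath),
                             header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(des) < 2L)
        stop("design table needs two columns (sample, group)")
    QPExpression(m, stats::setNames(as.character(des[[2L]]),
                                    as.character(des[[1L]])))
}

.sepFor <- function(path)
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a GMT gene set file
#'
#' Standard GMT dialect: one pathway per line, tab-separated fields
#' \code{set id}, \code{description}, then member gene ids. Lines with fewer
#' than three fields, empty member lists and duplicated pathway ids are
#' rejected.
#'
#' @param path GMT file path.
#' @param universe optional explicit gene universe; defaults to the union of
#'   all members.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path, universe = NULL) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty GMT file: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 3L)
    if (length(bad))
        stop("GMT line ", bad[1L], " has fewer than 3 tab-separated fields")
    ids <- vapply(fields, `[[`, character(1), 1L)
    if (anyDuplicated(ids))
        stop("duplicated pathway id(s) in GMT: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    desc <- vapply(fields, `[[`, character(1), 2L)
    members <- lapply(fields, function(f) {
        mm <- f[-(1:2)]
        mm[nzchar(mm)]
    })
    empty <- which(lengths(members) == 0L)
    if (length(empty))
        stop("GMT line ", empty[1L], " (set '", ids[empty[1L]],
             "') has an empty member list")
    names(members) <- ids
    GeneSetCollection(members, stats::setNames(desc, ids), universe)
}

#' Write a gene set collection as GMT
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @param path output path.
#' @export
writeGmt <- function(x, path) {
    stopifnot(is(x, "GeneSetCollection"))
    desc <- x@descriptions
    desc[!nzchar(desc)] <- "na"
    lines <- vapply(names(x@sets), function(id)
        paste(c(id, desc[[id]], x@sets[[id]]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Write a result table as TSV
#'
#' Writes any nonempty result table (data.frame, or an S4 result with an
#' \code{as.data.frame} method such as \linkS4class{DivergenceTable} /
#' \linkS4class{DEResult}) as a tab-separated file with a header, numeric
#' columns formatted to 6 significant digits, rows sorted by the first
#' column for deterministic output.
#'
#' @param x the table to write.
#' @param path output path.
#' @return invisibly, the path.
#' @seealso [readResultTable()] for the matching reader.
#' @export
writeResultTable <- function(x, path) {
    if (is(x, "DEResult")) x <- deTable(x)
    if (is(x, "DivergenceTable")) x <- divergence(x)
    x <- as.data.frame(x)
    if (nrow(x) == 0L) stop("refusing to write an empty table")
    x <- x[order(x[[1L]]), , drop = FALSE]
    num <- vapply(x, is.numeric, logical(1))
    x[num] <- lapply(x[num], function(v) {
        out <- ifelse(v == floor(v) & abs(v) < 1e15 & is.finite(v),
                      format(v, scientific = FALSE, trim = TRUE),
                      format(signif(v, 6), trim = TRUE))
        out[is.na(v)] <- NA
        out
    })
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read back a TSV result table
#'
#' @param path file written by [writeResultTable()].
#' @return a data.frame.
#' @export
readResultTable <- function(path)
    utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)

#' Write a profile matrix as TSV (gene rows, pathway columns)
#'
#' @param x a \linkS4class{PathwayProfile}.
#' @param path output path.
#' @export
writeProfile <- function(x, path) {
    stopifnot(is(x, "PathwayProfile"))
    v <- profileValues(x)
    df <- data.frame(gene = rownames(v), signif(v, 6),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df[order(df$gene), , drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
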