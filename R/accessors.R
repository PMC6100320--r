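#' Construct a QPExpression from a matrix and a design
#'
#' @param values numeric matrix, genes x samples, linear-scale nonnegative
#'   intensities, with gene rownames and sample colnames. Gene rows
#'   containing missing values are dropped with a message.
#' @param design either a named character vector (sample id -> group label)
#'   or a data.frame with columns \code{sample} and \code{group}.
#' @return a validated \linkS4class{QPExpression}.
#' @examples
#' m <- matrix(c(8, 8, 4, 4, 2, 8, 4, 4), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
#' expr <- QPExpression(m, c(s1 = "QJ", s2 = "QJ", s3 = "Model", s4 = "Model"))
#' groups(expr)
#' @export
QPExpression <- function(values, design) {
    values <- as.matrix(values)
    if (is.data.frame(design)) {
        if (!all(c("sample", "group") %in% colnames(design)))
            stop("design data.frame needs columns 'sample' and 'group'")
        design <- stats::setNames(as.character(design$group),
                                  as.character(design$sample))
    }
    if (anyDuplicated(names(design)))
        stop("duplicated sample identifier(s) in design: ",
             paste(unique(names(design)[duplicated(names(design))]),
                   collapse = ", "))
    if (is.null(colnames(values)))
        stop("sample identifiers (column names) are required")
    missing_in_design <- setdiff(colnames(values), names(design))
    if (length(missing_in_design))
        stop("sample(s) absent from design: ",
             paste(missing_in_design, collapse = ", "))
    missing_in_matrix <- setdiff(names(design), colnames(values))
    if (length(missing_in_matrix))
        stop("design sample(s) absent from matrix: ",
             paste(missing_in_matrix, collapse = ", "))
    nas <- rowSums(is.na(values)) > 0
    if (any(nas)) {
        message("dropping ", sum(nas), " gene(s) with missing values")
        values <- values[!nas, , drop = FALSE]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values),
        colData = S4Vectors::DataFrame(
            group = unname(design[colnames(values)]),
            row.names = colnames(values)))
    new("QPExpression", se)
}

#' @rdname QPExpression
#' @export
setMethod("groups", "QPExpression", function(x)
    stats::setNames(as.character(SummarizedExperiment::colData(x)$group),
                    colnames(x)))

#' @rdname QPExpression
#' @export
exprs <- function(x) SummarizedExperiment::assay(x, "exprs")

setMethod("show", "QPExpression", function(object) {
    grp <- groups(object)
    cat("QPExpression:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("groups:", paste(sprintf("%s (n=%d)", names(table(grp)), table(grp)),
                         collapse = ", "), "\n")
})

#' Construct a gene set collection
#'
#' @param sets named list of character vectors mapping pathway ids to member
#'   gene ids.
#' @param descriptions optional named character vector of descriptions.
#' @param universe optional explicit gene universe; defaults to the union of
#'   all members.
#' @return a validated \linkS4class{GeneSetCollection}.
#' @examples
#' gsc <- GeneSetCollection(list(foxo = c("Igf1", "Prkab2"),
#'                               ecm = c("Tgfb2", "Tgfb3")))
#' universe(gsc)
#' @export
GeneSetCollection <- function(sets, descriptions = NULL, universe = NULL) {
    sets <- lapply(sets, function(s) unique(as.character(s)))
    if (is.null(descriptions))
        descriptions <- stats::setNames(rep("", length(sets)), names(sets))
    if (is.null(universe))
        universe <- sort(unique(unlist(sets, use.names = FALSE)))
    new("GeneSetCollection", sets = sets,
        descriptions = descriptions[names(sets)],
        universe = as.character(universe))
}

#' @rdname GeneSetCollection
#' @param x a \linkS4class{GeneSetCollection}
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection
#' @export
setMethod("setIds", "GeneSetCollection", function(x) names(x@sets))

#' @rdname GeneSetCollection
#' @export
setMethod("universe", "GeneSetCollection", function(x) x@universe)

#' @rdname GeneSetCollection
#' @param universe character vector of gene ids to restrict members to.
#' @export
setMethod("restrictToUniverse", "GeneSetCollection", function(x, universe) {
    sets <- lapply(x@sets, intersect, y = universe)
    keep <- lengths(sets) > 0L
    if (!all(keep))
        message("dropping ", sum(!keep),
                " pathway(s) disjoint from the universe: ",
                paste(names(sets)[!keep], collapse = ", "))
    GeneSetCollection(sets[keep], x@descriptions[keep], universe)
})

setMethod("show", "GeneSetCollection", function(object) {
    cat("GeneSetCollection:", length(object@sets), "pathways,",
        length(object@universe), "genes in universe\n")
    cat("set sizes:", paste(range(lengths(object@sets)), collapse = "-"),
        "\n")
})

#' @rdname DEResult
#' @param x a \linkS4class{DEResult}
#' @export
setMethod("deTable", "DEResult", function(x) x@results)

#' @rdname DEResult
#' @export
setMethod("degs", "DEResult", function(x)
    x@results$gene[x@results$significant])

#' @rdname DEResult
#' @export
setMethod("contrast", "DEResult", function(x)
    c(treatment = x@treatment, reference = x@reference))

setMethod("show", "DEResult", function(object) {
    r <- object@results
    cat(sprintf("DEResult: %s vs %s | %d genes, %d significant (%d up, %d down)\n",
                object@treatment, object@reference, nrow(r),
                sum(r$significant), sum(r$direction == "up"),
                sum(r$direction == "down")))
    cat(sprintf("thresholds: p < %g, FC > %g or < %g\n", object@alpha,
                object@fcHigh, object@fcLow))
})

#' @rdname PathwayProfile
#' @param x a \linkS4class{PathwayProfile}
#' @export
setMethod("profileValues", "PathwayProfile", function(x) x@values)

#' @rdname PathwayProfile
#' @export
setMethod("membership", "PathwayProfile", function(x) x@membership)

setMethod("show", "PathwayProfile", function(object) {
    cat(sprintf("PathwayProfile [%s]: %d DEGs x %d pathways, %d member cells\n",
                object@treatment, nrow(object@values), ncol(object@values),
                sum(object@membership)))
})

#' @rdname MCIAResult
#' @param x,object an \linkS4class{MCIAResult}
#' @export
setMethod("eigenvalues", "MCIAResult", function(x) x@eigenvalues)

#' @rdname MCIAResult
#' @export
setMethod("syntheticScores", "MCIAResult", function(x) x@synthetic)

#' @rdname MCIAResult
#' @export
setMethod("tableScores", "MCIAResult", function(x) x@tableScores)

setMethod("show", "MCIAResult", function(object) {
    cat(sprintf("MCIAResult: %d tables (%s), %d pathways, %d axes\n",
                length(object@tableNames),
                paste(object@tableNames, collapse = ", "),
                length(object@pathwayIds), length(object@eigenvalues)))
    cat("eigenvalues:", paste(signif(object@eigenvalues, 4), collapse = ", "),
        "\n")
    cat("weighting:", object@weighting, "| preprocessing:",
        object@preprocessing, "\n")
})

#' @rdname DivergenceTable
#' @param x,object a \linkS4class{DivergenceTable}
#' @export
setMethod("divergence", "DivergenceTable", function(x) x@scores)

#' @rdname DivergenceTable
#' @export
setMethod("as.data.frame", "DivergenceTable",
          function(x, ...) x@scores)

setMethod("show", "DivergenceTable", function(object) {
    s <- object@scores
    cat(sprintf("DivergenceTable: %d pathways, %d pair(s), F = %d axes\n",
                length(unique(s$pathway)),
                nrow(unique(s[, c("table1", "table2")])), object@nAxes))
    if (object@B > 0)
        cat(sprintf("permutations: B = %d, alpha = %g, %d (pathway, pair) called different\n",
                    object@B, object@alpha, sum(s$different, na.rm = TRUE)))
    else cat("scores only (no permutation test)\n")
})

setMethod("show", "SimulationScenario", function(object) {
    cat(sprintf("SimulationScenario: %d genes, %d/group, groups: %s + %s\n",
                object@nGenes, object@nPerGroup, object@reference,
                paste(object@treatments, collapse = ", ")))
    cat(sprintf("%d pathways of size %d (overlap %g), noise sd %g log2\n",
                object@nPathways, object@setSize, object@overlap,
                object@noiseSd))
})
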