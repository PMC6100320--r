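#' Build the quantitative pathway profile for one contrast
#'
#' Constructs the genes-by-pathways table that quantifies pathways into
#' digital vectors: rows are the contrast's significant DEGs, columns the
#' selected pathways, and each cell holds the gene's linear fold change when
#' the gene is a member of the pathway and the neutral value 1 otherwise.
#' Because rows are DEGs, member cells are always > 2 or < 0.5 (under the
#' default thresholds); genes belonging to none of the selected pathways are
#' retained as all-1 rows unless \code{dropNonMembers = TRUE}.
#'
#' @param de a \linkS4class{DEResult} with called DEGs.
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param pathways pathway ids to use as columns (must exist in
#'   \code{sets}); typically the output of [commonPathways()].
#' @param dropNonMembers drop DEGs that belong to no selected pathway
#'   (default FALSE).
#' @param allowEmpty tolerate selected pathways with no DEG member in this
#'   contrast (their column is all-neutral). Needed when a common pathway
#'   set taken as a union across contrasts is imposed; default FALSE.
#' @return a \linkS4class{PathwayProfile}.
#' @export
buildProfile <- function(de, sets, pathways = setIds(sets),
                         dropNonMembers = FALSE, allowEmpty = FALSE) {
    stopifnot(is(de, "DEResult"), is(sets, "GeneSetCollection"))
    if (!length(pathways)) stop("no pathway selected")
    missing <- setdiff(pathways, setIds(sets))
    if (length(missing))
        stop("pathway(s) not in the collection: ",
             paste(missing, collapse = ", "))
    r <- deTable(de)
    r <- r[r$significant, , drop = FALSE]
    if (!nrow(r)) stop("contrast '", de@treatment, "' has no significant DEG")
    genes <- r$gene
    fc <- stats::setNames(r$fold_change, genes)
    memb <- vapply(pathways, function(p) genes %in% geneSets(sets)[[p]],
                   logical(length(genes)))
    memb <- matrix(memb, nrow = length(genes),
                   dimnames = list(genes, pathways))
    if (dropNonMembers) {
        keep <- rowSums(memb) > 0L
        memb <- memb[keep, , drop = FALSE]
        fc <- fc[keep]
        genes <- genes[keep]
        if (!length(genes)) stop("no DEG belongs to any selected pathway")
    }
    vals <- matrix(1, nrow = length(genes), ncol = length(pathways),
                   dimnames = list(genes, pathways))
    vals[memb] <- fc[row(vals)[memb]]
    new("PathwayProfile", treatment = de@treatment, values = vals,
        membership = memb, allowEmpty = allowEmpty)
}
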