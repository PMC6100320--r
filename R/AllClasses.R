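#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats p.adjust pf phyper rnorm runif setNames
#' @importFrom utils read.delim write.table
NULL

#' Expression matrix with group design
#'
#' Thin wrapper around \linkS4class{SummarizedExperiment} holding a
#' genes-by-samples matrix of nonnegative linear-scale intensities in the
#' \code{"exprs"} assay and a \code{group} column in \code{colData} mapping
#' each sample to its treatment group.
#'
#' Validity requires: unique gene and sample identifiers, finite nonnegative
#' intensities, a group label for every sample, and at least two samples in
#' every group.
#'
#' @seealso [QPExpression()] for construction, [readExpression()] to read
#'   from delimited files.
#' @export
setClass("QPExpression", contains = "SummarizedExperiment")

setValidity("QPExpression", function(object) {
    msg <- character()
    if (!("exprs" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        x <- SummarizedExperiment::assay(object, "exprs")
        if (!is.numeric(x))
            msg <- c(msg, "intensities must be numeric")
        else {
            if (any(!is.finite(x)))
                msg <- c(msg, "intensities must be finite (no NA/Inf)")
            else if (any(x < 0))
                msg <- c(msg, "intensities must be nonnegative")
        }
    }
    gid <- rownames(object); sid <- colnames(object)
    if (is.null(gid) || anyDuplicated(gid))
        msg <- c(msg, sprintf("duplicated gene identifier(s): %s",
                              paste(unique(gid[duplicated(gid)]), collapse = ", ")))
    if (is.null(sid) || anyDuplicated(sid))
        msg <- c(msg, "sample identifiers must be present and unique")
    if (!("group" %in% colnames(SummarizedExperiment::colData(object))))
        msg <- c(msg, "colData must contain a 'group' column")
    else {
        grp <- SummarizedExperiment::colData(object)$group
        if (any(is.na(grp)) || any(!nzchar(as.character(grp))))
            msg <- c(msg, "every sample needs a nonempty group label")
        else {
            tab <- table(as.character(grp))
            if (any(tab < 2))
                msg <- c(msg, sprintf("group(s) with fewer than 2 samples: %s",
                                      paste(names(tab)[tab < 2], collapse = ", ")))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Gene set (pathway) collection
#'
#' Maps pathway identifiers to member gene identifier sets, with a gene
#' universe. Pathway identifiers are unique, every set is nonempty, and the
#' universe defaults to the union of all members.
#'
#' @slot sets named list of character vectors (pathway id -> member genes).
#' @slot descriptions named character vector of pathway descriptions.
#' @slot universe character vector of gene identifiers.
#' @seealso [GeneSetCollection()], [readGmt()], [restrictToUniverse()]
#' @export
setClass("GeneSetCollection",
    representation(sets = "list", descriptions = "character",
                   universe = "character"))

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    nm <- names(object@sets)
    if (is.null(nm) || anyDuplicated(nm))
        msg <- c(msg, "pathway identifiers must be present and unique")
    if (any(lengths(object@sets) == 0L))
        msg <- c(msg, sprintf("empty gene set(s): %s",
                              paste(nm[lengths(object@sets) == 0L], collapse = ", ")))
    if (anyDuplicated(object@universe))
        msg <- c(msg, "universe contains duplicated gene identifiers")
    if (!identical(sort(nm), sort(names(object@descriptions))))
        msg <- c(msg, "descriptions must be named by pathway id")
    if (length(msg)) msg else TRUE
})

#' Differential expression result for one contrast
#'
#' Per-gene fold change (linear treatment/reference ratio), log2 fold change,
#' p-value, significance call and direction for a single
#' treatment-versus-reference contrast.
#'
#' @slot treatment,reference group labels of the contrast.
#' @slot results data.frame with columns \code{gene}, \code{fold_change},
#'   \code{log2_fc}, \code{p_value}, \code{significant}, \code{direction}.
#' @slot alpha,fcHigh,fcLow thresholds used for the significance call.
#' @seealso [callDegs()], [runDE()], [degs()]
#' @export
setClass("DEResult",
    representation(treatment = "character", reference = "character",
                   results = "data.frame", alpha = "numeric",
                   fcHigh = "numeric", fcLow = "numeric"))

setValidity("DEResult", function(object) {
    msg <- character()
    need <- c("gene", "fold_change", "log2_fc", "p_value", "significant",
              "direction")
    if (!all(need %in% colnames(object@results)))
        msg <- c(msg, paste("results must have columns:",
                            paste(need, collapse = ", ")))
    else {
        r <- object@results
        if (any(r$fold_change <= 0)) msg <- c(msg, "fold changes must be > 0")
        if (any(r$p_value < 0 | r$p_value > 1))
            msg <- c(msg, "p-values must lie in [0, 1]")
        want <- (r$p_value < object@alpha) &
                (r$fold_change > object@fcHigh | r$fold_change < object@fcLow)
        if (!identical(as.logical(r$significant), as.logical(want)))
            msg <- c(msg, "significance flags inconsistent with thresholds")
        up <- r$significant & r$fold_change > object@fcHigh
        dn <- r$significant & r$fold_change < object@fcLow
        dir <- ifelse(up, "up", ifelse(dn, "down", "none"))
        if (!identical(as.character(r$direction), dir))
            msg <- c(msg, "direction flags inconsistent with calls")
    }
    if (length(msg)) msg else TRUE
})

#' Quantitative pathway profile for one treatment
#'
#' The genes-by-pathways table at the heart of the method: rows are the
#' contrast's differentially expressed genes, columns are selected pathways,
#' and a cell holds the gene's linear fold change where the gene is a pathway
#' member and the neutral value 1 elsewhere.
#'
#' @slot treatment treatment label the profile belongs to.
#' @slot values numeric matrix, genes x pathways.
#' @slot membership logical matrix of the same shape (TRUE = member cell).
#' @slot allowEmpty if TRUE, pathways with no member entries are tolerated
#'   (used when a common pathway set is imposed across treatments).
#' @seealso [buildProfile()], [preprocessProfile()]
#' @export
setClass("PathwayProfile",
    representation(treatment = "character", values = "matrix",
                   membership = "matrix", allowEmpty = "logical"))

setValidity("PathwayProfile", function(object) {
    msg <- character()
    v <- object@values; m <- object@membership
    if (!identical(dim(v), dim(m)))
        msg <- c(msg, "values and membership must have identical dimensions")
    else {
        if (is.null(rownames(v)) || is.null(colnames(v)))
            msg <- c(msg, "values must carry gene rownames and pathway colnames")
        if (any(!is.finite(v)) || any(v <= 0))
            msg <- c(msg, "profile values must be finite and positive")
        else if (any(v[!m] != 1))
            msg <- c(msg, "non-member cells must hold the neutral value 1")
        if (!isTRUE(object@allowEmpty) && ncol(m) > 0 &&
            any(colSums(m) == 0L))
            msg <- c(msg, sprintf("pathway(s) with no member entries: %s",
                                  paste(colnames(m)[colSums(m) == 0L],
                                        collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' Statistical triplet (table, row weights, column weights)
#'
#' The object multiple co-inertia operates on: one treatment's preprocessed
#' table with pathways as rows (the dimension shared across treatments) and
#' that treatment's DEGs as columns, plus strictly positive row weights
#' (common to all tables, summing to 1) and column weights.
#'
#' @slot table numeric matrix, pathways x genes.
#' @slot rowWeights numeric, length nrow, strictly positive, sums to 1.
#' @slot colWeights numeric, length ncol, strictly positive.
#' @slot tableName treatment label.
#' @slot preprocessing character tag recording how the table was derived.
#' @seealso [preprocessProfile()], [mcoa()]
#' @export
setClass("StatisticalTriplet",
    representation(table = "matrix", rowWeights = "numeric",
                   colWeights = "numeric", tableName = "character",
                   preprocessing = "character"))

setValidity("StatisticalTriplet", function(object) {
    msg <- character()
    if (length(object@rowWeights) != nrow(object@table) ||
        any(object@rowWeights <= 0))
        msg <- c(msg, "row weights must be positive, one per row")
    else if (abs(sum(object@rowWeights) - 1) > 1e-8)
        msg <- c(msg, "row weights must sum to 1")
    if (length(object@colWeights) != ncol(object@table) ||
        any(object@colWeights <= 0))
        msg <- c(msg, "column weights must be positive, one per column")
    if (any(!is.finite(object@table)))
        msg <- c(msg, "table entries must be finite")
    if (is.null(rownames(object@table)))
        msg <- c(msg, "table must carry pathway rownames")
    if (length(msg)) msg else TRUE
})

#' Multiple co-inertia analysis result
#'
#' Common-space coordinates from co-projecting K per-treatment pathway
#' profile tables. \code{synthetic} holds the D-orthonormal common axes
#' (pathway coordinates of the synthetic/reference point), \code{tableScores}
#' each table's own pathway coordinates on those axes, \code{eigenvalues}
#' the maximized co-inertia criterion per axis.
#'
#' @slot synthetic numeric matrix, pathways x axes (v, unit D-norm columns).
#' @slot tableScores named list of pathways x axes matrices (s_k).
#' @slot tableLoadings named list of genes x axes matrices (u_k, unit
#'   Q-norm columns).
#' @slot eigenvalues numeric, non-increasing criterion values (lambda).
#' @slot tableWeights numeric table weights w_k.
#' @slot rowWeights the shared row weights D.
#' @slot colWeights named list of per-table column weights Q_k.
#' @slot pathwayIds,tableNames row/table identifiers.
#' @slot weighting,preprocessing provenance tags.
#' @seealso [mcoa()], [projectPathways()], [divergenceScores()]
#' @export
setClass("MCIAResult",
    representation(synthetic = "matrix", tableScores = "list",
                   tableLoadings = "list", eigenvalues = "numeric",
                   tableWeights = "numeric", rowWeights = "numeric",
                   colWeights = "list", pathwayIds = "character",
                   tableNames = "character", weighting = "character",
                   preprocessing = "character"))

setValidity("MCIAResult", function(object) {
    msg <- character()
    f <- length(object@eigenvalues)
    if (f > 1 && any(diff(object@eigenvalues) > 1e-8))
        msg <- c(msg, "eigenvalues must be non-increasing")
    if (any(object@eigenvalues < 0))
        msg <- c(msg, "eigenvalues must be nonnegative")
    if (ncol(object@synthetic) != f)
        msg <- c(msg, "synthetic axes must match eigenvalue count")
    d <- object@rowWeights
    if (length(d) == nrow(object@synthetic)) {
        g <- crossprod(object@synthetic, d * object@synthetic)
        if (max(abs(g - diag(f))) > 1e-6)
            msg <- c(msg, "synthetic axes must be D-orthonormal")
    }
    if (length(object@tableScores) != length(object@tableNames))
        msg <- c(msg, "one score matrix per table required")
    if (length(msg)) msg else TRUE
})

#' Per-pathway divergence between treatments
#'
#' For every pathway and treatment pair, the Euclidean distance between the
#' pathway's (optionally eigenvalue-standardized) coordinates in the two
#' tables over the first F common axes, with permutation p-values and BH
#' q-values when a permutation test has been run.
#'
#' @slot scores data.frame: pathway, table1, table2, distance, p_value,
#'   q_value, different.
#' @slot overall data.frame: pathway, mean_distance, p_value, q_value,
#'   different (mean over pairs).
#' @slot nAxes,B,alpha,seed test parameters (B = 0 when scores only).
#' @slot standardized whether axes were scaled by 1/sqrt(lambda).
#' @seealso [divergenceScores()], [permutationTest()],
#'   [pairwiseGroupReport()]
#' @export
setClass("DivergenceTable",
    representation(scores = "data.frame", overall = "data.frame",
                   nAxes = "integer", B = "integer", alpha = "numeric",
                   seed = "integer", standardized = "logical"))

setValidity("DivergenceTable", function(object) {
    msg <- character()
    need <- c("pathway", "table1", "table2", "distance", "p_value",
              "q_value", "different")
    if (!all(need %in% colnames(object@scores)))
        msg <- c(msg, paste("scores must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (any(object@scores$distance < 0))
            msg <- c(msg, "distances must be nonnegative")
        p <- object@scores$p_value
        if (object@B > 0 && any(!is.na(p) & (p < 1 / (object@B + 1) | p > 1)))
            msg <- c(msg, "permutation p-values must lie in [1/(B+1), 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Simulation scenario with planted pathway effects
#'
#' Defines a synthetic multi-group expression study: universe size, group
#' sizes, gene-set layout, planted per-(treatment, pathway) log2 effects,
#' noise level and the log2 baseline range. \code{divergenceThreshold} (tau)
#' sets how different two treatments' planted effects on a pathway must be
#' (in absolute log2 units) for the ground truth to call the pair divergent
#' on that pathway.
#'
#' @slot nGenes,nPerGroup,nPathways,setSize integer sizes.
#' @slot reference reference (model) group label.
#' @slot treatments treatment group labels.
#' @slot overlap fraction of each set shared with a common core block.
#' @slot coreGroups list of pathway-id groups sharing a private core.
#' @slot coreSize size of each private core block.
#' @slot effects numeric matrix treatments x pathways of planted log2
#'   effects added to member genes.
#' @slot noiseSd per-observation log2 noise standard deviation.
#' @slot baselineRange length-2 range of per-gene log2 baseline means.
#' @slot divergenceThreshold tau for the ground-truth divergence call.
#' @slot seed default seed for generation.
#' @seealso [SimulationScenario()], [generateExpression()],
#'   [threeArmScenario()], [nullScenario()]
#' @export
setClass("SimulationScenario",
    representation(nGenes = "integer", nPerGroup = "integer",
                   reference = "character", treatments = "character",
                   nPathways = "integer", setSize = "integer",
                   overlap = "numeric", coreGroups = "list",
                   coreSize = "integer", effects = "matrix",
                   noiseSd = "numeric", baselineRange = "numeric",
                   divergenceThreshold = "numeric", seed = "integer"))

setValidity("SimulationScenario", function(object) {
    msg <- character()
    if (object@nGenes < 1L || object@nPerGroup < 2L ||
        object@nPathways < 1L || object@setSize < 1L)
        msg <- c(msg, "sizes must be positive (and >= 2 samples per group)")
    if (object@noiseSd <= 0)
        msg <- c(msg, "noiseSd must be > 0")
    if (object@overlap < 0 || object@overlap >= 1)
        msg <- c(msg, "overlap must lie in [0, 1)")
    if (!identical(dim(object@effects),
                   c(length(object@treatments), object@nPathways)))
        msg <- c(msg, "effects must be a treatments x pathways matrix")
    if (object@reference %in% object@treatments)
        msg <- c(msg, "reference label must differ from treatment labels")
    if (length(object@baselineRange) != 2L ||
        diff(object@baselineRange) < 0)
        msg <- c(msg, "baselineRange must be an increasing length-2 vector")
    if (length(msg)) msg else TRUE
})
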