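#' Per-pathway divergence scores between treatment tables
#'
#' For every pathway i and table pair (j, k), the Euclidean distance between
#' the pathway's coordinates in tables j and k over the first F common axes,
#' with coordinates standardized per axis by \eqn{1/\sqrt{\lambda_f}}
#' (default) so the first axis does not drown the others. Pathways far apart
#' respond differently to the two treatments; identical tables give zero
#' distances everywhere. The overall score is the mean over pairs.
#'
#' @param result an \linkS4class{MCIAResult} with at least F axes.
#' @param nAxes number of axes F (default 2).
#' @param standardize \code{"by_sqrt_eigenvalue"} (default) or
#'   \code{"none"}.
#' @return a \linkS4class{DivergenceTable} with distances only (p/q NA).
#' @export
divergenceScores <- function(result, nAxes = 2L,
                             standardize = c("by_sqrt_eigenvalue",
                                             "none")) {
    standardize <- match.arg(standardize)
    stopifnot(is(result, "MCIAResult"))
    f <- length(eigenvalues(result))
    if (nAxes > f)
        stop("requested F = ", nAxes, " axes but only ", f, " were fitted")
    dm <- .pairDistances(tableScores(result), eigenvalues(result),
                         nAxes, standardize == "by_sqrt_eigenvalue")
    .divergenceTable(dm, result@pathwayIds, result@tableNames,
                     nAxes = nAxes,
                     standardized = standardize == "by_sqrt_eigenvalue")
}

# scores: named list of n x >=F matrices -> matrix n x nPairs of distances
.pairDistances <- function(scores, lambda, nAxes, standardize) {
    sel <- seq_len(nAxes)
    sc <- lapply(scores, function(m) m[, sel, drop = FALSE])
    if (standardize) {
        s <- 1 / sqrt(lambda[sel])
        sc <- lapply(sc, function(m) sweep(m, 2L, s, "*"))
    }
    kk <- length(sc)
    pairs <- which(upper.tri(matrix(0, kk, kk)), arr.ind = TRUE)
    out <- vapply(seq_len(nrow(pairs)), function(r) {
        dd <- sc[[pairs[r, 1L]]] - sc[[pairs[r, 2L]]]
        sqrt(rowSums(dd^2))
    }, numeric(nrow(sc[[1L]])))
    out <- matrix(out, nrow = nrow(sc[[1L]]))
    attr(out, "pairs") <- pairs
    out
}

.divergenceTable <- function(dm, pathwayIds, tableNames, nAxes,
                             standardized, pmat = NULL, B = 0L,
                             alpha = 0.05, seed = NA_integer_,
                             overallP = NULL) {
    pairs <- attr(dm, "pairs")
    npair <- nrow(pairs)
    scores <- do.call(rbind, lapply(seq_len(npair), function(r) {
        p <- if (is.null(pmat)) rep(NA_real_, nrow(dm)) else pmat[, r]
        q <- if (is.null(pmat)) rep(NA_real_, nrow(dm)) else
            stats::p.adjust(p, method = "BH")
        data.frame(pathway = unname(pathwayIds),
                   table1 = unname(tableNames[pairs[r, 1L]]),
                   table2 = unname(tableNames[pairs[r, 2L]]),
                   distance = unname(dm[, r]), p_value = p, q_value = q,
                   different = if (is.null(pmat)) NA else q < alpha,
                   stringsAsFactors = FALSE)
    }))
    rownames(scores) <- NULL
    op <- if (is.null(overallP)) rep(NA_real_, nrow(dm)) else overallP
    oq <- if (is.null(overallP)) rep(NA_real_, nrow(dm)) else
        stats::p.adjust(op, method = "BH")
    overall <- data.frame(pathway = pathwayIds,
                          mean_distance = unname(rowMeans(dm)),
                          p_value = op, q_value = oq,
                          different = if (is.null(overallP)) NA else
                              oq < alpha,
                          stringsAsFactors = FALSE)
    rownames(overall) <- NULL
    new("DivergenceTable", scores = scores, overall = overall,
        nAxes = as.integer(nAxes), B = as.integer(B), alpha = alpha,
        seed = as.integer(seed), standardized = standardized)
}

#' Permutation test for pathway divergence
#'
#' Tests, per pathway and per treatment pair, whether the observed
#' between-table divergence exceeds what is expected when member fold
#' changes carry no pathway-specific trend. The null relabels member
#' genes: one random permutation of the member-gene identities is drawn
#' per replicate and applied to every table, so each gene's fold-change
#' values travel together across tables to their new position in the
#' membership pattern (the pattern itself is preserved; within each table
#' the member values are exchanged across member rows). Relabelling
#' jointly rather than per table keeps the cross-table correlation that
#' the shared reference group induces in the fold changes, which makes
#' the test exact when member genes are exchangeable. The full MCOA and
#' the divergence scores are recomputed per replicate. The p-value is the
#' standard permutation
#' tail \eqn{p = (1 + \#\{b : d_b \ge d_{obs}\}) / (B + 1)};
#' Benjamini-Hochberg correction is applied across pathways within each
#' pair, and a pathway is called different when q < alpha. Fully
#' reproducible given \code{seed}.
#'
#' @param profiles list of \linkS4class{PathwayProfile} objects sharing the
#'   same pathway columns (same ids and order), one per treatment.
#' @param B number of permutations (default 999, minimum 99).
#' @param seed integer seed.
#' @param nAxes number of common axes F (default 2).
#' @param alpha significance level for the call (default 0.05).
#' @param method,rowWeighting passed to [preprocessProfile()].
#' @param weighting passed to [mcoa()].
#' @param standardize passed to [divergenceScores()].
#' @return a \linkS4class{DivergenceTable} with p- and q-values.
#' @export
permutationTest <- function(profiles, B = 999L, seed = 1L, nAxes = 2L,
                            alpha = 0.05,
                            method = c("log_center", "nsc"),
                            rowWeighting = c("uniform", "mass"),
                            weighting = c("lambda1", "uniform"),
                            standardize = c("by_sqrt_eigenvalue",
                                            "none")) {
    method <- match.arg(method)
    rowWeighting <- match.arg(rowWeighting)
    weighting <- match.arg(weighting)
    standardize <- match.arg(standardize)
    std <- standardize == "by_sqrt_eigenvalue"
    stopifnot(length(profiles) >= 2L,
              all(vapply(profiles, is, logical(1), "PathwayProfile")))
    if (B < 99L) stop("B must be at least 99")
    if ((B + 1) * alpha < 1)
        warning("B = ", B, " is too small to ever reject at alpha = ",
                alpha)
    ids <- colnames(profileValues(profiles[[1L]]))
    if (length(ids) < 2L) stop("need at least 2 pathways")
    for (pr in profiles[-1L])
        if (!identical(colnames(profileValues(pr)), ids))
            stop("profiles must share identical pathway columns: ",
                 paste(c(setdiff(ids, colnames(profileValues(pr))),
                         setdiff(colnames(profileValues(pr)), ids)),
                       collapse = ", "))
    nm <- vapply(profiles, slot, character(1), "treatment")
    set.seed(seed)

    triplets <- lapply(profiles, preprocessProfile, method = method,
                       rowWeighting = rowWeighting)
    obs <- mcoa(triplets, nAxes = nAxes, weighting = weighting)
    if (length(eigenvalues(obs)) < nAxes)
        stop("fewer than ", nAxes, " axes available; reduce nAxes")
    kept <- obs@pathwayIds  # after the all-zero-row drop, if any
    dObs <- .pairDistances(tableScores(obs), eigenvalues(obs), nAxes, std)
    pairs <- attr(dObs, "pairs")

    # per-table member rows, their gene ids and values, fixed once
    memberRows <- lapply(profiles, function(pr)
        which(rowSums(membership(pr)) > 0L))
    memberGenes <- Map(function(pr, rws)
        rownames(profileValues(pr))[rws], profiles, memberRows)
    rowVals <- Map(function(pr, rws) {
        m <- membership(pr)[rws, , drop = FALSE]
        v <- profileValues(pr)[rws, , drop = FALSE]
        # a profile row holds one fold change in all its member cells
        v[cbind(seq_along(rws), max.col(m, ties.method = "first"))]
    }, profiles, memberRows)
    allGenes <- unique(unlist(memberGenes, use.names = FALSE))
    d <- obs@rowWeights
    qsTmpl <- obs@colWeights
    keepRows <- match(kept, ids)

    exceed <- matrix(0L, nrow(dObs), ncol(dObs))
    exceedOverall <- numeric(nrow(dObs))
    meanObs <- rowMeans(dObs)
    for (b in seq_len(B)) {
        # one joint relabelling of member genes, shared by all tables
        rank <- stats::setNames(sample.int(length(allGenes)), allGenes)
        xs <- vector("list", length(profiles))
        for (k in seq_along(profiles)) {
            pr <- profiles[[k]]
            v <- profileValues(pr)
            mb <- membership(pr)
            o <- order(rank[memberGenes[[k]]])
            newv <- rowVals[[k]]
            newv[o] <- rowVals[[k]]
            vrow <- rep(1, nrow(v))
            vrow[memberRows[[k]]] <- newv
            v[mb] <- vrow[row(v)[mb]]
            prb <- new("PathwayProfile", treatment = pr@treatment,
                       values = v, membership = mb, allowEmpty = TRUE)
            tb <- preprocessProfile(prb, method = method,
                                    rowWeighting = rowWeighting)
            xs[[k]] <- tb@table[keepRows, , drop = FALSE]
        }
        core <- .mcoaCore(xs, d, qsTmpl, nAxes = nAxes,
                          weighting = weighting)
        if (length(core$lambda) < nAxes) next
        db <- .pairDistances(core$scores, core$lambda, nAxes, std)
        exceed <- exceed + (db >= dObs)
        exceedOverall <- exceedOverall + (rowMeans(db) >= meanObs)
    }
    pmat <- (1 + exceed) / (B + 1)
    overallP <- (1 + exceedOverall) / (B + 1)
    out <- .divergenceTable(dObs, kept, nm, nAxes = nAxes,
                            standardized = std, pmat = pmat, B = B,
                            alpha = alpha, seed = seed,
                            overallP = overallP)
    out
}

#' Which treatment pairs differ on which pathways
#'
#' Summarizes a tested \linkS4class{DivergenceTable} per treatment pair:
#' how many pathways were tested, how many called different, and the
#' different pathways sorted by q-value.
#'
#' @param x a \linkS4class{DivergenceTable} from [permutationTest()], or a
#'   list of them (e.g. one per pair).
#' @param alpha significance level (default: the table's own).
#' @return data.frame with columns \code{table1}, \code{table2},
#'   \code{n_tested}, \code{n_different}, \code{pathways} (comma-joined,
#'   sorted by q).
#' @export
pairwiseGroupReport <- function(x, alpha = NULL) {
    if (is(x, "DivergenceTable")) x <- list(x)
    stopifnot(all(vapply(x, is, logical(1), "DivergenceTable")))
    out <- do.call(rbind, lapply(x, function(dt) {
        if (dt@B == 0L)
            stop("divergence table carries no permutation test; run ",
                 "permutationTest() first")
        a <- if (is.null(alpha)) dt@alpha else alpha
        s <- divergence(dt)
        do.call(rbind, lapply(split(s, paste(s$table1, s$table2, sep = "\r")),
                              function(g) {
            g <- g[order(g$q_value, g$pathway), , drop = FALSE]
            hit <- g$q_value < a
            data.frame(table1 = g$table1[1L], table2 = g$table2[1L],
                       n_tested = nrow(g), n_different = sum(hit),
                       pathways = paste(g$pathway[hit], collapse = ","),
                       stringsAsFactors = FALSE)
        }))
    }))
    out <- out[order(out$table1, out$table2), , drop = FALSE]
    rownames(out) <- NULL
    out
}
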