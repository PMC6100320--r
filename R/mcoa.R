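#' Preprocess a pathway profile into a statistical triplet
#'
#' Transposes the profile so pathways become rows (the dimension shared
#' across treatments) and applies one of two classical transforms:
#' \describe{
#'   \item{\code{log_center} (default)}{entries become log2(value), so the
#'     neutral value 1 maps to 0, then each column (gene) is centered with
#'     the row weights D. The natural transform for a fold-change table:
#'     "no change" is the origin.}
#'   \item{\code{nsc}}{nonsymmetric-correspondence preprocessing of the
#'     nonnegative table: scale to overall sum 1, form row profiles and
#'     center by column masses; row weights become the row masses. Provided
#'     for cross-checks against correspondence-analysis conventions.}
#' }
#'
#' @param profile a \linkS4class{PathwayProfile}.
#' @param method \code{"log_center"} or \code{"nsc"}.
#' @param rowWeighting \code{"uniform"} (default, D = 1/n) or \code{"mass"}
#'   (rows weighted by their share of the table total; for \code{nsc} the
#'   row masses are always used).
#' @return a \linkS4class{StatisticalTriplet} with uniform column weights
#'   Q = 1/p.
#' @export
preprocessProfile <- function(profile, method = c("log_center", "nsc"),
                              rowWeighting = c("uniform", "mass")) {
    method <- match.arg(method)
    rowWeighting <- match.arg(rowWeighting)
    stopifnot(is(profile, "PathwayProfile"))
    x <- t(profileValues(profile))  # pathways x genes
    n <- nrow(x); p <- ncol(x)
    if (method == "log_center") {
        lx <- log2(x)
        d <- if (rowWeighting == "uniform") rep(1 / n, n)
             else rowSums(abs(lx)) / sum(abs(lx))
        if (any(d <= 0)) d <- pmax(d, 1e-12) / sum(pmax(d, 1e-12))
        ctr <- colSums(d * lx)
        tab <- sweep(lx, 2L, ctr, "-")
    } else {
        pm <- x / sum(x)
        r <- rowSums(pm)
        cm <- colSums(pm)
        tab <- sweep(pm / r, 2L, cm, "-")
        d <- r
    }
    new("StatisticalTriplet", table = tab, rowWeights = unname(d),
        colWeights = rep(1 / p, p), tableName = profile@treatment,
        preprocessing = method)
}

#' Multiple co-inertia analysis of K matched tables
#'
#' Computes common axes over the shared pathway dimension of K statistical
#' triplets. Axis f maximizes the summed squared co-inertia
#' \eqn{\sum_k w_k \langle s_{k,f}, v \rangle_D^2} over unit-D-norm vectors
#' v, which is attained by the leading eigenvector of the D-symmetrized
#' summed cross-product operator \eqn{M = \sum_k w_k X_k Q_k X_k^\top}.
#' Per-table loadings \eqn{u_{k,f} = X_k^\top D v_f} (unit Q-norm) and
#' scores \eqn{s_{k,f} = X_k Q_k u_{k,f}} follow; tables are then deflated
#' by the D-metric projector on \eqn{v_f} so successive axes are
#' D-orthonormal.
#'
#' Table weights: \code{"lambda1"} (default) sets \eqn{w_k = 1/\lambda_1^{(k)}}
#' with \eqn{\lambda_1^{(k)}} table k's own leading eigenvalue, equalizing
#' table influence (and making scores invariant to global rescaling of a
#' table); \code{"uniform"} sets \eqn{w_k = 1}.
#'
#' Sign convention: each axis is flipped so the synthetic entry with the
#' largest absolute value is positive. Axes requested beyond the numerical
#' rank are truncated with a warning; eigenvalue near-degeneracy (gap below
#' 1e-10 relative) is reported with a message.
#'
#' @param triplets list of \linkS4class{StatisticalTriplet} sharing pathway
#'   rows (same ids, same order) and the same row weights.
#' @param nAxes number of axes F to extract (default 2).
#' @param weighting \code{"lambda1"} or \code{"uniform"}.
#' @return an \linkS4class{MCIAResult}.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(24), 6, 4, dimnames = list(paste0("P", 1:6), NULL))
#' tr <- new("StatisticalTriplet", table = m, rowWeights = rep(1/6, 6),
#'           colWeights = rep(1/4, 4), tableName = "A",
#'           preprocessing = "log_center")
#' res <- mcoa(list(tr), nAxes = 2)
#' eigenvalues(res)
#' @export
mcoa <- function(triplets, nAxes = 2L,
                 weighting = c("lambda1", "uniform")) {
    weighting <- match.arg(weighting)
    stopifnot(length(triplets) >= 1L,
              all(vapply(triplets, is, logical(1), "StatisticalTriplet")))
    ids <- rownames(triplets[[1L]]@table)
    for (tr in triplets[-1L]) {
        if (!identical(rownames(tr@table), ids)) {
            diffs <- c(setdiff(ids, rownames(tr@table)),
                       setdiff(rownames(tr@table), ids))
            stop("pathway rows differ across tables",
                 if (length(diffs)) paste0(": ",
                     paste(unique(diffs), collapse = ", "))
                 else " (same set, different order)")
        }
        if (max(abs(tr@rowWeights - triplets[[1L]]@rowWeights)) > 1e-8)
            stop("row weights must be identical across tables")
    }
    nm <- vapply(triplets, slot, character(1), "tableName")
    if (anyDuplicated(nm)) nm <- make.unique(nm, sep = ".")
    xs <- lapply(triplets, slot, "table")
    d <- triplets[[1L]]@rowWeights
    qs <- lapply(triplets, slot, "colWeights")

    # drop pathways carrying no signal in any table
    dead <- Reduce(`&`, lapply(xs, function(x) rowSums(x != 0) == 0L))
    if (all(dead)) stop("all tables are zero; nothing to analyse")
    if (any(dead)) {
        warning("dropping ", sum(dead),
                " pathway row(s) that are zero in every table: ",
                paste(ids[dead], collapse = ", "))
        xs <- lapply(xs, function(x) x[!dead, , drop = FALSE])
        ids <- ids[!dead]
        d <- d[!dead] / sum(d[!dead])
    }

    core <- .mcoaCore(xs, d, qs, nAxes = nAxes, weighting = weighting,
                      verbose = TRUE)
    f <- length(core$lambda)
    dimnames(core$v) <- list(ids, paste0("Axis", seq_len(f)))
    scores <- lapply(core$scores, function(s) {
        dimnames(s) <- dimnames(core$v); s })
    loads <- Map(function(u, x) {
        dimnames(u) <- list(colnames(x), colnames(core$v)); u },
        core$loadings, xs)
    names(scores) <- names(loads) <- nm
    new("MCIAResult", synthetic = core$v, tableScores = scores,
        tableLoadings = loads, eigenvalues = core$lambda,
        tableWeights = core$w, rowWeights = d, colWeights = qs,
        pathwayIds = ids, tableNames = nm, weighting = weighting,
        preprocessing = triplets[[1L]]@preprocessing)
}

# Lean numerical core shared by mcoa() and the permutation loop.
# xs: list of n x p_k matrices; d: row weights; qs: list of column weights.
# Returns v (n x F), lambda, per-table scores and loadings, weights w.
.mcoaCore <- function(xs, d, qs, nAxes = 2L,
                      weighting = c("lambda1", "uniform"),
                      verbose = FALSE) {
    weighting <- match.arg(weighting)
    n <- nrow(xs[[1L]])
    sqd <- sqrt(d)
    xq <- Map(function(x, q) sweep(x, 2L, q, "*"), xs, qs)  # X_k Q_k
    w <- if (weighting == "uniform") rep(1, length(xs)) else
        vapply(seq_along(xs), function(k) {
            mk <- tcrossprod(xq[[k]], xs[[k]])          # X Q X^T
            l1 <- eigen(sqd * t(sqd * mk), symmetric = TRUE,
                        only.values = TRUE)$values[1L]
            if (l1 <= 0) stop("table ", k, " is zero; cannot weight by ",
                              "its leading eigenvalue")
            1 / l1
        }, numeric(1))
    fmax <- min(nAxes, n - (n > 1L))
    v <- matrix(0, n, 0L)
    lambda <- numeric(0)
    scores <- lapply(xs, function(x) matrix(0, n, 0L))
    loadings <- lapply(xs, function(x) matrix(0, ncol(x), 0L))
    tol <- 1e-12
    for (f in seq_len(fmax)) {
        m <- matrix(0, n, n)
        for (k in seq_along(xs))
            m <- m + w[k] * tcrossprod(xq[[k]], xs[[k]])
        ms <- sqd * t(sqd * m)           # D^1/2 M D^1/2, symmetric
        ms <- (ms + t(ms)) / 2
        ev <- eigen(ms, symmetric = TRUE)
        lam <- ev$values[1L]
        if (lam <= tol * max(1, if (length(lambda)) lambda[1L] else lam)) {
            if (f == 1L) stop("all tables are zero; nothing to analyse")
            warning("requested ", nAxes, " axes but numerical rank is ",
                    f - 1L, "; truncating")
            break
        }
        if (verbose && length(ev$values) > 1L &&
            (lam - ev$values[2L]) <= 1e-10 * lam)
            message("axis ", f, ": near-degenerate leading eigenvalues ",
                    "(gap <= 1e-10 relative); ordering fixed by the ",
                    "deterministic symmetric eigensolver")
        u1 <- ev$vectors[, 1L]
        resid <- sqrt(sum((ms %*% u1 - lam * u1)^2))
        if (resid > 1e-8 * lam)
            warning("eigenvector residual ", format(resid),
                    " exceeds tolerance on axis ", f)
        vf <- u1 / sqd                    # unit D-norm
        i <- which.max(abs(vf))
        if (vf[i] < 0) vf <- -vf
        v <- cbind(v, vf)
        lambda <- c(lambda, lam)
        dv <- d * vf
        for (k in seq_along(xs)) {
            a <- crossprod(xs[[k]], dv)             # X^T D v
            nq <- sqrt(sum(qs[[k]] * a^2))
            u <- if (nq > 0) a / nq else a * 0
            s <- xq[[k]] %*% u                      # X Q u
            loadings[[k]] <- cbind(loadings[[k]], u)
            scores[[k]] <- cbind(scores[[k]], s)
            # deflate in the D metric
            proj <- crossprod(dv, xs[[k]])          # v^T D X
            xs[[k]] <- xs[[k]] - vf %*% proj
            xq[[k]] <- sweep(xs[[k]], 2L, qs[[k]], "*")
        }
    }
    list(v = v, lambda = lambda, scores = scores, loadings = loadings,
         w = w)
}

#' Per-pathway coordinates in the common space
#'
#' For each pathway, the K table points and the synthetic point over the
#' first F axes, in long format; optionally standardized per axis by
#' \eqn{1/\sqrt{\lambda_f}} so axes contribute comparably.
#'
#' @param result an \linkS4class{MCIAResult}.
#' @param nAxes axes to keep (default: all fitted).
#' @param standardize divide axis f coordinates by sqrt(lambda_f)
#'   (default FALSE).
#' @return data.frame with columns \code{pathway}, \code{table} (treatment
#'   label or \code{"synthetic"}) and \code{Axis1..AxisF}.
#' @export
projectPathways <- function(result, nAxes = length(eigenvalues(result)),
                            standardize = FALSE) {
    stopifnot(is(result, "MCIAResult"))
    f <- length(eigenvalues(result))
    if (nAxes > f) stop("requested ", nAxes, " axes but only ", f,
                        " were fitted")
    sel <- seq_len(nAxes)
    sc <- c(list(synthetic = syntheticScores(result)), tableScores(result))
    if (standardize) {
        s <- 1 / sqrt(eigenvalues(result)[sel])
        sc <- lapply(sc, function(m)
            sweep(m[, sel, drop = FALSE], 2L, s, "*"))
    } else sc <- lapply(sc, function(m) m[, sel, drop = FALSE])
    out <- do.call(rbind, lapply(names(sc), function(nmk) {
        m <- sc[[nmk]]
        rownames(m) <- NULL
        data.frame(pathway = result@pathwayIds, table = nmk, m,
                   check.names = FALSE, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}
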