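#' Per-gene fold change between two groups
#'
#' Linear-scale treatment/reference fold change per gene. The geometric
#' definition (default, standard for microarray intensity summaries) is the
#' anti-log of the difference of group means of log2 intensities,
#' \eqn{2^{\bar y_T - \bar y_R}}; the arithmetic definition is the ratio of
#' linear group means. Zero intensities are replaced by a small positive
#' offset before taking logs.
#'
#' @param expr a \linkS4class{QPExpression}.
#' @param treatment,reference group labels (must exist in the design).
#' @param scale \code{"geometric"} (default) or \code{"arithmetic"}.
#' @param offset positive value substituted for zero intensities under the
#'   geometric scale (default 1.0).
#' @return named numeric vector of per-gene fold changes (> 0).
#' @examples
#' m <- matrix(c(8, 8, 4, 4), nrow = 1,
#'             dimnames = list("g1", paste0("s", 1:4)))
#' expr <- QPExpression(m, c(s1 = "T", s2 = "T", s3 = "M", s4 = "M"))
#' foldChange(expr, "T", "M")  # 2
#' @export
foldChange <- function(expr, treatment, reference,
                       scale = c("geometric", "arithmetic"), offset = 1.0) {
    scale <- match.arg(scale)
    x <- .groupMatrices(expr, treatment, reference)
    if (scale == "geometric") {
        stopifnot(offset > 0)
        tt <- x$t; rr <- x$r
        tt[tt == 0] <- offset
        rr[rr == 0] <- offset
        fc <- 2^(rowMeans(log2(tt)) - rowMeans(log2(rr)))
    } else {
        mr <- rowMeans(x$r)
        if (any(mr == 0))
            stop("all-zero reference under arithmetic scale for gene(s): ",
                 paste(rownames(x$r)[mr == 0], collapse = ", "))
        fc <- rowMeans(x$t) / mr
    }
    fc
}

.groupMatrices <- function(expr, treatment, reference) {
    grp <- groups(expr)
    for (g in c(treatment, reference))
        if (!(g %in% grp)) stop("unknown group label: ", g)
    m <- exprs(expr)
    list(t = m[, grp == treatment, drop = FALSE],
         r = m[, grp == reference, drop = FALSE])
}

#' Per-gene two-group one-way ANOVA on log2 intensities
#'
#' One-way ANOVA of log2 intensity on group, per gene. With two groups the
#' F statistic equals the squared pooled-variance t statistic and the
#' p-value equals the two-sided t-test p-value; the implementation is
#' vectorized over genes but satisfies that identity exactly. Degenerate
#' genes with zero variance in both groups yield p = 1 when group means are
#' equal (p = 0 when they differ).
#'
#' @inheritParams foldChange
#' @param offset positive value substituted for zero intensities before
#'   taking logs.
#' @return named numeric vector of per-gene p-values in [0, 1].
#' @export
deTest <- function(expr, treatment, reference, offset = 1.0) {
    x <- .groupMatrices(expr, treatment, reference)
    tt <- x$t; rr <- x$r
    tt[tt == 0] <- offset
    rr[rr == 0] <- offset
    tt <- log2(tt); rr <- log2(rr)
    n1 <- ncol(tt); n2 <- ncol(rr)
    m1 <- rowMeans(tt); m2 <- rowMeans(rr)
    ss1 <- rowSums((tt - m1)^2); ss2 <- rowSums((rr - m2)^2)
    df2 <- n1 + n2 - 2L
    sp2 <- (ss1 + ss2) / df2
    fstat <- (m1 - m2)^2 / (sp2 * (1 / n1 + 1 / n2))
    p <- stats::pf(fstat, 1L, df2, lower.tail = FALSE)
    degen <- sp2 == 0
    p[degen & (m1 == m2)] <- 1
    p[degen & (m1 != m2)] <- 0
    p
}

#' Call differentially expressed genes
#'
#' Applies the strict fold-change and p-value thresholds: a gene is
#' significant iff \code{p < alpha} AND (\code{FC > fcHigh} OR
#' \code{FC < fcLow}), with direction \code{up} for high fold changes and
#' \code{down} for low ones. Defaults are p < 0.05 and FC > 2 or < 0.5; the
#' inequalities are strict, so FC exactly 2 is not significant.
#'
#' @param fc named numeric vector of per-gene linear fold changes.
#' @param p named numeric vector of per-gene p-values over the same genes.
#' @param alpha p-value threshold (default 0.05).
#' @param fcHigh,fcLow fold-change thresholds (defaults 2.0 and 0.5).
#' @param treatment,reference contrast labels recorded in the result.
#' @return a \linkS4class{DEResult}.
#' @examples
#' callDegs(c(Igf1 = 0.490, Nt5e = 1.640, Nnt = 2.120),
#'          c(Igf1 = 0.013, Nt5e = 0.030, Nnt = 0.001))
#' @export
callDegs <- function(fc, p, alpha = 0.05, fcHigh = 2.0, fcLow = 0.5,
                     treatment = "treatment", reference = "reference") {
    if (length(fc) != length(p) ||
        (!is.null(names(fc)) && !is.null(names(p)) &&
         !identical(names(fc), names(p))))
        stop("fold changes and p-values must cover the same genes")
    genes <- names(fc)
    if (is.null(genes)) genes <- paste0("g", seq_along(fc))
    sig <- (p < alpha) & (fc > fcHigh | fc < fcLow)
    dir <- ifelse(sig & fc > fcHigh, "up",
                  ifelse(sig & fc < fcLow, "down", "none"))
    res <- data.frame(gene = genes, fold_change = unname(fc),
                      log2_fc = unname(log2(fc)), p_value = unname(p),
                      significant = unname(sig), direction = unname(dir),
                      stringsAsFactors = FALSE)
    new("DEResult", treatment = treatment, reference = reference,
        results = res, alpha = alpha, fcHigh = fcHigh, fcLow = fcLow)
}

#' Full differential expression for one contrast
#'
#' Convenience wrapper: [foldChange()] + [deTest()] + [callDegs()].
#'
#' @inheritParams foldChange
#' @inheritParams callDegs
#' @return a \linkS4class{DEResult}.
#' @export
runDE <- function(expr, treatment, reference, alpha = 0.05, fcHigh = 2.0,
                  fcLow = 0.5, scale = c("geometric", "arithmetic"),
                  offset = 1.0) {
    fc <- foldChange(expr, treatment, reference, scale = scale,
                     offset = offset)
    p <- deTest(expr, treatment, reference, offset = offset)
    callDegs(fc, p, alpha = alpha, fcHigh = fcHigh, fcLow = fcLow,
             treatment = treatment, reference = reference)
}
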