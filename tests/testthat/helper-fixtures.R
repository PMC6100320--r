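# Shared fixtures and independent oracles, built in code.

# genes x samples toy expression with two groups of two samples
toyExpression <- function(values = NULL) {
    if (is.null(values))
        values <- matrix(c(8, 8, 4, 4,
                           2, 8, 4, 4,
                           5, 5, 5, 5), nrow = 3, byrow = TRUE)
    dimnames(values) <- list(paste0("g", seq_len(nrow(values))),
                             paste0("s", seq_len(ncol(values))))
    QPExpression(values, stats::setNames(
        rep(c("QJ", "Model"), each = 2), colnames(values)))
}

# random expression for two groups on the log2 scale
randomExpression <- function(nGenes, n1 = 4, n2 = 4, seed = 1,
                             delta = 0) {
    set.seed(seed)
    m <- 2^cbind(matrix(rnorm(nGenes * n1, 8 + delta, 0.5), nGenes),
                 matrix(rnorm(nGenes * n2, 8, 0.5), nGenes))
    dimnames(m) <- list(sprintf("g%03d", seq_len(nGenes)),
                        paste0("s", seq_len(n1 + n2)))
    QPExpression(m, stats::setNames(rep(c("A", "B"), c(n1, n2)),
                                    colnames(m)))
}

writeTempGmt <- function(lines) {
    path <- tempfile(fileext = ".gmt")
    writeLines(lines, path)
    path
}

# random gene set collection for round-trip property tests
randomCollection <- function(seed) {
    set.seed(seed)
    nSets <- sample(2:6, 1)
    genes <- sprintf("gene%03d", 1:60)
    sets <- lapply(seq_len(nSets), function(i)
        sample(genes, sample(3:12, 1)))
    names(sets) <- sprintf("path%02d", seq_len(nSets))
    GeneSetCollection(sets, stats::setNames(
        sprintf("description %d", seq_len(nSets)), names(sets)))
}

# exhaustive enumeration oracle for the hypergeometric upper tail:
# probability that a uniform draw of n from N contains >= k of the K marked
enumHyperTail <- function(k, K, N, n) {
    draws <- utils::combn(N, n)
    mean(colSums(draws <= K) >= k)  # mark elements 1..K
}

# dense MCOA oracle: explicit loops, no shared code with the implementation
denseMcoaLambda1Axis <- function(xs, d, qs, w) {
    n <- nrow(xs[[1]])
    m <- matrix(0, n, n)
    for (k in seq_along(xs)) {
        x <- xs[[k]]; q <- qs[[k]]
        for (i in seq_len(n)) for (j in seq_len(n)) {
            acc <- 0
            for (g in seq_len(ncol(x)))
                acc <- acc + x[i, g] * q[g] * x[j, g]
            m[i, j] <- m[i, j] + w[k] * acc
        }
    }
    ms <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
        ms[i, j] <- sqrt(d[i]) * m[i, j] * sqrt(d[j])
    eigen((ms + t(ms)) / 2, symmetric = TRUE)
}

# random statistical triplets on shared rows
randomTriplets <- function(n, ps, seed, center = TRUE) {
    set.seed(seed)
    d <- rep(1 / n, n)
    lapply(seq_along(ps), function(k) {
        x <- matrix(rnorm(n * ps[k]), n, ps[k])
        if (center) x <- sweep(x, 2, colMeans(x), "-")
        rownames(x) <- sprintf("P%02d", seq_len(n))
        new("StatisticalTriplet", table = x, rowWeights = d,
            colWeights = rep(1 / ps[k], ps[k]),
            tableName = paste0("T", k), preprocessing = "log_center")
    })
}

# profile built directly from a membership layout and per-gene fold changes
profileFromValues <- function(lfc, memb, treatment = "T") {
    v <- matrix(1, nrow(memb), ncol(memb), dimnames = dimnames(memb))
    v[memb] <- (2^lfc)[row(v)[memb]]
    new("PathwayProfile", treatment = treatment, values = v,
        membership = memb, allowEmpty = TRUE)
}

# block-diagonal membership: nPath disjoint pathways of size m
blockMembership <- function(nPath, m) {
    genes <- sprintf("g%03d", seq_len(nPath * m))
    memb <- matrix(FALSE, length(genes), nPath,
                   dimnames = list(genes, sprintf("P%02d", seq_len(nPath))))
    for (j in seq_len(nPath)) memb[(j - 1) * m + seq_len(m), j] <- TRUE
    memb
}

# full pipeline from a scenario draw to a tested divergence table
scenarioDivergence <- function(scenario, seed, B = 199, mode = "union") {
    sim <- generateExpression(scenario, seed = seed)
    trs <- scenario@treatments
    de <- lapply(trs, function(tr) runDE(sim$expr, tr, scenario@reference))
    names(de) <- trs
    en <- lapply(de, enrichPathways, sets = sim$sets)
    cp <- commonPathways(en, mode = mode)
    pr <- lapply(de, buildProfile, sets = sim$sets, pathways = cp,
                 allowEmpty = TRUE)
    suppressWarnings(suppressMessages(
        permutationTest(pr, B = B, seed = seed + 1000)))
}
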