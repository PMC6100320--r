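test_that("log-center preprocessing maps neutral cells to zero", {
    memb <- blockMembership(3, 4)
    lfc <- rep(c(1.084, -1.2, 0.8), each = 4)  # log2(2.120) = 1.084
    pr <- profileFromValues(c(lfc), memb)
    tr <- preprocessProfile(pr)
    expect_equal(dim(tr@table), c(3L, 12L))  # pathways x genes
    # before centering a non-member cell is log2(1) = 0; with uniform D the
    # centered value of a member cell is log2(fc) minus the column mean
    x <- t(log2(profileValues(pr)))
    expect_equal(tr@table, sweep(x, 2, colMeans(x), "-"))
    expect_equal(log2(2.120), 1.084, tolerance = 1e-3)
    # a constant column centers to zero
    expect_true(all(abs(tr@table[, colSums(t(memb)) == 0]) < 1e-12))
})

test_that("nsc preprocessing uses row masses and column-mass centering", {
    memb <- blockMembership(3, 4)
    pr <- profileFromValues(rep(1.5, 12), memb)
    tr <- preprocessProfile(pr, method = "nsc")
    x <- t(profileValues(pr)) / sum(profileValues(pr))
    r <- rowSums(x)
    expect_equal(tr@rowWeights, unname(r))
    expect_equal(tr@table, sweep(x / r, 2, colSums(x), "-"))
})

test_that("single-table MCOA reduces to the SVD of the weighted table", {
    tr <- randomTriplets(7, 5, seed = 21)
    res <- mcoa(tr, nAxes = 3, weighting = "uniform")
    x <- tr[[1]]@table
    sv <- svd(x)
    n <- nrow(x); p <- ncol(x)
    # eigenvalues are squared singular values scaled by the weights
    expect_equal(eigenvalues(res), (sv$d[1:3]^2) / (n * p),
                 tolerance = 1e-10)
    for (f in 1:3) {
        r <- abs(stats::cor(syntheticScores(res)[, f], sv$u[, f]))
        expect_gt(r, 0.999999)
        r2 <- abs(stats::cor(tableScores(res)[[1]][, f], sv$u[, f]))
        expect_gt(r2, 0.999999)
    }
})

test_that("identical tables coincide in the common space", {
    tr1 <- randomTriplets(6, 4, seed = 22)[[1]]
    trs <- lapply(c("A", "B", "C"), function(nm) {
        t2 <- tr1; t2@tableName <- nm; t2
    })
    res <- mcoa(trs, nAxes = 2, weighting = "uniform")
    sc <- tableScores(res)
    expect_lt(max(abs(sc[[1]] - sc[[2]])), 1e-10)
    expect_lt(max(abs(sc[[2]] - sc[[3]])), 1e-10)
})

test_that("axis-1 criterion matches a dense explicit-loop oracle and beats
           random probes", {
    for (seed in 1:12) {
        set.seed(seed * 100)
        n <- sample(4:8, 1)
        kk <- sample(1:3, 1)
        ps <- sample(3:6, kk, replace = TRUE)
        tr <- randomTriplets(n, ps, seed = seed)
        w <- rep(1, kk)
        res <- mcoa(tr, nAxes = 2, weighting = "uniform")
        ev <- denseMcoaLambda1Axis(lapply(tr, slot, "table"),
                                   tr[[1]]@rowWeights,
                                   lapply(tr, slot, "colWeights"), w)
        expect_equal(eigenvalues(res)[1], ev$values[1], tolerance = 1e-10)
        # brute-force probes never beat the maximizer
        d <- tr[[1]]@rowWeights
        ms <- outer(sqrt(d), sqrt(d)) *
            Reduce(`+`, Map(function(t1, wk)
                wk * tcrossprod(sweep(t1@table, 2, t1@colWeights, "*"),
                                t1@table), tr, w))
        probes <- matrix(rnorm(2000 * n), 2000, n)
        probes <- probes / sqrt(rowSums(probes^2))
        crit <- rowSums((probes %*% ms) * probes)
        expect_true(all(crit <= eigenvalues(res)[1] + 1e-10))
        expect_equal(max(eigenvalues(res)[1],
                         drop(crossprod(ev$vectors[, 1],
                                        ms %*% ev$vectors[, 1]))),
                     eigenvalues(res)[1], tolerance = 1e-10)
    }
})

test_that("the co-inertia criterion identity holds on every axis", {
    tr <- randomTriplets(8, c(5, 6, 4), seed = 30)
    for (wt in c("lambda1", "uniform")) {
        res <- mcoa(tr, nAxes = 4, weighting = wt)
        d <- res@rowWeights
        for (f in seq_along(eigenvalues(res))) {
            v <- syntheticScores(res)[, f]
            crit <- sum(vapply(seq_along(tr), function(k)
                res@tableWeights[k] *
                    sum(tableScores(res)[[k]][, f] * d * v)^2,
                numeric(1)))
            expect_equal(crit, eigenvalues(res)[f], tolerance = 1e-8)
        }
        # D-orthonormal synthetic axes, non-increasing eigenvalues
        g <- crossprod(syntheticScores(res), d * syntheticScores(res))
        expect_equal(g, diag(ncol(g)), tolerance = 1e-8,
                     ignore_attr = TRUE)
        expect_true(all(diff(eigenvalues(res)) <= 1e-10))
    }
})

test_that("permuting pathway rows permutes all scores identically", {
    tr <- randomTriplets(6, c(4, 5), seed = 31)
    res <- mcoa(tr, nAxes = 2)
    set.seed(31)
    perm <- sample(6)
    trp <- lapply(tr, function(t1) {
        t1@table <- t1@table[perm, , drop = FALSE]
        t1
    })
    resp <- mcoa(trp, nAxes = 2)
    expect_equal(abs(syntheticScores(resp)),
                 abs(syntheticScores(res)[perm, ]), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(abs(tableScores(resp)[[1]]),
                 abs(tableScores(res)[[1]][perm, ]), tolerance = 1e-8,
                 ignore_attr = TRUE)
})

test_that("lambda1 weighting makes scores invariant to table rescaling", {
    tr <- randomTriplets(6, c(4, 5), seed = 32)
    res <- mcoa(tr, nAxes = 2, weighting = "lambda1")
    tr2 <- tr
    tr2[[1]]@table <- 7 * tr2[[1]]@table
    res2 <- mcoa(tr2, nAxes = 2, weighting = "lambda1")
    expect_equal(syntheticScores(res2), syntheticScores(res),
                 tolerance = 1e-8)
    expect_equal(eigenvalues(res2), eigenvalues(res), tolerance = 1e-8)
    # under uniform weighting the rescaled table dominates instead
    resu <- mcoa(tr, nAxes = 1, weighting = "uniform")
    resu2 <- mcoa(tr2, nAxes = 1, weighting = "uniform")
    expect_gt(eigenvalues(resu2)[1], eigenvalues(resu)[1])
})

test_that("axes beyond the numerical rank are truncated with a warning", {
    x <- matrix(rnorm(6), 6, 1)
    x <- sweep(x %*% t(c(1, 1)), 2, colMeans(x %*% t(c(1, 1))), "-")
    rownames(x) <- sprintf("P%02d", 1:6)
    tr <- new("StatisticalTriplet", table = x, rowWeights = rep(1/6, 6),
              colWeights = rep(1/2, 2), tableName = "A",
              preprocessing = "log_center")
    expect_warning(res <- mcoa(list(tr), nAxes = 4), "rank")
    expect_lt(length(eigenvalues(res)), 4L)
    zero <- tr; zero@table <- matrix(0, 6, 2,
                                     dimnames = list(rownames(x), NULL))
    expect_error(suppressWarnings(mcoa(list(zero), nAxes = 1)), "zero")
})

test_that("mismatched pathway rows across tables are rejected", {
    tr <- randomTriplets(6, c(4, 4), seed = 33)
    rownames(tr[[2]]@table)[6] <- "P99"
    expect_error(mcoa(tr, nAxes = 2), "P99")
})

test_that("pathway projection returns table and synthetic points", {
    tr <- randomTriplets(5, c(4, 3), seed = 34)
    res <- mcoa(tr, nAxes = 2)
    prj <- projectPathways(res)
    expect_setequal(unique(prj$table), c("synthetic", "T1", "T2"))
    expect_equal(nrow(prj), 15L)
    std <- projectPathways(res, standardize = TRUE)
    expect_equal(std$Axis1[std$table == "T1"],
                 tableScores(res)[[1]][, 1] / sqrt(eigenvalues(res)[1]),
                 ignore_attr = TRUE)
    expect_error(projectPathways(res, nAxes = 5), "5")
})
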