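test_that("identical tables give zero divergence and p = 1 everywhere", {
    set.seed(40)
    memb <- blockMembership(6, 5)
    lfc <- rnorm(nrow(memb), 1.8, 0.3)
    profiles <- lapply(c("A", "B", "C"), function(nm)
        profileFromValues(lfc, memb, treatment = nm))
    tr <- lapply(profiles, preprocessProfile)
    res <- mcoa(tr, nAxes = 2, weighting = "uniform")
    dv <- divergenceScores(res)
    expect_lt(max(divergence(dv)$distance), 1e-9)
    pt <- suppressWarnings(permutationTest(profiles, B = 99, seed = 1))
    expect_true(all(divergence(pt)$p_value == 1))
    expect_false(any(divergence(pt)$different))
})

test_that("divergence is symmetric in the table labels", {
    set.seed(41)
    memb <- blockMembership(6, 5)
    p1 <- profileFromValues(rnorm(30, 1.6, 0.3), memb, "A")
    p2 <- profileFromValues(rnorm(30, 1.6, 0.3), memb, "B")
    r12 <- mcoa(lapply(list(p1, p2), preprocessProfile), nAxes = 2)
    r21 <- mcoa(lapply(list(p2, p1), preprocessProfile), nAxes = 2)
    d12 <- divergence(divergenceScores(r12))
    d21 <- divergence(divergenceScores(r21))
    expect_equal(d12$distance[order(d12$pathway)],
                 d21$distance[order(d21$pathway)], tolerance = 1e-9)
})

test_that("a sign inversion on disjoint support leaves the common-space
           scores invariant (the method's documented blind spot)", {
    # the per-table scores are quadratic forms, so flipping every member
    # fold change of one pathway (FC -> 1/FC) cancels exactly when its
    # genes are shared with no other pathway
    set.seed(44)
    memb <- blockMembership(6, 5)
    lfc <- rnorm(30, 1.5, 0.3)
    lfc2 <- lfc
    lfc2[memb[, "P03"]] <- -lfc2[memb[, "P03"]]
    p1 <- profileFromValues(lfc, memb, "A")
    p2 <- profileFromValues(lfc2, memb, "B")
    res <- mcoa(lapply(list(p1, p2), preprocessProfile), nAxes = 2)
    ov <- divergenceScores(res)@overall
    expect_lt(max(ov$mean_distance), 1e-9)
})

test_that("an amplitude-divergent pathway attains the maximum divergence", {
    # table B loses the response that table A carries on one pathway;
    # that pathway must show the largest inter-table point spread
    hits <- 0L
    reps <- 50L
    for (seed in seq_len(reps)) {
        set.seed(seed)
        memb <- blockMembership(8, 6)
        lfcA <- rnorm(48, 1.5, 0.2)
        lfcA[memb[, "P03"]] <- rnorm(6, 3, 0.2)
        lfcB <- lfcA + rnorm(48, 0, 0.2)
        lfcB[memb[, "P03"]] <- rnorm(6, 0, 0.2)
        pA <- profileFromValues(lfcA, memb, "A")
        pB <- profileFromValues(lfcB, memb, "B")
        res <- mcoa(lapply(list(pA, pB), preprocessProfile), nAxes = 2)
        ov <- divergenceScores(res)@overall
        hits <- hits + (ov$pathway[which.max(ov$mean_distance)] == "P03")
    }
    expect_gte(hits / reps, 0.9)
})

test_that("stronger planted discordance never reduces the mean divergence
           score", {
    # effect grid: the divergent pathway's response in table B shrinks from
    # concordant (3) to absent (0) while table A stays at 3
    grid <- c(3, 2.25, 1.5, 0.75, 0)
    for (seed in 1:5) {
        set.seed(seed + 50)
        memb <- blockMembership(8, 6)
        base <- rnorm(48, 1.5, 0.1)
        base[memb[, "P05"]] <- rnorm(6, 3, 0.1)
        dmean <- vapply(grid, function(eb) {
            lfcB <- base + rnorm(48, 0, 0.1)
            lfcB[memb[, "P05"]] <- eb + rnorm(sum(memb[, "P05"]), 0, 0.1)
            pA <- profileFromValues(base, memb, "A")
            pB <- profileFromValues(lfcB, memb, "B")
            res <- mcoa(lapply(list(pA, pB), preprocessProfile),
                        nAxes = 2, weighting = "uniform")
            ov <- divergenceScores(res)@overall
            ov$mean_distance[ov$pathway == "P05"]
        }, numeric(1))
        # allow small noise wiggle, require the trend
        expect_gt(dmean[length(grid)], dmean[1])
        expect_true(all(diff(dmean) > -0.25 * max(dmean)))
    }
})

test_that("permutation p-values are reproducible and respect their bounds", {
    sc <- nullScenario()
    pt1 <- scenarioDivergence(sc, seed = 5, B = 99)
    pt2 <- scenarioDivergence(sc, seed = 5, B = 99)
    expect_identical(divergence(pt1), divergence(pt2))  # bit identical
    p <- divergence(pt1)$p_value
    expect_true(all(p >= 1 / 100 & p <= 1))
    expect_error(permutationTest(list(), B = 99))
    memb <- blockMembership(1, 4)
    pr <- profileFromValues(rep(1.5, 4), memb)
    expect_error(permutationTest(list(pr, pr), B = 99, seed = 1),
                 "2 pathways")
    expect_warning(try(permutationTest(list(pr, pr), B = 99, seed = 1,
                                       alpha = 0.001), silent = TRUE),
                   "too small")
})

test_that("the pairwise report lists differing pathways per pair", {
    sc <- threeArmScenario()
    pt <- scenarioDivergence(sc, seed = 2, B = 99)
    rep <- pairwiseGroupReport(pt)
    expect_equal(nrow(rep), 3L)
    expect_setequal(paste(rep$table1, rep$table2),
                    c("QJ WYH", "QSG QJ", "QSG WYH"))
    expect_true(all(rep$n_tested == 20L))
    dv <- divergenceScores(mcoa(lapply(list(
        profileFromValues(rep(1.5, 20), blockMembership(4, 5), "A"),
        profileFromValues(rep(1.5, 20), blockMembership(4, 5), "B")),
        preprocessProfile), nAxes = 2))
    expect_error(pairwiseGroupReport(dv), "no permutation")
})

test_that("single-pair input yields a single-pair report", {
    sc <- nullScenario()
    pt <- scenarioDivergence(sc, seed = 9, B = 99)
    rep <- pairwiseGroupReport(pt)
    expect_equal(nrow(rep), 1L)
    expect_equal(c(rep$table1, rep$table2), c("T1", "T2"))
})
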