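test_that("disjoint gene sets partition the requested genes", {
    gsc <- generateGeneSets(100, nPathways = 10, setSize = 8,
                            overlap = 0, seed = 3)
    sets <- geneSets(gsc)
    expect_length(sets, 10L)
    expect_true(all(lengths(sets) == 8L))
    expect_length(unique(unlist(sets)), 80L)  # fully disjoint
    expect_length(universe(gsc), 100L)
    expect_error(generateGeneSets(50, 10, 8, seed = 1), "universe")
})

test_that("the overlap fraction is calibrated on the pairwise Jaccard", {
    jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
    meanJ <- vapply(1:100, function(seed) {
        sets <- geneSets(generateGeneSets(200, 8, 10, overlap = 0.5,
                                          seed = seed))
        pairs <- utils::combn(length(sets), 2)
        mean(apply(pairs, 2, function(ij)
            jac(sets[[ij[1]]], sets[[ij[2]]])))
    }, numeric(1))
    expect_gte(mean(meanJ), 0.2)
    expect_lte(mean(meanJ), 0.5)
})

test_that("generation is deterministic under a fixed seed", {
    g1 <- generateGeneSets(150, 10, 8, overlap = 0.25, seed = 11)
    g2 <- generateGeneSets(150, 10, 8, overlap = 0.25, seed = 11)
    expect_identical(geneSets(g1), geneSets(g2))
    sim1 <- generateExpression(nullScenario(), seed = 4)
    sim2 <- generateExpression(nullScenario(), seed = 4)
    expect_identical(exprs(sim1$expr), exprs(sim2$expr))
    expect_identical(sim1$truth, sim2$truth)
})

test_that("private core groups share exactly their core block", {
    gsc <- generateGeneSets(200, 10, 12, overlap = 0,
                            coreGroups = list(c("P02", "P05", "P08")),
                            coreSize = 6, seed = 7)
    sets <- geneSets(gsc)
    core <- Reduce(intersect, sets[c("P02", "P05", "P08")])
    expect_length(core, 6L)
    expect_true(all(lengths(sets) == 12L))
    expect_length(intersect(sets$P01, sets$P02), 0L)
})

test_that("zero noise and zero effects give fold change 1 and no DEGs", {
    sc <- SimulationScenario(nGenes = 60, nPerGroup = 3,
                             treatments = c("T1", "T2"), nPathways = 4,
                             setSize = 6,
                             effects = matrix(0, 2, 4), noiseSd = 1e-9)
    sim <- generateExpression(sc, seed = 1)
    fc <- foldChange(sim$expr, "T1", "Model")
    expect_equal(unname(fc), rep(1, 60), tolerance = 1e-6)
    de <- runDE(sim$expr, "T1", "Model")
    expect_length(degs(de), 0L)
})

test_that("planted effects are recovered within sampling error", {
    # +1.5 log2 on one pathway, noise 0.25, n = 5: the estimated log2 FC
    # of exclusive members lands within 1.5 +/- 0.4 nearly always
    eff <- matrix(c(1.5, 0, 0, 0), 1, 4, dimnames = list("T1", NULL))
    sc <- SimulationScenario(nGenes = 80, nPerGroup = 5,
                             treatments = "T1", nPathways = 4,
                             setSize = 8, effects = eff, noiseSd = 0.25)
    hit <- 0L; total <- 0L
    for (seed in 1:100) {
        sim <- generateExpression(sc, seed = seed)
        members <- geneSets(sim$sets)$P01
        lfc <- log2(foldChange(sim$expr, "T1", "Model"))[members]
        hit <- hit + sum(abs(lfc - 1.5) <= 0.4)
        total <- total + length(lfc)
    }
    expect_gte(hit / total, 0.95)
})

test_that("ground truth marks pairs divergent per the effect threshold", {
    eff <- matrix(c(1, 1, 0,
                    1, 2.5, 0), 2, 3, byrow = TRUE,
                  dimnames = list(c("T1", "T2"), NULL))
    sc <- SimulationScenario(nGenes = 80, nPerGroup = 3,
                             treatments = c("T1", "T2"), nPathways = 3,
                             setSize = 6, effects = eff, noiseSd = 0.2,
                             divergenceThreshold = 1)
    sim <- generateExpression(sc, seed = 2)
    div <- sim$truth$divergent
    expect_equal(div$divergent, c(FALSE, TRUE, FALSE))
    # true per-gene log2 fold changes follow the membership sums
    members <- geneSets(sim$sets)$P02
    expect_true(all(sim$truth$log2fc[members, "T2"] == 2.5))
})

test_that("the three-arm scenario encodes the designed ground truth", {
    sc <- threeArmScenario()
    sim <- generateExpression(sc, seed = 1)
    div <- sim$truth$divergent
    qw <- div[div$table1 == "QJ" & div$table2 == "WYH", ]
    expect_equal(sort(qw$pathway[qw$divergent]),
                 c("P04", "P10", "P16"))
    qsg <- div[div$table1 == "QSG" | div$table2 == "QSG", ]
    expect_false(any(qsg$divergent))
    expect_equal(sum(div$divergent), 3L)
})

test_that("the null scenario plants no divergence but plenty of DEGs", {
    sc <- nullScenario()
    sim <- generateExpression(sc, seed = 3)
    expect_false(any(sim$truth$divergent$divergent))
    de <- runDE(sim$expr, "T1", "Model")
    expect_gte(length(degs(de)), 70L)  # ~80 member genes all respond
})
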