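#' Construct a simulation scenario
#'
#' @param nGenes universe size.
#' @param nPerGroup samples per group.
#' @param reference reference (model) group label.
#' @param treatments character vector of treatment labels.
#' @param nPathways,setSize gene-set layout.
#' @param overlap fraction of each set drawn from a core block shared by
#'   all sets (0 = disjoint sets).
#' @param coreGroups,coreSize optional private-core layout passed to
#'   [generateGeneSets()].
#' @param effects treatments x pathways matrix of planted log2 effects
#'   added to member genes (rownames = treatments); overlapping pathways
#'   sum their effects on shared genes.
#' @param noiseSd per-observation log2 noise sd (> 0).
#' @param baselineRange range of per-gene log2 baseline means.
#' @param divergenceThreshold tau: a (pathway, treatment pair) is
#'   ground-truth divergent iff the absolute difference of planted effects
#'   is >= tau. The near-zero default makes any difference divergent.
#' @param seed default generation seed.
#' @return a validated \linkS4class{SimulationScenario}.
#' @export
SimulationScenario <- function(nGenes, nPerGroup, reference = "Model",
                               treatments, nPathways, setSize,
                               overlap = 0, coreGroups = list(),
                               coreSize = 0L, effects, noiseSd = 0.25,
                               baselineRange = c(6, 12),
                               divergenceThreshold = 1e-8, seed = 1L) {
    effects <- as.matrix(effects)
    if (is.null(rownames(effects))) rownames(effects) <- treatments
    if (is.null(colnames(effects)))
        colnames(effects) <- sprintf("P%02d", seq_len(ncol(effects)))
    new("SimulationScenario", nGenes = as.integer(nGenes),
        nPerGroup = as.integer(nPerGroup), reference = reference,
        treatments = treatments, nPathways = as.integer(nPathways),
        setSize = as.integer(setSize), overlap = overlap,
        coreGroups = coreGroups, coreSize = as.integer(coreSize),
        effects = effects, noiseSd = noiseSd,
        baselineRange = baselineRange,
        divergenceThreshold = divergenceThreshold, seed = as.integer(seed))
}

#' Generate a gene set collection with controlled overlap
#'
#' Draws \code{nPathways} sets of \code{setSize} genes from a universe of
#' \code{nGenes}. A core block of \code{round(overlap * setSize)} genes is
#' shared by every set; the remaining members are drawn without replacement
#' from the rest of the universe, so sets are pairwise disjoint outside the
#' core. \code{overlap = 0} gives fully disjoint sets; \code{overlap = 0.5}
#' gives a pairwise Jaccard index of about 1/3. In addition,
#' \code{coreGroups} can name groups of pathways that share a private core
#' of \code{coreSize} genes (replacing that many of their own members) —
#' this emulates the dense local sharing of related pathways in curated
#' collections. Deterministic given \code{seed}.
#'
#' @param nGenes universe size (genes are labelled g0001, g0002, ...).
#' @param nPathways,setSize layout.
#' @param overlap global core fraction in [0, 1).
#' @param coreGroups list of character vectors of pathway ids; pathways in
#'   one group share a private core block.
#' @param coreSize number of genes in each private core block.
#' @param seed integer seed.
#' @return a \linkS4class{GeneSetCollection} whose universe is the full
#'   gene panel.
#' @export
generateGeneSets <- function(nGenes, nPathways, setSize, overlap = 0,
                             coreGroups = list(), coreSize = 0L,
                             seed = 1L) {
    stopifnot(overlap >= 0, overlap < 1, coreSize >= 0,
              coreSize < setSize)
    nCore <- as.integer(round(overlap * setSize))
    nOwn <- setSize - nCore
    ids <- sprintf("P%02d", seq_len(nPathways))
    grouped <- unlist(coreGroups, use.names = FALSE)
    if (anyDuplicated(grouped) || !all(grouped %in% ids))
        stop("coreGroups must name distinct, existing pathway ids")
    need <- nCore + nPathways * nOwn + length(coreGroups) * coreSize -
        length(grouped) * coreSize
    if (need > nGenes)
        stop("requested sets need ", need,
             " genes but the universe has only ", nGenes)
    set.seed(seed)
    genes <- sprintf("g%04d", seq_len(nGenes))
    pool <- sample(genes)
    take <- function(k) {
        out <- pool[seq_len(k)]
        pool <<- pool[-seq_len(k)]
        out
    }
    core <- if (nCore > 0) take(nCore) else character(0)
    groupCore <- lapply(coreGroups, function(g) take(coreSize))
    groupOf <- stats::setNames(rep(NA_integer_, nPathways), ids)
    for (gi in seq_along(coreGroups)) groupOf[coreGroups[[gi]]] <- gi
    sets <- lapply(ids, function(id) {
        gi <- groupOf[[id]]
        own <- take(nOwn - (if (is.na(gi)) 0L else coreSize))
        sort(c(core, if (!is.na(gi)) groupCore[[gi]], own))
    })
    names(sets) <- ids
    GeneSetCollection(sets, universe = genes)
}

#' Generate expression data with planted pathway effects
#'
#' Log-normal intensity model: for gene g in group t, log2 intensity =
#' baseline_g + effect(t, g) + N(0, noiseSd^2), exported on the linear
#' scale. effect(t, g) is the sum of the planted log2 effects of the
#' pathways containing g for treatment t (0 for the reference group and
#' for non-member genes). Baselines are uniform over
#' \code{baselineRange}. Deterministic given the seed.
#'
#' @param scenario a \linkS4class{SimulationScenario}.
#' @param seed overrides the scenario's seed when given.
#' @return list with elements \code{expr} (\linkS4class{QPExpression}),
#'   \code{sets} (\linkS4class{GeneSetCollection}) and \code{truth}, a list
#'   holding \code{log2fc} (genes x treatments true log2 fold changes) and
#'   \code{divergent}, a data.frame (pathway, table1, table2, divergent)
#'   with divergent = |effect difference| >= the scenario's tau.
#' @export
generateExpression <- function(scenario, seed = NULL) {
    stopifnot(is(scenario, "SimulationScenario"))
    if (is.null(seed)) seed <- scenario@seed
    sets <- generateGeneSets(scenario@nGenes, scenario@nPathways,
                             scenario@setSize, scenario@overlap,
                             coreGroups = scenario@coreGroups,
                             coreSize = scenario@coreSize, seed = seed)
    set.seed(seed + 1L)
    genes <- universe(sets)
    nG <- length(genes)
    baseline <- stats::runif(nG, scenario@baselineRange[1L],
                             scenario@baselineRange[2L])
    memb <- vapply(geneSets(sets), function(m) genes %in% m,
                   logical(nG))  # genes x pathways
    rownames(memb) <- genes
    eff <- memb %*% t(scenario@effects)  # genes x treatments
    groupsAll <- c(scenario@reference, scenario@treatments)
    n <- scenario@nPerGroup
    sampleIds <- unlist(lapply(groupsAll, function(g)
        sprintf("%s_%d", g, seq_len(n))))
    design <- stats::setNames(rep(groupsAll, each = n), sampleIds)
    mu <- cbind(0, eff)  # reference first
    colnames(mu) <- groupsAll
    lg <- mu[, rep(groupsAll, each = n)] +
        matrix(stats::rnorm(nG * length(sampleIds), 0, scenario@noiseSd),
               nG)
    lg <- baseline + lg
    vals <- 2^lg
    dimnames(vals) <- list(genes, sampleIds)
    tr <- scenario@treatments
    div <- NULL
    if (length(tr) >= 2L) {
        pr <- which(upper.tri(matrix(0, length(tr), length(tr))),
                    arr.ind = TRUE)
        div <- do.call(rbind, lapply(seq_len(nrow(pr)), function(r) {
            dd <- abs(scenario@effects[pr[r, 1L], ] -
                      scenario@effects[pr[r, 2L], ])
            data.frame(pathway = colnames(scenario@effects),
                       table1 = tr[pr[r, 1L]], table2 = tr[pr[r, 2L]],
                       divergent = dd >= scenario@divergenceThreshold,
                       stringsAsFactors = FALSE)
        }))
        rownames(div) <- NULL
    }
    list(expr = QPExpression(vals, design), sets = sets,
         truth = list(log2fc = eff, divergent = div))
}

#' Three-arm scenario: a full formula and two decomposed recipes
#'
#' Canned scenario emulating the comparison of a complete multi-herb
#' formula (QSG) with its two decomposed recipes (QJ and WYH) against an
#' untreated disease model: 20 pathways of 12 genes in a 400-gene
#' universe, 5 samples per group, log2 noise sd 0.45. Seventeen
#' concordant pathways (disjoint gene sets) carry the same planted effect
#' in all three treatments, with alternating sign and magnitudes spanning
#' 1.3-2.1 log2 units. Exactly three pathways (P04, P10, P16) are planted
#' divergent between the two recipes through response amplitude: one
#' recipe (QJ) responds strongly (+2.2 log2 on members), the other (WYH)
#' more weakly (+1.3), and the full formula at the intermediate
#' root-mean-square strength (+1.81), so its pathway positions sit midway
#' between the recipes in the co-inertia geometry. The three divergent
#' pathways share a private 6-gene core (the dense local sharing typical
#' of related pathways in curated collections), whose genes accumulate
#' the summed effect of the three memberships - strong hub-like
#' responders. With the scenario's divergence threshold tau = 0.75 the
#' ground truth marks those three pathways divergent for the QJ/WYH pair
#' only (|2.2 - 1.3| >= 0.75) and no pathway divergent for either QSG
#' pair (|0.39| and |0.51| < 0.75).
#'
#' @param seed default generation seed (default 20).
#' @return a \linkS4class{SimulationScenario}.
#' @export
threeArmScenario <- function(seed = 20L) {
    nPath <- 20L
    pathways <- sprintf("P%02d", seq_len(nPath))
    divergent <- c("P04", "P10", "P16")
    conc <- setdiff(pathways, divergent)
    mag <- seq(1.3, 2.1, length.out = length(conc))
    sgn <- rep(c(1, -1), length.out = length(conc))
    eff <- matrix(0, 3L, nPath,
                  dimnames = list(c("QSG", "QJ", "WYH"), pathways))
    eff[, conc] <- rep(mag * sgn, each = 3L)
    eff["QJ", divergent] <- 2.2
    eff["WYH", divergent] <- 1.3
    eff["QSG", divergent] <- sqrt((2.2^2 + 1.3^2) / 2)
    SimulationScenario(nGenes = 400L, nPerGroup = 5L, reference = "Model",
                       treatments = c("QSG", "QJ", "WYH"),
                       nPathways = nPath, setSize = 12L, overlap = 0,
                       coreGroups = list(divergent), coreSize = 6L,
                       effects = eff, noiseSd = 0.45,
                       baselineRange = c(6, 12),
                       divergenceThreshold = 0.75,
                       seed = as.integer(seed))
}

#' Null scenario: two treatments with no planted divergence
#'
#' Every (treatment, pathway) pair carries the same +2.5 log2 planted
#' effect, so every member gene is unambiguously differentially expressed
#' in both contrasts (the fold-change threshold sits many standard errors
#' below the planted effect, so the DEG selection never couples a gene's
#' presence to its value) and member fold changes are exchangeable across
#' pathways within each table - the exact null of the permutation
#' divergence test. 10 disjoint pathways of 8 genes in a 150-gene
#' universe, 4 samples per group.
#'
#' @param seed default generation seed (default 7).
#' @return a \linkS4class{SimulationScenario}.
#' @export
nullScenario <- function(seed = 7L) {
    nPath <- 10L
    eff <- matrix(2.5, 2L, nPath,
                  dimnames = list(c("T1", "T2"),
                                  sprintf("P%02d", seq_len(nPath))))
    SimulationScenario(nGenes = 150L, nPerGroup = 4L, reference = "Model",
                       treatments = c("T1", "T2"), nPathways = nPath,
                       setSize = 8L, overlap = 0, effects = eff,
                       noiseSd = 0.25, baselineRange = c(6, 12),
                       seed = as.integer(seed))
}
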