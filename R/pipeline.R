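#' Run the full quantitative pathway analysis pipeline
#'
#' Ties the stages together: read (or simulate) expression data, call DEGs
#' per contrast, score pathway enrichment, pick the common pathway set,
#' build the per-treatment profile tables, co-project them by MCOA, and run
#' the permutation divergence test with a per-pair report. Every stage
#' writes its TSV outputs into \code{outdir} as it completes (so a failed
#' run retains the finished stages' files), and a machine-readable JSON
#' manifest with the config echo, seed, package version and per-stage row
#' counts is written at the end.
#'
#' @param config either a path to a YAML file or a list with entries:
#'   \describe{
#'     \item{expression, design, gmt}{input paths (omit when
#'       \code{scenario} is given).}
#'     \item{scenario}{optional: \code{"three_arm"} or \code{"null"} to
#'       simulate instead of reading files.}
#'     \item{reference}{reference group label (default \code{"Model"}).}
#'     \item{treatments}{treatment labels; default: all non-reference
#'       groups.}
#'     \item{alpha, fc_high, fc_low}{DEG thresholds (0.05, 2, 0.5).}
#'     \item{enrichment_alpha, common_mode}{enrichment cutoff (0.05) and
#'       \code{"intersection"}/\code{"union"} (default intersection).}
#'     \item{axes, weighting, preprocess}{MCOA settings (2,
#'       \code{"lambda1"}, \code{"log_center"}).}
#'     \item{permutations, divergence_alpha}{B (999) and call level
#'       (0.05).}
#'     \item{seed}{integer seed (default 1).}
#'     \item{outdir}{output directory (required).}
#'   }
#' @param outdir overrides \code{config$outdir} when given.
#' @return invisibly, a list with the in-memory stage results
#'   (\code{de}, \code{enrichment}, \code{common}, \code{profiles},
#'   \code{mcia}, \code{divergence}, \code{report}, \code{manifest}).
#' @export
runPipeline <- function(config, outdir = NULL) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    stopifnot(is.list(config))
    cfg <- utils::modifyList(list(reference = "Model", alpha = 0.05,
        fc_high = 2, fc_low = 0.5, enrichment_alpha = 0.05,
        common_mode = "intersection", axes = 2L, weighting = "lambda1",
        preprocess = "log_center", permutations = 999L,
        divergence_alpha = 0.05, seed = 1L, scale = "geometric"), config)
    if (!is.null(outdir)) cfg$outdir <- outdir
    if (is.null(cfg$outdir)) stop("config must name an output directory")
    stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$fc_high > 1,
              cfg$fc_low > 0, cfg$fc_low < 1, cfg$axes >= 1,
              cfg$permutations >= 99)
    cfg$seed <- as.integer(cfg$seed)
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    counts <- list()
    stage <- function(name, fun) {
        message("[", name, "] ...")
        tryCatch(fun(), error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    inputs <- stage("input", function() {
        if (!is.null(cfg$scenario)) {
            sc <- switch(cfg$scenario,
                         three_arm = threeArmScenario(),
                         null = nullScenario(),
                         stop("unknown scenario '", cfg$scenario, "'"))
            sim <- generateExpression(sc, seed = cfg$seed)
            list(expr = sim$expr, sets = sim$sets, truth = sim$truth)
        } else {
            if (is.null(cfg$expression) || is.null(cfg$design) ||
                is.null(cfg$gmt))
                stop("config needs 'expression', 'design' and 'gmt' paths ",
                     "(or a 'scenario')")
            list(expr = readExpression(cfg$expression, cfg$design),
                 sets = readGmt(cfg$gmt), truth = NULL)
        }
    })
    expr <- inputs$expr
    grp <- unique(groups(expr))
    if (!(cfg$reference %in% grp))
        stop("unknown reference group '", cfg$reference, "'")
    treatments <- cfg$treatments
    if (is.null(treatments)) treatments <- setdiff(grp, cfg$reference)
    unknown <- setdiff(treatments, grp)
    if (length(unknown))
        stop("unknown treatment group(s): ", paste(unknown, collapse = ", "))
    sets <- restrictToUniverse(inputs$sets,
                               intersect(universe(inputs$sets),
                                         rownames(expr)))

    deList <- stage("de", function() {
        out <- lapply(treatments, function(tr) {
            de <- runDE(expr, tr, cfg$reference, alpha = cfg$alpha,
                        fcHigh = cfg$fc_high, fcLow = cfg$fc_low,
                        scale = cfg$scale)
            writeResultTable(de, file.path(cfg$outdir,
                                           sprintf("de_%s.tsv", tr)))
            de
        })
        names(out) <- treatments
        out
    })
    counts$de <- vapply(deList, function(d) length(degs(d)), integer(1))

    enrList <- stage("enrichment", function() {
        out <- lapply(treatments, function(tr) {
            e <- enrichPathways(deList[[tr]], sets,
                                alpha = cfg$enrichment_alpha,
                                universe = rownames(expr))
            writeResultTable(e, file.path(cfg$outdir,
                                          sprintf("enrichment_%s.tsv", tr)))
            e
        })
        names(out) <- treatments
        out
    })
    counts$enriched <- vapply(enrList, function(e) sum(e$enriched),
                              integer(1))

    common <- stage("common_pathways", function() {
        cp <- commonPathways(enrList, mode = cfg$common_mode)
        writeLines(cp, file.path(cfg$outdir, "common_pathways.txt"))
        cp
    })
    counts$common <- length(common)

    profiles <- stage("profiles", function() {
        out <- lapply(treatments, function(tr) {
            pr <- buildProfile(deList[[tr]], sets, pathways = common,
                               allowEmpty = cfg$common_mode == "union")
            writeProfile(pr, file.path(cfg$outdir,
                                       sprintf("profile_%s.tsv", tr)))
            pr
        })
        names(out) <- treatments
        out
    })
    counts$profile_genes <- vapply(profiles, function(p)
        nrow(profileValues(p)), integer(1))

    mc <- stage("mcia", function() {
        triplets <- lapply(profiles, preprocessProfile,
                           method = cfg$preprocess)
        res <- mcoa(triplets, nAxes = cfg$axes, weighting = cfg$weighting)
        writeResultTable(projectPathways(res),
                         file.path(cfg$outdir, "mcia_scores.tsv"))
        writeResultTable(data.frame(axis = seq_along(eigenvalues(res)),
                                    eigenvalue = eigenvalues(res)),
                         file.path(cfg$outdir, "mcia_eigenvalues.tsv"))
        res
    })

    div <- stage("divergence", function() {
        dt <- permutationTest(profiles, B = cfg$permutations,
                              seed = cfg$seed, nAxes = cfg$axes,
                              alpha = cfg$divergence_alpha,
                              method = cfg$preprocess,
                              weighting = cfg$weighting)
        writeResultTable(dt, file.path(cfg$outdir, "divergence.tsv"))
        rep <- pairwiseGroupReport(dt)
        writeResultTable(rep, file.path(cfg$outdir, "pair_summary.tsv"))
        list(table = dt, report = rep)
    })
    counts$different <- sum(divergence(div$table)$different, na.rm = TRUE)

    manifest <- list(package = "qpathdiff",
                     version = as.character(utils::packageVersion("qpathdiff")),
                     seed = cfg$seed,
                     config = cfg[order(names(cfg))],
                     stages = c("input", "de", "enrichment",
                                "common_pathways", "profiles", "mcia",
                                "divergence"),
                     counts = counts)
    jsonlite::write_json(manifest,
                         file.path(cfg$outdir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    message("pipeline complete: ", cfg$outdir)
    invisible(list(de = deList, enrichment = enrList, common = common,
                   profiles = profiles, mcia = mc, divergence = div$table,
                   report = div$report, truth = inputs$truth,
                   manifest = manifest))
}
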