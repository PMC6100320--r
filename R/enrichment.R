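#' Hypergeometric pathway enrichment of a DEG list
#'
#' One-sided (upper tail) hypergeometric test per pathway: with N genes in
#' the universe, K pathway members, n DEGs and k DEG members, the p-value is
#' P(X >= k) for X hypergeometric(N, K, n). Benjamini-Hochberg q-values are
#' computed across pathways; a pathway is enriched when its (corrected)
#' value falls below \code{alpha}. Pathways disjoint from the universe are
#' skipped with a message. DEGs outside the universe are ignored.
#'
#' @param de a \linkS4class{DEResult} (its significant genes form the DEG
#'   list) or a character vector of DEG identifiers.
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param alpha enrichment threshold (default 0.05).
#' @param correction \code{"BH"} (default; enriched iff q < alpha) or
#'   \code{"none"} (enriched iff p < alpha).
#' @param universe optional universe override; defaults to the collection's
#'   universe.
#' @return data.frame with columns \code{pathway}, \code{description},
#'   \code{n_members_in_universe}, \code{n_deg_members}, \code{p_value},
#'   \code{q_value}, \code{enriched}, sorted by p-value.
#' @export
enrichPathways <- function(de, sets, alpha = 0.05,
                           correction = c("BH", "none"), universe = NULL) {
    correction <- match.arg(correction)
    deg <- if (is(de, "DEResult")) degs(de) else as.character(de)
    if (is.null(universe)) universe <- universe(sets)
    deg <- intersect(deg, universe)
    empty <- data.frame(pathway = character(), description = character(),
                        n_members_in_universe = integer(),
                        n_deg_members = integer(), p_value = numeric(),
                        q_value = numeric(), enriched = logical(),
                        stringsAsFactors = FALSE)
    if (!length(deg)) {
        warning("empty DEG list; returning an empty enrichment table")
        return(empty)
    }
    N <- length(universe)
    n <- length(deg)
    members <- lapply(geneSets(sets), intersect, y = universe)
    skip <- lengths(members) == 0L
    if (any(skip))
        message("skipping ", sum(skip),
                " pathway(s) disjoint from the universe: ",
                paste(names(members)[skip], collapse = ", "))
    members <- members[!skip]
    if (!length(members)) return(empty)
    K <- lengths(members)
    k <- vapply(members, function(m) length(intersect(m, deg)), integer(1))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    q <- stats::p.adjust(p, method = "BH")
    enr <- if (correction == "BH") q < alpha else p < alpha
    out <- data.frame(pathway = names(members),
                      description = unname(sets@descriptions[names(members)]),
                      n_members_in_universe = unname(K),
                      n_deg_members = unname(k), p_value = unname(p),
                      q_value = unname(q), enriched = unname(enr),
                      stringsAsFactors = FALSE)
    out[order(out$p_value, out$pathway), , drop = FALSE]
}

#' Common pathways across contrasts
#'
#' Intersection (default) or union of the enriched pathway sets from two or
#' more enrichment tables, in deterministic sorted order.
#'
#' @param enrichments list of enrichment tables from [enrichPathways()].
#' @param mode \code{"intersection"} (default) or \code{"union"}.
#' @return sorted character vector of pathway ids.
#' @export
commonPathways <- function(enrichments,
                           mode = c("intersection", "union")) {
    mode <- match.arg(mode)
    if (length(enrichments) < 2L)
        stop("need at least two enrichment tables")
    sets <- lapply(enrichments, function(e) e$pathway[e$enriched])
    out <- Reduce(if (mode == "intersection") intersect else union, sets)
    if (!length(out))
        stop("no common enriched pathways under mode '", mode, "'",
             if (mode == "intersection")
                 "; consider mode = \"union\"" else "")
    sort(out)
}
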