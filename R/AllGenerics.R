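#' @rdname QPExpression
#' @param object,x a \linkS4class{QPExpression}
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))

#' @rdname GeneSetCollection
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection
#' @export
setGeneric("setIds", function(x) standardGeneric("setIds"))

#' @rdname GeneSetCollection
#' @export
setGeneric("universe", function(x) standardGeneric("universe"))

#' @rdname GeneSetCollection
#' @export
setGeneric("restrictToUniverse",
           function(x, universe) standardGeneric("restrictToUniverse"))

#' @rdname DEResult
#' @export
setGeneric("deTable", function(x) standardGeneric("deTable"))

#' @rdname DEResult
#' @export
setGeneric("degs", function(x) standardGeneric("degs"))

#' @rdname DEResult
#' @export
setGeneric("contrast", function(x) standardGeneric("contrast"))

#' @rdname PathwayProfile
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname PathwayProfile
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname MCIAResult
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname MCIAResult
#' @export
setGeneric("syntheticScores", function(x) standardGeneric("syntheticScores"))

#' @rdname MCIAResult
#' @export
setGeneric("tableScores", function(x) standardGeneric("tableScores"))

#' @rdname DivergenceTable
#' @export
setGeneric("divergence", function(x) standardGeneric("divergence"))
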