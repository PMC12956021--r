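#' @rdname accessors
#' @export
setGeneric("equilibriumFraction",
           function(object) standardGeneric("equilibriumFraction"))

#' @rdname accessors
#' @export
setGeneric("memoryGenerations",
           function(object) standardGeneric("memoryGenerations"))

#' @rdname accessors
#' @export
setGeneric("passages", function(object) standardGeneric("passages"))

#' @rdname accessors
#' @export
setGeneric("cloneIds", function(object) standardGeneric("cloneIds"))

#' @rdname accessors
#' @export
setGeneric("survivalFractions",
           function(object, passage = NULL)
             standardGeneric("survivalFractions"))

#' @rdname accessors
#' @export
setGeneric("records", function(object) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("passageStats", function(object) standardGeneric("passageStats"))

#' @rdname accessors
#' @export
setGeneric("growthStats", function(object) standardGeneric("growthStats"))

#' @rdname accessors
#' @export
setGeneric("passagePairs", function(object) standardGeneric("passagePairs"))

#' Analyze a clone-survival table
#'
#' @param object a [CloneSurvivalTable-class] (or coercible object).
#' @param ... further arguments passed to methods.
#' @export
setGeneric("analyzeTable", function(object, ...)
  standardGeneric("analyzeTable"))
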