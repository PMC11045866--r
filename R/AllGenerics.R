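#' @rdname AbundanceTable
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' @rdname AbundanceTable
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname TestResult
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname TestResult
#' @export
setGeneric("statistic", function(x) standardGeneric("statistic"))

#' @rdname StandardCurve
#' @export
setGeneric("slope", function(x) standardGeneric("slope"))

#' @rdname StandardCurve
#' @export
setGeneric("intercept", function(x) standardGeneric("intercept"))

#' @rdname StandardCurve
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @rdname BeadCloud
#' @export
setGeneric("beads", function(x) standardGeneric("beads"))

#' @rdname BeadCloud
#' @export
setGeneric("epithelium", function(x) standardGeneric("epithelium"))
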