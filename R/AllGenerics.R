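#' @rdname expectedDetectable
#' @export
setGeneric("expectedDetectable",
           function(x, event) standardGeneric("expectedDetectable"))

#' @rdname expectedElements
#' @export
setGeneric("expectedElements",
           function(x, events) standardGeneric("expectedElements"))

#' @rdname zeroCoverageEvents
#' @export
setGeneric("zeroCoverageEvents",
           function(x) standardGeneric("zeroCoverageEvents"))

#' @rdname validateMatrix
#' @export
setGeneric("validateMatrix", function(x) standardGeneric("validateMatrix"))

#' @rdname writeMatrix
#' @export
setGeneric("writeMatrix", function(x, path) standardGeneric("writeMatrix"))

#' @rdname maskingCheck
#' @export
setGeneric("maskingCheck",
           function(x, confirmed) standardGeneric("maskingCheck"))

#' Event names of a specificity matrix
#' @param x a [SpecificityMatrix-class]
#' @return character vector of event names (matrix row order)
#' @export
setGeneric("eventNames", function(x) standardGeneric("eventNames"))

#' Screening-target names of a specificity matrix
#' @param x a [SpecificityMatrix-class]
#' @return character vector of matrix column names
#' @export
setGeneric("screeningTargets",
           function(x) standardGeneric("screeningTargets"))

#' Assay catalogue accessor
#' @param x a [SpecificityMatrix-class]
#' @return data.frame of all 32 assays
#' @export
setGeneric("assayCatalogue", function(x) standardGeneric("assayCatalogue"))

#' Event catalogue accessor
#' @param x a [SpecificityMatrix-class]
#' @return data.frame with `name`, `crop`, `status`
#' @export
setGeneric("eventCatalogue", function(x) standardGeneric("eventCatalogue"))
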