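#' @export
setGeneric("snapValues", function(x) standardGeneric("snapValues"))

#' @export
setGeneric("timeGrid", function(x) standardGeneric("timeGrid"))

#' @export
setGeneric("spaceRegistry", function(x) standardGeneric("spaceRegistry"))

#' @export
setGeneric("gapMask", function(x) standardGeneric("gapMask"))

#' @export
setGeneric("timepoints", function(x) standardGeneric("timepoints"))

#' @export
setGeneric("nSpace", function(x) standardGeneric("nSpace"))

#' @export
setGeneric("nTime", function(x) standardGeneric("nTime"))

#' @export
setGeneric("unflatten", function(x) standardGeneric("unflatten"))

#' @export
setGeneric("levelResults", function(x) standardGeneric("levelResults"))

#' @export
setGeneric("globalBands", function(x) standardGeneric("globalBands"))

#' @export
setGeneric("coiMask", function(x, ...) standardGeneric("coiMask"))

#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @export
setGeneric("bandCentroids", function(x, ...) standardGeneric("bandCentroids"))
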