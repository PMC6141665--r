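#' @include AllClasses.R
NULL

#' @export
setGeneric("granules", function(x) standardGeneric("granules"))
#' @export
setGeneric("rois", function(x) standardGeneric("rois"))
#' @export
setGeneric("meshes", function(x) standardGeneric("meshes"))
#' @export
setGeneric("studyMeta", function(x) standardGeneric("studyMeta"))
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))
#' @export
setGeneric("perimeterIndices", function(x) standardGeneric("perimeterIndices"))
#' @export
setGeneric("contactLabels", function(x) standardGeneric("contactLabels"))
#' @export
setGeneric("coverageFraction", function(x) standardGeneric("coverageFraction"))
#' @export
setGeneric("summaries", function(x) standardGeneric("summaries"))
#' @export
setGeneric("omnibusResults", function(x) standardGeneric("omnibusResults"))
#' @export
setGeneric("posthocResults", function(x) standardGeneric("posthocResults"))
#' @export
setGeneric("correlationResults",
           function(x) standardGeneric("correlationResults"))
#' @export
setGeneric("perRoiMetrics", function(x) standardGeneric("perRoiMetrics"))
#' @export
setGeneric("reportMeta", function(x) standardGeneric("reportMeta"))
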