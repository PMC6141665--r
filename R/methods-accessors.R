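#' @include AllGenerics.R
NULL

#' Accessors for StudyDataset
#'
#' @param x a \linkS4class{StudyDataset}.
#' @return \code{granules} and \code{rois} return the annotation
#'   data.frames, \code{meshes} the named list of
#'   \linkS4class{AsiMesh}, \code{studyMeta} the provenance list.
#' @name StudyDataset-accessors
#' @aliases granules rois meshes studyMeta
NULL

#' @rdname StudyDataset-accessors
#' @export
setMethod("granules", "StudyDataset", function(x) x@granules)
#' @rdname StudyDataset-accessors
#' @export
setMethod("rois", "StudyDataset", function(x) x@rois)
#' @rdname StudyDataset-accessors
#' @export
setMethod("meshes", "StudyDataset", function(x) x@meshes)
#' @rdname StudyDataset-accessors
#' @export
setMethod("studyMeta", "StudyDataset", function(x) x@meta)

#' Accessors for AsiMesh
#'
#' @param x an \linkS4class{AsiMesh}.
#' @return \code{meshVertices}: numeric matrix (n x 3, nm);
#'   \code{meshFaces}: integer matrix (m x 3, 1-based);
#'   \code{perimeterIndices}: integer vector of the closed boundary;
#'   \code{contactLabels}: logical vector, one per perimeter segment.
#' @name AsiMesh-accessors
#' @aliases meshVertices meshFaces perimeterIndices contactLabels
NULL

#' @rdname AsiMesh-accessors
#' @export
setMethod("meshVertices", "AsiMesh", function(x) x@vertices)
#' @rdname AsiMesh-accessors
#' @export
setMethod("meshFaces", "AsiMesh", function(x) x@faces)
#' @rdname AsiMesh-accessors
#' @export
setMethod("perimeterIndices", "AsiMesh", function(x) x@perimeter)
#' @rdname AsiMesh-accessors
#' @export
setMethod("contactLabels", "AsiMesh", function(x) x@contactLabels)

#' Accessors for StatReport
#'
#' @param x a \linkS4class{StatReport}.
#' @return the corresponding result data.frame (see
#'   \linkS4class{StatReport}) or, for \code{reportMeta}, the metadata
#'   list.
#' @name StatReport-accessors
#' @aliases summaries omnibusResults posthocResults correlationResults
#'   perRoiMetrics reportMeta
NULL

#' @rdname StatReport-accessors
#' @export
setMethod("summaries", "StatReport", function(x) x@summaries)
#' @rdname StatReport-accessors
#' @export
setMethod("omnibusResults", "StatReport", function(x) x@omnibus)
#' @rdname StatReport-accessors
#' @export
setMethod("posthocResults", "StatReport", function(x) x@posthoc)
#' @rdname StatReport-accessors
#' @export
setMethod("correlationResults", "StatReport", function(x) x@correlations)
#' @rdname StatReport-accessors
#' @export
setMethod("perRoiMetrics", "StatReport", function(x) x@perRoi)
#' @rdname StatReport-accessors
#' @export
setMethod("reportMeta", "StatReport", function(x) x@meta)

setMethod("show", "AsiMesh", function(object) {
  cat(sprintf("AsiMesh: %d unique vertices, %d triangles, perimeter of %d segments (%d contacted)\n",
              nrow(object@vertices), nrow(object@faces),
              length(object@perimeter), sum(object@contactLabels)))
})

setMethod("show", "StudyDataset", function(object) {
  r <- object@rois
  cat(sprintf("StudyDataset: %d ROIs, %d granules, %d meshes\n",
              nrow(r), nrow(object@granules), length(object@meshes)))
  if (nrow(r)) {
    tab <- table(factor(r$condition, levels = .CONDITIONS))
    cat("  ROIs per condition:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  if (!is.null(object@meta$seed))
    cat("  generator seed:", object@meta$seed, "\n")
})

setMethod("show", "StatReport", function(object) {
  cat(sprintf("StatReport: %d summary rows, %d omnibus tests, %d post hoc pairs, %d correlations\n",
              nrow(object@summaries), nrow(object@omnibus),
              nrow(object@posthoc), nrow(object@correlations)))
  if (length(object@meta$stage_errors))
    cat("  stage errors:", length(object@meta$stage_errors), "\n")
})

setMethod("show", "GrParams", function(object) {
  cat(sprintf("GrParams: %g residues/chain, branching degree %g, tier length %g nm\n",
              object@residuesPerChain, object@branchingDegree,
              object@tierLength))
})

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf("PipelineConfig: window %g nm, alpha %g, %s distances, %s adjustment\n",
              object@windowNm, object@alpha, object@distanceMode,
              object@adjustment))
})
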