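#' @include AllClasses.R AllGenerics.R
NULL

#' Distance from granule balls to the nearest ASI mesh vertex
#'
#' The granule-to-synapse distance is defined as the shortest Euclidean
#' distance from a granule ball to the nearest vertex of the ASI
#' surface's unique-vertex set (not to the nearest point on a triangle
#' face). In \code{"center"} mode (the default) the distance is measured
#' from the ball center; in \code{"surface"} mode the ball radius is
#' subtracted and the result floored at zero.
#'
#' @param mesh an \linkS4class{AsiMesh} with at least one vertex.
#' @param centers numeric matrix (k x 3) of ball centers in nm, or a
#'   single length-3 vector.
#' @param mode "center" or "surface".
#' @param diameter numeric vector of ball diameters in nm (recycled to
#'   the number of centers); only used in surface mode.
#' @return numeric vector of distances in nm, one per center.
#' @examples
#' m <- AsiMesh(rbind(c(500, 0, 0), c(0, 800, 0)))
#' nearestVertexDistance(m, c(0, 0, 0)) # 500
#' @export
nearestVertexDistance <- function(mesh, centers, mode = c("center", "surface"),
                                  diameter = 0) {
  mode <- match.arg(mode)
  v <- meshVertices(mesh)
  if (nrow(v) < 1L) stop("geometry error: mesh has no vertices")
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 3L)
  if (ncol(centers) != 3L) stop("centers must have 3 columns")
  k <- nrow(centers)
  ## direct coordinate differences: exact (no cancellation from the
  ## |c|^2 + |v|^2 - 2 c.v expansion), so results match an exhaustive
  ## per-vertex scan bit for bit
  d2 <- outer(centers[, 1L], v[, 1L], "-")^2 +
    outer(centers[, 2L], v[, 2L], "-")^2 +
    outer(centers[, 3L], v[, 3L], "-")^2
  d <- sqrt(apply(d2, 1L, min))
  if (mode == "surface") {
    if (any(diameter < 0)) stop("diameter must be >= 0")
    d <- pmax(0, d - rep_len(diameter, k) / 2)
  }
  d
}

#' Compute distance records for every granule of a study
#'
#' Applies \code{\link{nearestVertexDistance}} ROI by ROI, using each
#' ROI's ASI mesh, and flags granules inside the inclusion window.
#'
#' @param dataset a \linkS4class{StudyDataset}.
#' @param windowNm inclusion window in nm (inclusive boundary).
#' @param mode distance mode, see \code{\link{nearestVertexDistance}}.
#' @param skipMissingGeometry if TRUE, granules whose ROI lacks a
#'   resolvable mesh are silently dropped from the result; if FALSE
#'   (default) a missing mesh is an error naming the ROI.
#' @return data.frame with columns \code{granule_id}, \code{roi_id},
#'   \code{distance_nm}, \code{within_window}, in granule-table order
#'   (minus any dropped rows).
#' @export
granuleDistances <- function(dataset, windowNm = 500,
                             mode = c("center", "surface"),
                             skipMissingGeometry = FALSE) {
  mode <- match.arg(mode)
  g <- granules(dataset); r <- rois(dataset); msh <- meshes(dataset)
  ref <- r$asi_mesh_ref[match(g$roi_id, r$roi_id)]
  have <- ref %in% names(msh)
  if (!all(have)) {
    if (!skipMissingGeometry) {
      badRoi <- unique(g$roi_id[!have])
      stop("geometry stage failed: no ASI mesh for ROI ",
           paste(utils::head(badRoi, 3L), collapse = ", "))
    }
    g <- g[have, , drop = FALSE]
    ref <- ref[have]
  }
  d <- numeric(nrow(g))
  idxByRef <- split(seq_len(nrow(g)), ref)
  for (rf in names(idxByRef)) {
    i <- idxByRef[[rf]]
    d[i] <- nearestVertexDistance(msh[[rf]],
                                  cbind(g$x_nm[i], g$y_nm[i], g$z_nm[i]),
                                  mode = mode, diameter = g$diameter_nm[i])
  }
  data.frame(granule_id = g$granule_id, roi_id = g$roi_id,
             distance_nm = d, within_window = d <= windowNm,
             stringsAsFactors = FALSE)
}

#' Filter distance records to the inclusion window
#'
#' Retains exactly the records with \code{distance_nm <= windowNm}
#' (inclusive boundary), preserving input order.
#'
#' @param records distance-record data.frame (see
#'   \code{\link{granuleDistances}}).
#' @param windowNm window in nm, > 0.
#' @return the retained subset, with \code{within_window} recomputed.
#' @export
applyWindow <- function(records, windowNm) {
  if (length(windowNm) != 1L || !is.finite(windowNm) || windowNm <= 0)
    stop("windowNm must be a single positive length")
  out <- records[records$distance_nm <= windowNm, , drop = FALSE]
  out$within_window <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Mean within-window granule distance of one ROI
#'
#' Averages the within-window distances of a single ROI. A ROI with no
#' granule inside the window has no defined mean distance and yields
#' \code{NA}; such ROIs are excluded from downstream distance
#' statistics.
#'
#' @param records distance records of exactly one ROI.
#' @param windowNm inclusion window in nm.
#' @return mean distance in nm, or \code{NA_real_}.
#' @export
meanRoiDistance <- function(records, windowNm = 500) {
  if (nrow(records) && length(unique(records$roi_id)) > 1L)
    stop("meanRoiDistance expects records of a single ROI; got ",
         length(unique(records$roi_id)))
  d <- records$distance_nm[records$distance_nm <= windowNm]
  if (!length(d)) return(NA_real_)
  mean(d)
}

#' Per-ROI mean within-window distances for a whole study
#'
#' @param records distance records of any number of ROIs.
#' @param windowNm inclusion window in nm.
#' @return named numeric vector of per-ROI mean distances (NA where a
#'   ROI has no within-window granule), one entry per ROI present in
#'   \code{records}.
#' @export
roiMeanDistances <- function(records, windowNm = 500) {
  keep <- records$distance_nm <= windowNm
  sums <- rowsum(records$distance_nm[keep],
                 records$roi_id[keep], reorder = TRUE)
  cnts <- rowsum(rep(1, sum(keep)), records$roi_id[keep], reorder = TRUE)
  out <- stats::setNames(rep(NA_real_, length(unique(records$roi_id))),
                         sort(unique(records$roi_id)))
  out[rownames(sums)] <- sums[, 1L] / cnts[, 1L]
  out
}

#' Astrocytic coverage of the ASI perimeter
#'
#' Fraction of the ASI perimeter length contacted by the perisynaptic
#' astrocytic process: sum of Euclidean lengths of the contacted
#' perimeter segments divided by the total perimeter length.
#'
#' @param x an \linkS4class{AsiMesh} with a closed perimeter and
#'   per-segment contact labels.
#' @return coverage fraction in [0, 1].
#' @export
setMethod("coverageFraction", "AsiMesh", function(x) {
  p <- perimeterIndices(x)
  if (length(p) < 3L) stop("geometry error: mesh has no closed perimeter")
  v <- meshVertices(x)
  a <- v[p, , drop = FALSE]
  b <- v[c(p[-1L], p[1L]), , drop = FALSE]
  len <- sqrt(rowSums((a - b)^2))
  total <- sum(len)
  if (total <= 0) stop("geometry error: zero-length perimeter")
  sum(len[contactLabels(x)]) / total
})
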