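#' @import methods
NULL

## Canonical condition ordering: sleep, spontaneous wake, acute sleep
## deprivation, chronic sleep restriction (increasing wake duration).
.CONDITIONS <- c("S", "W", "SD", "CSR")

## nm^3 per um^3; the only place this factor lives.
.NM3_PER_UM3 <- 1e9

#' Convert a volume from cubic nanometres to cubic micrometres
#'
#' All linear coordinates in the package are nanometres; volumes are
#' reported in cubic micrometres. This helper is the single point where
#' the conversion factor (1e9) is applied.
#'
#' @param x numeric vector of volumes in nm^3.
#' @return volumes in um^3.
#' @examples
#' nm3ToUm3(1000 * 1000 * 1000) # 1 um^3
#' @export
nm3ToUm3 <- function(x) x / .NM3_PER_UM3

.checkMatrix3 <- function(m, what, integerish = FALSE) {
  if (!is.matrix(m) || ncol(m) != 3L)
    return(sprintf("'%s' must be a matrix with 3 columns", what))
  if (integerish && !is.integer(m))
    return(sprintf("'%s' must be an integer matrix", what))
  NULL
}

#' AsiMesh: a triangulated axon-spine-interface surface
#'
#' Holds the triangulated surface of one axon-spine interface (ASI): a
#' unique-vertex set in nm coordinates, triangle faces as 1-based vertex
#' index triples, an ordered closed perimeter polyline, and one logical
#' PAP-contact label per perimeter segment. The perimeter is stored
#' without repeating the first vertex; segment i joins perimeter vertex i
#' to vertex i + 1, with the last segment closing back to the first
#' vertex, so there are exactly as many segments (and contact labels) as
#' perimeter vertices.
#'
#' @slot vertices numeric matrix (n x 3), nm; rows are unique coordinates.
#' @slot faces integer matrix (m x 3) of 1-based vertex indices.
#' @slot perimeter integer vector of 1-based vertex indices, ordered
#'   around the closed ASI boundary.
#' @slot contactLabels logical vector, one per perimeter segment; TRUE
#'   where the perisynaptic astrocytic process contacts the boundary.
#' @aliases AsiMesh
#' @exportClass AsiMesh
setClass("AsiMesh",
  representation(vertices = "matrix", faces = "matrix",
                 perimeter = "integer", contactLabels = "logical"))

setValidity("AsiMesh", function(object) {
  v <- object@vertices; f <- object@faces
  msg <- .checkMatrix3(v, "vertices")
  if (!is.null(msg)) return(msg)
  msg <- .checkMatrix3(f, "faces", integerish = TRUE)
  if (!is.null(msg)) return(msg)
  if (anyDuplicated(paste(v[, 1], v[, 2], v[, 3])))
    return("duplicate vertex coordinates: vertices must form a unique-vertex set")
  if (nrow(f) > 0L && (min(f) < 1L || max(f) > nrow(v)))
    return("face indices out of range")
  p <- object@perimeter
  if (length(p) > 0L) {
    if (length(p) < 3L) return("perimeter must have at least 3 vertices")
    if (min(p) < 1L || max(p) > nrow(v)) return("perimeter indices out of range")
    if (any(p == c(p[-1L], p[1L]))) return("perimeter has a zero-step segment")
    if (length(object@contactLabels) != length(p))
      return("need exactly one contact label per perimeter segment")
    if (anyNA(object@contactLabels)) return("contact labels must not be NA")
  } else if (length(object@contactLabels) != 0L) {
    return("contact labels supplied without a perimeter")
  }
  TRUE
})

#' Construct an AsiMesh
#'
#' @param vertices numeric matrix (n x 3) of nm coordinates. Duplicate
#'   coordinates are merged to the unique-vertex set and face/perimeter
#'   indices re-mapped accordingly.
#' @param faces integer matrix (m x 3), 1-based vertex indices.
#' @param perimeter integer vector of 1-based vertex indices forming the
#'   closed ASI boundary (first vertex not repeated at the end; a
#'   trailing repeat of the first index is accepted and dropped).
#' @param contactLabels logical vector, one label per perimeter segment.
#' @return an \linkS4class{AsiMesh}.
#' @examples
#' sq <- AsiMesh(rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)),
#'               rbind(c(1L,2L,3L), c(1L,3L,4L)),
#'               perimeter = 1:4, contactLabels = c(TRUE, FALSE, TRUE, FALSE))
#' coverageFraction(sq)
#' @export
AsiMesh <- function(vertices, faces = matrix(integer(), 0L, 3L),
                    perimeter = integer(), contactLabels = logical()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  if (ncol(faces) != 3L)
    stop("faces must be triangles (3 vertex indices per face)")
  storage.mode(faces) <- "integer"
  perimeter <- as.integer(perimeter)
  if (length(perimeter) > 1L && perimeter[1L] == perimeter[length(perimeter)])
    perimeter <- perimeter[-length(perimeter)]
  ## merge exact duplicate coordinates (unique-vertex contract)
  key <- paste(vertices[, 1], vertices[, 2], vertices[, 3])
  keep <- !duplicated(key)
  if (!all(keep)) {
    map <- match(key, key[keep])
    vertices <- vertices[keep, , drop = FALSE]
    if (nrow(faces) > 0L) faces[] <- map[faces]
    perimeter <- map[perimeter]
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  new("AsiMesh", vertices = vertices, faces = faces,
      perimeter = perimeter, contactLabels = as.logical(contactLabels))
}

#' StudyDataset: all annotations of one study
#'
#' Container for the annotation tables of one study (real or synthetic):
#' a granule table (one ball annotation per glycogen granule), a ROI
#' table (one cuboid neuropil region per synapse), the ASI meshes keyed
#' by \code{asi_mesh_ref}, and free-form provenance metadata.
#'
#' Granule table columns: \code{granule_id}, \code{roi_id}, \code{x_nm},
#' \code{y_nm}, \code{z_nm}, \code{diameter_nm}. ROI table columns:
#' \code{roi_id}, \code{condition}, \code{mouse_id}, \code{bbox_x_nm},
#' \code{bbox_y_nm}, \code{bbox_z_nm}, \code{edge_x_nm}, \code{edge_y_nm},
#' \code{edge_z_nm}, \code{roi_volume_um3}, \code{astro_volume_um3},
#' \code{asi_area_um2}, \code{ser_flag}, \code{mito_flag},
#' \code{asi_mesh_ref}. Coordinates are nm in a per-ROI frame with the
#' bounding-box corner at \code{(bbox_x_nm, bbox_y_nm, bbox_z_nm)}.
#'
#' @slot granules data.frame of granule ball annotations.
#' @slot rois data.frame of ROI records.
#' @slot meshes named list of \linkS4class{AsiMesh}, keyed by mesh ref.
#' @slot meta list of provenance metadata (generator seed, source, ...).
#' @aliases StudyDataset
#' @exportClass StudyDataset
.GRANULE_COLS <- c("granule_id", "roi_id", "x_nm", "y_nm", "z_nm", "diameter_nm")
.ROI_COLS <- c("roi_id", "condition", "mouse_id",
               "bbox_x_nm", "bbox_y_nm", "bbox_z_nm",
               "edge_x_nm", "edge_y_nm", "edge_z_nm",
               "roi_volume_um3", "astro_volume_um3", "asi_area_um2",
               "ser_flag", "mito_flag", "asi_mesh_ref")

.emptyGranuleTable <- function() {
  df <- data.frame(granule_id = character(), roi_id = character(),
                   x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
                   diameter_nm = numeric(), stringsAsFactors = FALSE)
  df
}

.emptyRoiTable <- function() {
  data.frame(roi_id = character(), condition = character(),
             mouse_id = character(), bbox_x_nm = numeric(),
             bbox_y_nm = numeric(), bbox_z_nm = numeric(),
             edge_x_nm = numeric(), edge_y_nm = numeric(),
             edge_z_nm = numeric(), roi_volume_um3 = numeric(),
             astro_volume_um3 = numeric(), asi_area_um2 = numeric(),
             ser_flag = logical(), mito_flag = logical(),
             asi_mesh_ref = character(), stringsAsFactors = FALSE)
}

setClass("StudyDataset",
  representation(granules = "data.frame", rois = "data.frame",
                 meshes = "list", meta = "list"),
  prototype(granules = .emptyGranuleTable(), rois = .emptyRoiTable()))

setValidity("StudyDataset", function(object) {
  g <- object@granules; r <- object@rois
  miss <- setdiff(.GRANULE_COLS, names(g))
  if (length(miss)) return(paste("granule table lacks column(s):",
                                 paste(miss, collapse = ", ")))
  miss <- setdiff(.ROI_COLS, names(r))
  if (length(miss)) return(paste("ROI table lacks column(s):",
                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(r$roi_id)) return("duplicated roi_id in ROI table")
  if (nrow(g)) {
    if (any(g$diameter_nm <= 0)) return("granule diameters must be > 0")
    i <- match(g$roi_id, r$roi_id)
    if (anyNA(i)) return("granule roi_id does not resolve to a ROI")
    lo <- cbind(r$bbox_x_nm, r$bbox_y_nm, r$bbox_z_nm)[i, , drop = FALSE]
    hi <- lo + cbind(r$edge_x_nm, r$edge_y_nm, r$edge_z_nm)[i, , drop = FALSE]
    ctr <- cbind(g$x_nm, g$y_nm, g$z_nm)
    if (any(ctr < lo) || any(ctr > hi))
      return("granule center outside its ROI bounding box")
  }
  if (nrow(r)) {
    if (!all(r$condition %in% .CONDITIONS))
      return(paste("condition labels must be drawn from",
                   paste(.CONDITIONS, collapse = ", ")))
    if (any(r$astro_volume_um3 <= 0)) return("astro_volume_um3 must be > 0")
    if (any(r$astro_volume_um3 > r$roi_volume_um3 * (1 + 1e-9)))
      return("astro_volume_um3 exceeds roi_volume_um3")
    if (any(r$asi_area_um2 <= 0)) return("asi_area_um2 must be > 0")
    bboxVol <- nm3ToUm3(r$edge_x_nm * r$edge_y_nm * r$edge_z_nm)
    if (any(abs(r$roi_volume_um3 - bboxVol) > 1e-6 * bboxVol))
      return("roi_volume_um3 inconsistent with bounding-box volume")
    bad <- setdiff(r$asi_mesh_ref, names(object@meshes))
    if (length(bad)) return(paste("asi_mesh_ref does not resolve:",
                                  paste(utils::head(bad, 3), collapse = ", ")))
  }
  TRUE
})

#' Construct a StudyDataset
#'
#' @param granules granule annotation data.frame (see
#'   \linkS4class{StudyDataset} for the schema).
#' @param rois ROI record data.frame.
#' @param meshes named list of \linkS4class{AsiMesh} keyed by the ROI
#'   table's \code{asi_mesh_ref} values.
#' @param meta list of provenance metadata.
#' @param validate check mesh references and geometry invariants
#'   (default TRUE). Set to FALSE only for deliberately incomplete
#'   datasets, e.g. annotations whose meshes are not yet available.
#' @return a \linkS4class{StudyDataset}.
#' @export
StudyDataset <- function(granules, rois, meshes = list(), meta = list(),
                         validate = TRUE) {
  rownames(granules) <- NULL
  rownames(rois) <- NULL
  ## slot assignment, so `validate = FALSE` really skips the validity
  ## method (new() always runs it)
  obj <- new("StudyDataset")
  obj@granules <- granules
  obj@rois <- rois
  obj@meshes <- meshes
  obj@meta <- meta
  if (validate) methods::validObject(obj)
  obj
}

#' StatReport: results of the full analysis
#'
#' Output container of \code{\link{runFullAnalysis}}: per-condition
#' summary rows, omnibus rank tests, pairwise post hoc results,
#' correlation results, the per-ROI metric table the summaries were
#' computed from, and run metadata (configuration echo, stage errors).
#'
#' @slot summaries data.frame: stage, metric, grain, condition, group,
#'   n, mean, sem.
#' @slot omnibus data.frame: stage, metric, grain, test, statistic, df, p.
#' @slot posthoc data.frame: stage, metric, group1, group2, z, p_raw,
#'   p_adj, adjustment.
#' @slot correlations data.frame: stage, condition, xvar, yvar, grain,
#'   n, n_excluded, rho, p.
#' @slot perRoi data.frame of per-ROI metrics (see
#'   \code{\link{computeRoiMetrics}}).
#' @slot meta list (configuration echo, stage errors, dataset seed).
#' @aliases StatReport
#' @exportClass StatReport
setClass("StatReport",
  representation(summaries = "data.frame", omnibus = "data.frame",
                 posthoc = "data.frame", correlations = "data.frame",
                 perRoi = "data.frame", meta = "list"))

.emptySummaries <- function() data.frame(
  stage = character(), metric = character(), grain = character(),
  condition = character(), group = character(),
  n = integer(), mean = numeric(), sem = numeric(),
  stringsAsFactors = FALSE)

.emptyOmnibus <- function() data.frame(
  stage = character(), metric = character(), grain = character(),
  test = character(), statistic = numeric(), df = integer(),
  p = numeric(), stringsAsFactors = FALSE)

.emptyPosthoc <- function() data.frame(
  stage = character(), metric = character(), group1 = character(),
  group2 = character(), z = numeric(), p_raw = numeric(),
  p_adj = numeric(), adjustment = character(), stringsAsFactors = FALSE)

.emptyCorrelations <- function() data.frame(
  stage = character(), condition = character(), xvar = character(),
  yvar = character(), grain = character(), n = integer(),
  n_excluded = integer(), rho = numeric(), p = numeric(),
  stringsAsFactors = FALSE)

setValidity("StatReport", function(object) {
  ps <- c(object@omnibus$p, object@posthoc$p_raw, object@posthoc$p_adj,
          object@correlations$p)
  ps <- ps[!is.na(ps)]
  if (length(ps) && (any(ps < 0) || any(ps > 1)))
    return("p-values must lie in [0, 1]")
  ph <- object@posthoc
  if (nrow(ph) && any(ph$p_adj < ph$p_raw - 1e-12, na.rm = TRUE))
    return("adjusted p-values must be >= raw p-values")
  TRUE
})

#' Construct a StatReport
#'
#' @param summaries,omnibus,posthoc,correlations,perRoi data.frames as
#'   documented for \linkS4class{StatReport}; default to empty tables
#'   with the canonical columns.
#' @param meta list of run metadata.
#' @return a \linkS4class{StatReport}.
#' @export
StatReport <- function(summaries = .emptySummaries(),
                       omnibus = .emptyOmnibus(),
                       posthoc = .emptyPosthoc(),
                       correlations = .emptyCorrelations(),
                       perRoi = data.frame(), meta = list()) {
  obj <- new("StatReport", summaries = summaries, omnibus = omnibus,
             posthoc = posthoc, correlations = correlations,
             perRoi = perRoi, meta = meta)
  methods::validObject(obj)
  obj
}

#' GrParams: parameters of the glucose-residue formula
#'
#' Parameters of the tiered-branching estimate of glucose residues per
#' granule: a glycogen particle grows in concentric tiers of thickness
#' \code{tierLength} (~1.9 nm); each chain carries
#' \code{residuesPerChain} glucose residues (~13) and branches with
#' degree \code{branchingDegree} (2) from tier to tier.
#'
#' @slot residuesPerChain average glucose residues per chain (default 13).
#' @slot branchingDegree chain branching degree per tier (default 2).
#' @slot tierLength tier thickness in nm (default 1.9).
#' @aliases GrParams
#' @exportClass GrParams
setClass("GrParams",
  representation(residuesPerChain = "numeric", branchingDegree = "numeric",
                 tierLength = "numeric"),
  prototype(residuesPerChain = 13, branchingDegree = 2, tierLength = 1.9))

setValidity("GrParams", function(object) {
  v <- c(object@residuesPerChain, object@branchingDegree, object@tierLength)
  if (length(v) != 3L || anyNA(v) || any(v <= 0))
    return("all GrParams fields must be single positive numbers")
  TRUE
})

#' @describeIn GrParams constructor.
#' @param residuesPerChain,branchingDegree,tierLength see slots.
#' @export
grParams <- function(residuesPerChain = 13, branchingDegree = 2,
                     tierLength = 1.9) {
  obj <- new("GrParams", residuesPerChain = residuesPerChain,
             branchingDegree = branchingDegree, tierLength = tierLength)
  methods::validObject(obj)
  obj
}

#' PipelineConfig: tunable parameters of the full analysis
#'
#' @slot windowNm inclusion window for granule-to-ASI distances, nm
#'   (default 500; granules farther than this from the nearest ASI
#'   vertex are excluded from distance analyses).
#' @slot alpha significance threshold (default 0.05).
#' @slot grParams \linkS4class{GrParams} of the glucose-residue formula.
#' @slot adjustment p-value adjustment for Dunn's test: "bonferroni"
#'   (default), "sidak" or "none".
#' @slot distanceMode "center" (default: ball center to nearest vertex)
#'   or "surface" (ball surface, i.e. center distance minus the radius,
#'   floored at 0).
#' @slot log2DensityForAsiCorr correlate log2(density) rather than raw
#'   density with ASI area (default TRUE; zero-density ROIs are then
#'   excluded from that correlation and counted).
#' @aliases PipelineConfig
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(windowNm = "numeric", alpha = "numeric",
                 grParams = "GrParams", adjustment = "character",
                 distanceMode = "character",
                 log2DensityForAsiCorr = "logical"))

setValidity("PipelineConfig", function(object) {
  if (length(object@windowNm) != 1L || object@windowNm <= 0)
    return("windowNm must be a single positive length")
  if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
    return("alpha must lie in (0, 1)")
  if (!object@adjustment %in% c("bonferroni", "sidak", "none"))
    return("adjustment must be one of bonferroni, sidak, none")
  if (!object@distanceMode %in% c("center", "surface"))
    return("distanceMode must be 'center' or 'surface'")
  TRUE
})

#' @describeIn PipelineConfig constructor.
#' @param windowNm,alpha,grParams,adjustment,distanceMode,log2DensityForAsiCorr
#'   see slots.
#' @export
pipelineConfig <- function(windowNm = 500, alpha = 0.05,
                           grParams = glycoPAP::grParams(),
                           adjustment = "bonferroni",
                           distanceMode = "center",
                           log2DensityForAsiCorr = TRUE) {
  obj <- new("PipelineConfig", windowNm = windowNm, alpha = alpha,
             grParams = grParams, adjustment = adjustment,
             distanceMode = distanceMode,
             log2DensityForAsiCorr = log2DensityForAsiCorr)
  methods::validObject(obj)
  obj
}
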