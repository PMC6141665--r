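#' @include AllClasses.R
NULL

#' Estimated glucose residues per glycogen granule
#'
#' Estimates the number of glucose monomers stored in a granule of a
#' given diameter under the tiered-branching model of glycogen
#' structure: a particle of diameter d spans d / (2 L) tiers of
#' thickness L, chains branch with degree b from tier to tier and each
#' chain carries c residues, giving
#' \deqn{GR(d) = c \, (b^{d/(2L)} - 1)}
#' with defaults c = 13 residues per chain, b = 2 and L = 1.9 nm. The
#' estimate is continuous and strictly increasing in d, and reported as
#' a real number (granule-level values enter averages unrounded).
#'
#' @param diameter numeric vector of granule diameters in nm, >= 0.
#' @param params a \linkS4class{GrParams}.
#' @return numeric vector of estimated glucose-residue counts.
#' @examples
#' glucoseResidues(0)    # 0
#' glucoseResidues(3.8)  # one full tier of branching: exactly 13
#' @export
glucoseResidues <- function(diameter, params = grParams()) {
  if (any(!is.finite(diameter)) || any(diameter < 0))
    stop("diameter must be finite and >= 0")
  params@residuesPerChain *
    (params@branchingDegree^(diameter / (2 * params@tierLength)) - 1)
}

#' Granule density normalized to the astrocytic volume
#'
#' @param granuleCount number of granules in the ROI's astrocytic
#'   compartment (vectorized).
#' @param astroVolume astrocytic volume within the ROI, um^3, > 0.
#' @return granules per um^3 of astrocyte.
#' @export
normalizedDensity <- function(granuleCount, astroVolume) {
  if (any(!is.finite(astroVolume)) || any(astroVolume <= 0))
    stop("astroVolume must be finite and > 0")
  granuleCount / astroVolume
}

#' Per-ROI metric table
#'
#' Joins the granule, ROI and distance tables into one row per ROI:
#' granule count, normalized density, mean granule diameter, mean
#' estimated glucose residues, mean within-window granule-to-ASI
#' distance (NA where no granule lies inside the window), astrocytic
#' coverage of the ASI perimeter, and the copied condition / mouse /
#' synapse-flag labels.
#'
#' @param dataset a \linkS4class{StudyDataset}.
#' @param distances distance records from \code{\link{granuleDistances}}
#'   (computed if NULL and meshes are available).
#' @param params \linkS4class{GrParams} for the glucose-residue formula.
#' @param windowNm inclusion window in nm.
#' @return data.frame with one row per ROI, in ROI-table order.
#' @export
computeRoiMetrics <- function(dataset, distances = NULL,
                              params = grParams(), windowNm = 500) {
  g <- granules(dataset); r <- rois(dataset)
  if (nrow(g) && anyNA(match(g$roi_id, r$roi_id)))
    stop("granule table references unknown ROI(s)")
  if (is.null(distances)) distances <- granuleDistances(dataset, windowNm)
  cnt <- integer(nrow(r)); meanDiam <- rep(NA_real_, nrow(r))
  meanGr <- rep(NA_real_, nrow(r))
  if (nrow(g)) {
    gr <- glucoseResidues(g$diameter_nm, params)
    tabCnt <- rowsum(rep(1L, nrow(g)), g$roi_id)
    tabDiam <- rowsum(g$diameter_nm, g$roi_id)
    tabGr <- rowsum(gr, g$roi_id)
    i <- match(r$roi_id, rownames(tabCnt))
    cnt <- unname(ifelse(is.na(i), 0L, tabCnt[i, 1L]))
    meanDiam <- unname(tabDiam[i, 1L]) / cnt
    meanGr <- unname(tabGr[i, 1L]) / cnt
  }
  meanDist <- rep(NA_real_, nrow(r))
  if (NROW(distances)) {
    md <- roiMeanDistances(distances, windowNm)
    meanDist <- unname(md[match(r$roi_id, names(md))])
  }
  coverage <- rep(NA_real_, nrow(r))
  msh <- meshes(dataset)
  for (k in seq_len(nrow(r))) {
    m <- msh[[r$asi_mesh_ref[k]]]
    if (!is.null(m) && length(perimeterIndices(m)) >= 3L)
      coverage[k] <- coverageFraction(m)
  }
  data.frame(
    roi_id = r$roi_id, condition = r$condition, mouse_id = r$mouse_id,
    granule_count = as.integer(cnt),
    density = normalizedDensity(cnt, r$astro_volume_um3),
    mean_diameter = meanDiam, mean_gr = meanGr, mean_distance = meanDist,
    coverage = coverage,
    roi_volume_um3 = r$roi_volume_um3,
    astro_volume_um3 = r$astro_volume_um3,
    asi_area_um2 = r$asi_area_um2,
    ser_flag = r$ser_flag, mito_flag = r$mito_flag,
    stringsAsFactors = FALSE)
}

#' Partition ROI metrics by a synapse flag
#'
#' Splits a per-ROI metric table into flag-positive and flag-negative
#' groups. The partition is exhaustive and disjoint; empty groups are
#' returned as zero-row data.frames.
#'
#' @param metrics per-ROI metric data.frame (see
#'   \code{\link{computeRoiMetrics}}).
#' @param flag "ser_flag" or "mito_flag".
#' @return list with elements \code{positive} and \code{negative}.
#' @export
stratifyMetrics <- function(metrics, flag = c("ser_flag", "mito_flag")) {
  flag <- match.arg(flag)
  if (!flag %in% names(metrics)) stop("metrics lack column ", flag)
  f <- metrics[[flag]]
  if (anyNA(f)) stop("flag column ", flag, " contains NA")
  list(positive = metrics[f, , drop = FALSE],
       negative = metrics[!f, , drop = FALSE])
}
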