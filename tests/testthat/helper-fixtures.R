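# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# unit square in the z = 0 plane, split into two triangles, with its
# 4-segment perimeter labelled
squareMesh <- function(contact = c(TRUE, FALSE, TRUE, FALSE), side = 1) {
  AsiMesh(rbind(c(0, 0, 0), c(side, 0, 0), c(side, side, 0), c(0, side, 0)),
          rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)),
          perimeter = 1:4, contactLabels = contact)
}

# random point cloud mesh (vertices only) for distance oracles
randomVertexMesh <- function(nV, lim = 1000) {
  AsiMesh(matrix(stats::runif(3 * nV, -lim, lim), ncol = 3))
}

# random closed labelled polyline as an AsiMesh perimeter
randomPerimeterMesh <- function(nSeg) {
  v <- matrix(stats::runif(3 * nSeg, -500, 500), ncol = 3)
  AsiMesh(v, perimeter = seq_len(nSeg),
          contactLabels = stats::runif(nSeg) < 0.5)
}

# minimal hand-built study: nRois cuboid ROIs in one condition set, with
# granules at known offsets from a square ASI at the ROI center
tinyStudy <- function(conditions = c("S", "W"), roisPer = 2L,
                      granulesPer = 3L, diameter = 20) {
  rois <- list(); grans <- list(); msh <- list()
  gid <- 0L
  for (cnd in conditions) for (i in seq_len(roisPer)) {
    rid <- sprintf("%s_%d", cnd, i)
    ref <- paste0("mesh_", rid)
    edge <- 3000
    rois[[rid]] <- data.frame(
      roi_id = rid, condition = cnd, mouse_id = paste0(cnd, "_m1"),
      bbox_x_nm = 0, bbox_y_nm = 0, bbox_z_nm = 0,
      edge_x_nm = edge, edge_y_nm = edge, edge_z_nm = edge,
      roi_volume_um3 = edge^3 / 1e9, astro_volume_um3 = 0.1 * edge^3 / 1e9,
      asi_area_um2 = 0.1, ser_flag = i %% 2L == 0L, mito_flag = TRUE,
      asi_mesh_ref = ref, stringsAsFactors = FALSE)
    sq <- squareMesh(side = 300)
    # shift square to the ROI center plane
    v <- meshVertices(sq) + matrix(rep(c(1350, 1350, 1500), each = 4), ncol = 3)
    msh[[ref]] <- AsiMesh(v, meshFaces(sq), perimeterIndices(sq),
                          contactLabels(sq))
    for (j in seq_len(granulesPer)) {
      gid <- gid + 1L
      grans[[gid]] <- data.frame(
        granule_id = sprintf("g%04d", gid), roi_id = rid,
        x_nm = 1350, y_nm = 1350, z_nm = 1500 + 100 * j,
        diameter_nm = diameter + j, stringsAsFactors = FALSE)
    }
  }
  StudyDataset(do.call(rbind, unname(grans)), do.call(rbind, unname(rois)),
               msh, meta = list(source = "tinyStudy"))
}

crossProd3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# small-but-complete synthetic configuration for pipeline tests
smallConfig <- function(roiFactor = 0.08) {
  scaleStudyConfig(defaultStudyConfig(), roiFactor)
}
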