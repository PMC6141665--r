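test_that("glucose residues follow the tiered-branching formula", {
  expect_identical(glucoseResidues(0), 0)
  # one full tier of branching: exponent exactly 1, GR equals the
  # per-chain residue count
  expect_identical(glucoseResidues(3.8), 13)
  # closed-form evaluation frozen as the oracle value
  expect_equal(glucoseResidues(27.2), 1843.4547751552088, tolerance = 1e-12)
  expect_error(glucoseResidues(-1), ">= 0")

  # strictly increasing and continuous on a grid
  d <- seq(0, 60, length.out = 400)
  gr <- glucoseResidues(d)
  expect_true(all(diff(gr) > 0))

  # doubling recurrence: GR(d + 2L) = b GR(d) + c (b - 1)
  p <- grParams()
  lhs <- glucoseResidues(d + 2 * p@tierLength, p)
  rhs <- p@branchingDegree * gr + p@residuesPerChain * (p@branchingDegree - 1)
  expect_equal(lhs, rhs, tolerance = 1e-9)

  # non-default parameters honoured
  p2 <- grParams(residuesPerChain = 10, branchingDegree = 3, tierLength = 2)
  expect_equal(glucoseResidues(4, p2), 10 * (3 - 1))
})

test_that("normalized density is the exact quotient", {
  expect_equal(normalizedDensity(10, 0.1), 100)
  expect_equal(normalizedDensity(0, 0.5), 0)
  expect_error(normalizedDensity(5, 0), "> 0")
  set.seed(21)
  cnt <- rpois(200, 20); vol <- runif(200, 0.05, 3)
  expect_equal(normalizedDensity(cnt, vol), cnt / vol, tolerance = 1e-12)
})

test_that("per-ROI metrics join counts, GR means and distances", {
  ds <- tinyStudy(conditions = "S", roisPer = 1, granulesPer = 2)
  g <- granules(ds)
  g$diameter_nm <- c(3.8, 7.6)
  ds2 <- StudyDataset(g, rois(ds), meshes(ds))
  m <- computeRoiMetrics(ds2)
  expect_equal(m$granule_count, 2L)
  expect_equal(m$density, 2 / rois(ds2)$astro_volume_um3)
  expect_equal(m$mean_gr, mean(glucoseResidues(c(3.8, 7.6))))
  expect_equal(m$mean_distance, 150)  # granules at 100 and 200 nm
  expect_equal(m$coverage, 0.5)

  # ROI with no granules: count 0, density 0, undefined means
  emptyRoi <- rois(ds2); emptyRoi$roi_id <- "empty"; emptyRoi$asi_mesh_ref <- "mesh_S_1"
  both <- StudyDataset(g, rbind(rois(ds2), emptyRoi), meshes(ds2))
  m2 <- computeRoiMetrics(both)
  i <- match("empty", m2$roi_id)
  expect_equal(m2$granule_count[i], 0L)
  expect_equal(m2$density[i], 0)
  expect_true(is.na(m2$mean_gr[i]) && is.na(m2$mean_distance[i]))

  # conservation: ROI counts sum to the granule-table size
  ds3 <- generateStudy(smallConfig(0.05), seed = 5)
  m3 <- computeRoiMetrics(ds3)
  expect_equal(sum(m3$granule_count), nrow(granules(ds3)))
})

test_that("density is invariant to linear rescaling of the bookkeeping", {
  ds <- tinyStudy(conditions = "S", roisPer = 2, granulesPer = 4)
  m <- computeRoiMetrics(ds)
  k <- 2
  r2 <- rois(ds)
  for (col in c("bbox_x_nm", "bbox_y_nm", "bbox_z_nm",
                "edge_x_nm", "edge_y_nm", "edge_z_nm")) r2[[col]] <- r2[[col]] * k
  r2$roi_volume_um3 <- r2$roi_volume_um3 * k^3
  r2$astro_volume_um3 <- r2$astro_volume_um3 * k^3
  g2 <- granules(ds)
  for (col in c("x_nm", "y_nm", "z_nm")) g2[[col]] <- g2[[col]] * k
  msh2 <- lapply(meshes(ds), function(m)
    AsiMesh(meshVertices(m) * k, meshFaces(m), perimeterIndices(m),
            contactLabels(m)))
  m2 <- computeRoiMetrics(StudyDataset(g2, r2, msh2))
  expect_equal(m2$density, m$density / k^3, tolerance = 1e-12)
})

test_that("stratification is an exhaustive disjoint partition", {
  ds <- tinyStudy(roisPer = 5)
  m <- computeRoiMetrics(ds)
  parts <- stratifyMetrics(m, "ser_flag")
  expect_equal(nrow(parts$positive) + nrow(parts$negative), nrow(m))
  expect_length(intersect(parts$positive$roi_id, parts$negative$roi_id), 0L)
  expect_true(all(parts$positive$ser_flag) && !any(parts$negative$ser_flag))

  allTrue <- m; allTrue$mito_flag <- TRUE
  parts2 <- stratifyMetrics(allTrue, "mito_flag")
  expect_equal(nrow(parts2$negative), 0L)
})

test_that("synthetic SER prevalence is binomially consistent with its target", {
  ds <- generateStudy(seed = 31)
  r <- rois(ds)
  p <- 0.575; n <- 308
  obs <- mean(r$ser_flag[r$condition == "S"])
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(obs - p), 3 * se)
})
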