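test_that("nearest-vertex distance matches hand cases and the brute-force oracle", {
  m <- AsiMesh(rbind(c(500, 0, 0), c(0, 800, 0)))
  expect_equal(nearestVertexDistance(m, c(0, 0, 0)), 500)
  m345 <- AsiMesh(matrix(c(3, 4, 0), 1))
  expect_equal(nearestVertexDistance(m345, c(0, 0, 0)), 5)

  # exhaustive min-over-all-vertices oracle, exact equality
  set.seed(101)
  mesh <- randomVertexMesh(500)
  v <- meshVertices(mesh)
  centers <- matrix(runif(3 * 200, -1200, 1200), ncol = 3)
  got <- nearestVertexDistance(mesh, centers)
  oracle <- apply(centers, 1, function(p) min(sqrt(colSums((t(v) - p)^2))))
  expect_equal(got, oracle, tolerance = 1e-12)

  expect_error(
    nearestVertexDistance(AsiMesh(matrix(numeric(), 0, 3)), c(0, 0, 0)),
    "geometry error")
})

test_that("surface mode subtracts the radius, floors at zero, never exceeds center mode", {
  set.seed(102)
  mesh <- randomVertexMesh(50)
  centers <- matrix(runif(3 * 100, -800, 800), ncol = 3)
  diam <- runif(100, 5, 400)
  dc <- nearestVertexDistance(mesh, centers)
  ds <- nearestVertexDistance(mesh, centers, mode = "surface", diameter = diam)
  expect_true(all(ds <= dc + 1e-12))
  expect_equal(ds, pmax(0, dc - diam / 2), tolerance = 1e-12)
  # equality only in the zero-diameter limit
  expect_equal(nearestVertexDistance(mesh, centers, mode = "surface",
                                     diameter = 0), dc, tolerance = 1e-12)
})

test_that("distances are invariant under rigid transforms", {
  set.seed(103)
  mesh <- randomVertexMesh(40)
  centers <- matrix(runif(3 * 20, -500, 500), ncol = 3)
  d0 <- nearestVertexDistance(mesh, centers)
  for (i in 1:100) {
    # random rotation via QR of a gaussian matrix, plus random translation
    qr0 <- qr(matrix(rnorm(9), 3))
    R <- qr.Q(qr0) %*% diag(sign(diag(qr.R(qr0))))
    t0 <- runif(3, -1e4, 1e4)
    mT <- AsiMesh(sweep(meshVertices(mesh) %*% t(R), 2, -t0))
    cT <- sweep(centers %*% t(R), 2, -t0)
    expect_equal(nearestVertexDistance(mT, cT), d0, tolerance = 1e-9)
  }
})

test_that("the inclusion window boundary is inclusive and monotone", {
  rec <- data.frame(granule_id = letters[1:4], roi_id = "r",
                    distance_nm = c(100, 499.9, 500.0, 500.1),
                    within_window = NA)
  kept <- applyWindow(rec, 500)
  expect_identical(kept$granule_id, c("a", "b", "c"))
  expect_true(all(kept$within_window))
  expect_equal(nrow(applyWindow(rec, 50)), 0L)

  set.seed(104)
  rec2 <- data.frame(granule_id = as.character(1:1000), roi_id = "r",
                     distance_nm = runif(1000, 0, 1000), within_window = NA)
  expect_equal(nrow(applyWindow(rec2, 500)),
               sum(rec2$distance_nm <= 500))  # naive scan oracle
  # enlarging the window never drops records
  wins <- c(50, 200, 400, 500, 750, 1000)
  counts <- vapply(wins, function(w) nrow(applyWindow(rec2, w)), integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(applyWindow(rec2, 0), "positive")
})

test_that("per-ROI mean distances average within the window, NA when empty", {
  rec <- data.frame(granule_id = c("a", "b", "c"), roi_id = "r",
                    distance_nm = c(300, 400, 900), within_window = NA)
  expect_equal(meanRoiDistance(rec, 500), 350)
  far <- data.frame(granule_id = "z", roi_id = "r", distance_nm = 700,
                    within_window = NA)
  expect_true(is.na(meanRoiDistance(far, 500)))
  mixed <- rbind(rec, data.frame(granule_id = "q", roi_id = "other",
                                 distance_nm = 10, within_window = NA))
  expect_error(meanRoiDistance(mixed, 500), "single ROI")

  set.seed(105)
  n <- 400
  rec3 <- data.frame(granule_id = as.character(1:n),
                     roi_id = sample(c("r1", "r2", "r3"), n, TRUE),
                     distance_nm = runif(n, 0, 800), within_window = NA)
  got <- roiMeanDistances(rec3, 500)
  for (r in names(got)) {
    d <- rec3$distance_nm[rec3$roi_id == r]
    d <- d[d <= 500]
    expect_equal(unname(got[r]), sum(d) / length(d), tolerance = 1e-12)
  }
})

test_that("coverage fraction matches the segment-summation oracle", {
  expect_equal(coverageFraction(squareMesh(rep(TRUE, 4))), 1.0)
  expect_equal(coverageFraction(squareMesh(c(TRUE, FALSE, TRUE, FALSE))), 0.5)

  set.seed(106)
  for (i in 1:20) {
    m <- randomPerimeterMesh(sample(4:40, 1))
    v <- meshVertices(m); p <- perimeterIndices(m); lab <- contactLabels(m)
    tot <- 0; hit <- 0
    for (s in seq_along(p)) {
      a <- v[p[s], ]; b <- v[p[ifelse(s == length(p), 1L, s + 1L)], ]
      len <- sqrt(sum((a - b)^2))
      tot <- tot + len
      if (lab[s]) hit <- hit + len
    }
    expect_equal(coverageFraction(m), hit / tot, tolerance = 1e-12)
  }
})

test_that("coverage is invariant to traversal direction and starting vertex", {
  set.seed(107)
  m <- randomPerimeterMesh(15)
  v <- meshVertices(m); p <- perimeterIndices(m); lab <- contactLabels(m)
  c0 <- coverageFraction(m)
  # rotate the starting vertex
  for (shift in c(3, 7)) {
    ps <- c(p[-seq_len(shift)], p[seq_len(shift)])
    labs <- c(lab[-seq_len(shift)], lab[seq_len(shift)])
    expect_equal(coverageFraction(AsiMesh(v, perimeter = ps,
                                          contactLabels = labs)), c0,
                 tolerance = 1e-12)
  }
  # reverse traversal: segment s (p[s] -> p[s+1]) becomes the segment
  # starting at its far endpoint in the reversed ordering
  pr <- rev(p)
  labr <- c(rev(lab)[-1L], rev(lab)[1L])
  expect_equal(coverageFraction(AsiMesh(v, perimeter = pr,
                                        contactLabels = labr)), c0,
               tolerance = 1e-12)
})

test_that("granuleDistances uses each ROI's own mesh and flags the window", {
  ds <- tinyStudy(roisPer = 2, granulesPer = 3)
  rec <- granuleDistances(ds, windowNm = 250)
  # granules sit 100, 200, 300 nm above a square corner vertex
  expect_equal(sort(unique(round(rec$distance_nm))), c(100, 200, 300))
  expect_identical(rec$within_window, rec$distance_nm <= 250)
  # missing mesh: named error, or silent drop when skipping
  broken <- StudyDataset(granules(ds), rois(ds),
                         meshes(ds)[-1], validate = FALSE)
  expect_error(granuleDistances(broken), "S_1")
  kept <- granuleDistances(broken, skipMissingGeometry = TRUE)
  expect_equal(nrow(kept), nrow(rec) - 3L)
})
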