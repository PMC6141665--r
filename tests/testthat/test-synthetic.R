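test_that("the default configuration encodes the study design", {
  cfg <- defaultStudyConfig()
  expect_identical(names(cfg$conditions), c("S", "W", "SD", "CSR"))
  s <- cfg$conditions$S
  expect_equal(s$nRois, 308L)
  # population SDs derive from SEM * sqrt(n)
  expect_equal(s$densitySd, 5.4 * sqrt(308), tolerance = 1e-12)
  expect_equal(s$diamSd, 0.1 * sqrt(3248), tolerance = 1e-12)
  expect_equal(cfg$conditions$CSR$rankCorrs$cov_dist, -0.2)
  expect_error(conditionParams("S", 10, 100, 5, 27, 0.1, 100, 350, 7,
                               0.5, 0.5, rankCorrs = list(density_asi = 1.2,
                                                          diam_dist = 0,
                                                          cov_dist = 0)),
               "configuration error")
})

test_that("study configurations round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- smallConfig()
  writeStudyConfig(cfg, path)
  back <- readStudyConfig(path)
  expect_equal(back$conditions$S$densitySd, cfg$conditions$S$densitySd,
               tolerance = 1e-9)
  expect_equal(back$conditions$CSR$rankCorrs, cfg$conditions$CSR$rankCorrs)
  expect_equal(back$global$pNear, cfg$global$pNear)
})

test_that("generation is bit-identical for a fixed seed", {
  cfg <- smallConfig(0.05)
  d1 <- generateStudy(cfg, seed = 9)
  d2 <- generateStudy(cfg, seed = 9)
  expect_identical(granules(d1), granules(d2))
  expect_identical(rois(d1), rois(d2))
  expect_identical(lapply(meshes(d1), meshVertices),
                   lapply(meshes(d2), meshVertices))
  d3 <- generateStudy(cfg, seed = 10)
  expect_false(identical(granules(d1), granules(d3)))
})

test_that("zero density SD collapses per-ROI densities to the mean", {
  cfg <- smallConfig(0.1)
  for (nm in names(cfg$conditions)) {
    cfg$conditions[[nm]]$densitySd <- 0
    cfg$conditions[[nm]]$densitySem <- 0
  }
  ds <- generateStudy(cfg, seed = 12)
  m <- computeRoiMetrics(ds)
  for (nm in names(cfg$conditions)) {
    dens <- m$density[m$condition == nm]
    # exact up to integer granule rounding: |count - mean*astro| <= 0.5
    astro <- m$astro_volume_um3[m$condition == nm]
    expect_true(all(abs(dens - cfg$conditions[[nm]]$densityMean) <=
                      0.5 / astro + 1e-9))
  }
})

test_that("generated datasets satisfy the schema and geometric invariants", {
  ds <- generateStudy(smallConfig(0.1), seed = 13)
  expect_true(validObject(ds))  # bbox containment, volumes, mesh refs
  r <- rois(ds)
  expect_true(all(r$edge_x_nm >= 2000 & r$edge_x_nm <= 4000))
  frac <- r$astro_volume_um3 / r$roi_volume_um3
  expect_true(all(frac >= 0.05 & frac <= 0.15))
  # ASI polygon area equals the recorded area
  for (ref in names(meshes(ds))[1:5]) {
    m <- meshes(ds)[[ref]]
    v <- meshVertices(m); p <- perimeterIndices(m)
    ctr <- colMeans(v[p, ])
    a <- 0
    for (s in seq_along(p)) {
      i <- p[s]; j <- p[ifelse(s == length(p), 1, s + 1)]
      a <- a + 0.5 * sqrt(sum(crossProd3(v[i, ] - ctr, v[j, ] - ctr)^2))
    }
    expect_equal(a / 1e6, r$asi_area_um2[r$asi_mesh_ref == ref],
                 tolerance = 1e-9)
  }
  # three mice per condition, round-robin
  expect_equal(length(unique(r$mouse_id[r$condition == "S"])), 3L)
})

test_that("rank-correlation induction hits its target and preserves margins", {
  set.seed(51)
  # null target: realized rho stays within 3/sqrt(n) almost always
  hits <- replicate(400, {
    pr <- induceRankCorrelation(runif(300), runif(300), 0)
    abs(spearmanTest(pr$x, pr$y)$estimate) < 3 / sqrt(300)
  })
  expect_gte(mean(hits), 0.97)

  # strong target at large n
  pr <- induceRankCorrelation(runif(10000), runif(10000), -0.2)
  rho <- spearmanTest(pr$x, pr$y)$estimate
  expect_gt(rho, -0.23); expect_lt(rho, -0.17)

  # margins preserved exactly (rank multiset unchanged)
  u <- rnorm(500); v <- rexp(500)
  pr2 <- induceRankCorrelation(u, v, 0.6)
  expect_identical(sort(pr2$x), sort(u))
  expect_identical(sort(pr2$y), sort(v))

  expect_error(induceRankCorrelation(runif(10), runif(10), 1),
               "configuration error")
})

test_that("granule distances recovered by the pipeline equal the generated ones", {
  # placement contract: the nearest unique vertex of the ASI mesh is the
  # anchor vertex, so distances are exactly the drawn values; all far
  # granules must fall outside the 500 nm window, near granules inside
  ds <- generateStudy(smallConfig(0.08), seed = 14)
  rec <- granuleDistances(ds, windowNm = 500)
  expect_true(all(rec$distance_nm >= 0))
  expect_true(all(rec$distance_nm <= 950 + 1e-9))
  # bimodal by construction: nothing between 500 and 520
  expect_equal(sum(rec$distance_nm > 500 & rec$distance_nm < 520), 0L)
})
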