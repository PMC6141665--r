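#' @include AllClasses.R
NULL

## ---- truncated-normal helpers (quantile + moment matching) ----------

.tnQ <- function(p, mu, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(mu, length(p)))
  pa <- stats::pnorm(lo, mu, sd); pb <- stats::pnorm(hi, mu, sd)
  q <- stats::qnorm(pa + p * (pb - pa), mu, sd)
  pmin(pmax(q, lo), hi)
}

.tnMean <- function(mu, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(mu)
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / Z
}

## location parameter such that the [lo, hi]-truncated normal with the
## given sd has the requested mean
.tnSolveMu <- function(target, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(target)
  f <- function(mu) .tnMean(mu, sd, lo, hi) - target
  stats::uniroot(f, lower = target - 6 * sd, upper = target + 6 * sd,
                 tol = 1e-10)$root
}

.qlnormTrunc <- function(p, meanlog, sdlog, lo, hi) {
  pa <- stats::plnorm(lo, meanlog, sdlog); pb <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(pa + p * (pb - pa), meanlog, sdlog)
}

## ---- configuration ---------------------------------------------------

#' Per-condition generator parameters
#'
#' Bundles the per-condition calibration of the synthetic-study
#' generator. Population SDs are derived from the supplied standard
#' errors as SD = SEM * sqrt(n), with n the ROI count for ROI-level
#' variables (density, per-ROI mean distance) and the expected granule
#' count for the granule-level diameter.
#'
#' @param condition condition label ("S", "W", "SD" or "CSR").
#' @param nRois number of ROIs.
#' @param densityMean,densitySem normalized granule density, per um^3.
#' @param diamMean,diamSem granule diameter, nm.
#' @param nGranulesExpected granule count backing the diameter SEM.
#' @param distMean,distSem per-ROI mean within-window granule-to-ASI
#'   distance, nm.
#' @param serPrev,mitoPrev prevalence of SER-positive spine heads and of
#'   presynaptic mitochondria, fractions in [0, 1].
#' @param rankCorrs named list of target Spearman correlations:
#'   \code{density_asi} (log2 density vs ASI area, ROI level),
#'   \code{diam_dist} (diameter vs distance, within-window granules),
#'   \code{cov_dist} (ASI coverage vs mean distance, ROI level).
#' @return a list of class \code{"ConditionParams"}.
#' @export
conditionParams <- function(condition, nRois, densityMean, densitySem,
                            diamMean, diamSem, nGranulesExpected,
                            distMean, distSem, serPrev, mitoPrev,
                            rankCorrs = list(density_asi = 0, diam_dist = 0,
                                             cov_dist = 0)) {
  stopifnot(condition %in% .CONDITIONS, nRois > 0,
            densityMean > 0, diamMean > 0, distMean > 0,
            serPrev >= 0, serPrev <= 1, mitoPrev >= 0, mitoPrev <= 1)
  if (any(abs(unlist(rankCorrs)) >= 1))
    stop("configuration error: target Spearman correlations must satisfy |rho| < 1")
  structure(list(
    condition = condition, nRois = as.integer(nRois),
    densityMean = densityMean, densitySem = densitySem,
    densitySd = densitySem * sqrt(nRois),
    diamMean = diamMean, diamSem = diamSem,
    diamSd = diamSem * sqrt(nGranulesExpected),
    nGranulesExpected = as.integer(nGranulesExpected),
    distMean = distMean, distSem = distSem,
    distSd = distSem * sqrt(nRois),
    serPrev = serPrev, mitoPrev = mitoPrev,
    rankCorrs = rankCorrs), class = "ConditionParams")
}

#' Default synthetic-study configuration
#'
#' Returns the calibrated defaults of the generator: four conditions
#' (S, W, SD, CSR; sleep, spontaneous wake, acute sleep deprivation,
#' chronic sleep restriction) with the per-condition ROI counts,
#' normalized-density, diameter and distance summaries, synapse-flag
#' prevalences and target rank correlations of the study design the
#' generator emulates, plus the global geometric assumptions (cuboid
#' edge range, astrocytic volume fraction, ASI area distribution,
#' perimeter discretisation, near-synapse granule fraction).
#'
#' @return list with elements \code{conditions} (named list of
#'   \code{\link{conditionParams}}) and \code{global} (named list of
#'   generator-wide parameters).
#' @export
defaultStudyConfig <- function() {
  conditions <- list(
    S = conditionParams("S", 308, 103.6, 5.4, 27.2, 0.1, 3248,
                        357.2, 6.9, 0.575, 0.695,
                        rankCorrs = list(density_asi = -0.16,
                                         diam_dist = -0.001,
                                         cov_dist = -0.07)),
    W = conditionParams("W", 268, 116.3, 5.2, 27.1, 0.1, 3718,
                        368.7, 7.6, 0.359, 0.661,
                        rankCorrs = list(density_asi = -0.16,
                                         diam_dist = 0, cov_dist = 0)),
    SD = conditionParams("SD", 339, 125.7, 3.8, 26.9, 0.1, 5399,
                         366.5, 6.9, 0.472, 0.677,
                         rankCorrs = list(density_asi = -0.1,
                                          diam_dist = 0, cov_dist = 0)),
    CSR = conditionParams("CSR", 339, 123.1, 4.7, 26.3, 0.1, 4289,
                          334.9, 6.1, 0.486, 0.599,
                          rankCorrs = list(density_asi = 0,
                                           diam_dist = -0.16,
                                           cov_dist = -0.2)))
  global <- list(
    edgeRangeNm = c(2000, 4000),      # cuboid ROI edge lengths
    astroFracRange = c(0.05, 0.15),   # astro volume / ROI volume
    windowNm = 500,                   # distance inclusion window
    asiAreaMeanlog = log(0.09),       # lognormal ASI area, um^2
    asiAreaSdlog = 0.6,
    asiAreaRangeUm2 = c(0.01, 0.6),
    coverageBeta = c(5, 5),           # ASI perimeter coverage marginal
    pNear = 0.15,                     # fraction of granules near the ASI
    withinRoiJitterNm = 75,           # half-width of within-ROI spread
    farRangeNm = c(520, 950),         # out-of-window granule distances
    perimeterSegments = 32L,
    nMice = 3L,
    diamFamily = "truncnorm")         # or "lognormal"
  list(conditions = conditions, global = global)
}

#' Scale a study configuration down
#'
#' Reduces the per-condition ROI counts (for fast exploratory runs and
#' tests) while leaving every distributional parameter -- including the
#' population SDs already derived from the full-size SEMs -- untouched.
#'
#' @param config a study configuration (see
#'   \code{\link{defaultStudyConfig}}).
#' @param roiFactor multiplier applied to each condition's ROI count;
#'   the result is floored at 8 ROIs.
#' @return the scaled configuration.
#' @export
scaleStudyConfig <- function(config, roiFactor) {
  for (nm in names(config$conditions))
    config$conditions[[nm]]$nRois <-
      max(8L, as.integer(round(config$conditions[[nm]]$nRois * roiFactor)))
  config
}

## ---- rank-correlation induction -------------------------------------

#' Pair two samples at a target Spearman correlation
#'
#' Induces a target Spearman rank correlation between two marginal
#' samples through a Gaussian copula: a latent bivariate normal pair
#' with Pearson correlation r = 2 sin(pi rho / 6) supplies the joint
#' ranks, and the sorted values of \code{u} and \code{v} are assigned to
#' those ranks. The marginal multisets of both inputs are preserved
#' exactly; the realized sample Spearman correlation fluctuates around
#' the target with SD of roughly 1/sqrt(n). Consumes random numbers
#' from the current RNG stream.
#'
#' @param u,v numeric vectors of equal length (the marginal samples;
#'   latent uniforms in copula use, but any margins are allowed).
#' @param rho target Spearman correlation, |rho| < 1.
#' @return list with elements \code{x} and \code{y}: the re-paired
#'   samples, and \code{latentR}: the latent Pearson correlation used.
#' @export
induceRankCorrelation <- function(u, v, rho) {
  n <- length(u)
  if (length(v) != n) stop("u and v must have equal length")
  if (!is.finite(rho) || abs(rho) >= 1)
    stop("configuration error: |rho| must be < 1")
  r <- 2 * sin(pi * rho / 6)
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  list(x = sort(u)[rank(z1, ties.method = "first")],
       y = sort(v)[rank(z2, ties.method = "first")],
       latentR = r)
}

## rank template for coupling an existing ordering to fresh draws:
## element with x-rank j receives the y-value of rank yRankForXRank[j]
.coupledRankTemplate <- function(n, rho) {
  r <- 2 * sin(pi * rho / 6)
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  rank(z2, ties.method = "first")[order(z1)]
}

## ---- mesh construction ----------------------------------------------

## planar triangle-fan disc with k perimeter vertices; polygon area is
## exactly areaUm2
.discMesh <- function(areaUm2, center, k = 32L, phase = 0,
                      coverage = 0, startSeg = 1L) {
  areaNm2 <- areaUm2 * 1e6
  r <- sqrt(2 * areaNm2 / (k * sin(2 * pi / k)))
  th <- phase + 2 * pi * (seq_len(k) - 1L) / k
  ring <- cbind(center[1] + r * cos(th), center[2] + r * sin(th),
                rep(center[3], k))
  vertices <- rbind(ring, matrix(center, 1L, 3L))
  faces <- cbind(seq_len(k), c(seq_len(k)[-1L], 1L), rep(k + 1L, k))
  nc <- as.integer(round(coverage * k))
  labels <- rep(FALSE, k)
  if (nc > 0L) labels[(startSeg - 1L + seq_len(nc) - 1L) %% k + 1L] <- TRUE
  AsiMesh(vertices, faces, perimeter = seq_len(k), contactLabels = labels)
}

## ---- the generator ---------------------------------------------------

#' Generate a seeded synthetic study
#'
#' Generates a \linkS4class{StudyDataset} with the structure the
#' analysis pipeline expects: per condition, cuboid ROIs with edges
#' uniform in the configured range, astrocytic volumes as a uniform
#' fraction of the ROI volume, granule counts whose normalized density
#' has the configured mean and SD (gamma-distributed per-ROI density
#' targets, rounded to integer counts), granule diameters from a
#' truncated-normal (or lognormal) marginal, granule positions offset
#' from ASI mesh vertices along the mesh normal so that nearest-vertex
#' distances follow a moment-matched truncated-normal per-ROI location
#' with symmetric within-ROI spread, planar-disc ASI meshes with the
#' configured area distribution, Bernoulli synapse flags, and target
#' Spearman correlations induced through a Gaussian copula
#' (\code{\link{induceRankCorrelation}}). Deterministic for a fixed
#' seed.
#'
#' @param config study configuration, see
#'   \code{\link{defaultStudyConfig}}.
#' @param seed integer RNG seed, recorded in the dataset metadata.
#' @return a \linkS4class{StudyDataset}.
#' @export
generateStudy <- function(config = defaultStudyConfig(), seed) {
  if (missing(seed)) stop("a seed is required for reproducible generation")
  set.seed(as.integer(seed))
  glb <- config$global
  k <- as.integer(glb$perimeterSegments)
  win <- glb$windowNm
  roiTabs <- list(); granTabs <- list(); meshList <- list()
  for (cnd in names(config$conditions)) {
    cp <- config$conditions[[cnd]]
    n <- cp$nRois
    ## --- ROI geometry ---
    edges <- matrix(stats::runif(3L * n, glb$edgeRangeNm[1], glb$edgeRangeNm[2]),
                    n, 3L)
    roiV <- nm3ToUm3(edges[, 1] * edges[, 2] * edges[, 3])
    astro <- stats::runif(n, glb$astroFracRange[1], glb$astroFracRange[2]) * roiV
    ## --- density / ASI area, copula-coupled ---
    pr <- induceRankCorrelation(stats::runif(n), stats::runif(n),
                                cp$rankCorrs$density_asi)
    lambda <- if (cp$densitySd > 0) {
      shape <- (cp$densityMean / cp$densitySd)^2
      stats::qgamma(pr$x, shape = shape, scale = cp$densitySd^2 / cp$densityMean)
    } else rep(cp$densityMean, n)
    asi <- .qlnormTrunc(pr$y, glb$asiAreaMeanlog, glb$asiAreaSdlog,
                        glb$asiAreaRangeUm2[1], glb$asiAreaRangeUm2[2])
    count <- as.integer(round(lambda * astro))
    ## --- per-ROI distance location / coverage, copula-coupled ---
    muAdj <- .tnSolveMu(cp$distMean, cp$distSd, 0, win)
    pc <- induceRankCorrelation(stats::runif(n), stats::runif(n),
                                cp$rankCorrs$cov_dist)
    ## cov_dist coupling is negative in distance: pair coverage against
    ## the distance location directly
    m <- .tnQ(pc$x, muAdj, cp$distSd, 0, win)
    cov <- stats::qbeta(pc$y, glb$coverageBeta[1], glb$coverageBeta[2])
    ## --- flags, ids ---
    ser <- stats::runif(n) < cp$serPrev
    mito <- stats::runif(n) < cp$mitoPrev
    roiId <- sprintf("%s_%04d", cnd, seq_len(n))
    meshRef <- sprintf("mesh_%s_%04d", cnd, seq_len(n))
    mouse <- sprintf("%s_m%d", cnd, (seq_len(n) - 1L) %% glb$nMice + 1L)
    roiTabs[[cnd]] <- data.frame(
      roi_id = roiId, condition = cnd, mouse_id = mouse,
      bbox_x_nm = 0, bbox_y_nm = 0, bbox_z_nm = 0,
      edge_x_nm = edges[, 1], edge_y_nm = edges[, 2], edge_z_nm = edges[, 3],
      roi_volume_um3 = roiV, astro_volume_um3 = astro, asi_area_um2 = asi,
      ser_flag = ser, mito_flag = mito, asi_mesh_ref = meshRef,
      stringsAsFactors = FALSE)
    ## --- meshes ---
    ctr <- edges / 2
    phase <- stats::runif(n, 0, 2 * pi)
    startSeg <- sample.int(k, n, replace = TRUE)
    condMeshes <- vector("list", n)
    for (i in seq_len(n))
      condMeshes[[i]] <- .discMesh(asi[i], ctr[i, ], k, phase[i],
                                   coverage = cov[i], startSeg = startSeg[i])
    names(condMeshes) <- meshRef
    meshList[[cnd]] <- condMeshes
    ## --- granules ---
    total <- sum(count)
    roiIdx <- rep(seq_len(n), count)
    near <- stats::runif(total) < glb$pNear
    d <- numeric(total)
    if (any(near)) {
      mi <- m[roiIdx[near]]
      w <- pmin(glb$withinRoiJitterNm, mi, win - mi)
      d[near] <- mi + stats::runif(sum(near), -w, w)
    }
    if (any(!near))
      d[!near] <- stats::runif(sum(!near), glb$farRangeNm[1], glb$farRangeNm[2])
    ## diameters
    uD <- stats::runif(total)
    diam <- if (identical(glb$diamFamily, "lognormal")) {
      sdlog <- sqrt(log(1 + (cp$diamSd / cp$diamMean)^2))
      stats::qlnorm(uD, log(cp$diamMean) - sdlog^2 / 2, sdlog)
    } else {
      .tnQ(uD, .tnSolveMu(cp$diamMean, cp$diamSd, 0, Inf), cp$diamSd, 0, Inf)
    }
    diam <- pmax(diam, 1e-6)
    ## diameter-vs-distance coupling among near (within-window) granules
    if (cp$rankCorrs$diam_dist != 0 && sum(near) > 2L) {
      idx <- which(near)
      tmpl <- .coupledRankTemplate(length(idx), cp$rankCorrs$diam_dist)
      od <- idx[order(d[idx])]
      diam[od] <- sort(diam[idx])[tmpl]
    }
    ## placement: anchor vertex + distance along the disc normal (z), so
    ## the nearest unique vertex is the anchor at exactly distance d
    anchor <- integer(total); px <- numeric(total); py <- numeric(total)
    pz <- numeric(total)
    if (total > 0L) {
      anchor <- sample.int(k + 1L, total, replace = TRUE)
      sgn <- sample(c(-1, 1), total, replace = TRUE)
      idxByRoi <- split(seq_len(total), roiIdx)
      for (nm in names(idxByRoi)) {
        sel <- idxByRoi[[nm]]
        vv <- meshVertices(condMeshes[[as.integer(nm)]])
        px[sel] <- vv[anchor[sel], 1L]
        py[sel] <- vv[anchor[sel], 2L]
        pz[sel] <- vv[anchor[sel], 3L] + sgn[sel] * d[sel]
      }
    }
    granTabs[[cnd]] <- data.frame(
      granule_id = sprintf("%s_g%06d", cnd, seq_len(total)),
      roi_id = roiId[roiIdx], x_nm = px, y_nm = py, z_nm = pz,
      diameter_nm = diam, stringsAsFactors = FALSE)
  }
  rois <- do.call(rbind, unname(roiTabs))
  granules <- do.call(rbind, unname(granTabs))
  meshes <- do.call(c, unname(meshList))
  StudyDataset(granules, rois, meshes,
               meta = list(seed = as.integer(seed),
                           generator = "glycoPAP::generateStudy",
                           windowNm = win))
}

#' Read or write a study configuration as YAML
#'
#' @param path YAML file path.
#' @return \code{readStudyConfig}: a configuration list as returned by
#'   \code{\link{defaultStudyConfig}}.
#' @export
readStudyConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  conditions <- lapply(raw$conditions, function(cc) {
    cp <- conditionParams(cc$condition, cc$nRois, cc$densityMean,
                          cc$densitySem, cc$diamMean, cc$diamSem,
                          cc$nGranulesExpected, cc$distMean, cc$distSem,
                          cc$serPrev, cc$mitoPrev, rankCorrs = cc$rankCorrs)
    ## derived SDs are persisted explicitly so that configurations whose
    ## ROI counts were rescaled after derivation survive a round-trip
    for (sd in c("densitySd", "diamSd", "distSd"))
      if (!is.null(cc[[sd]])) cp[[sd]] <- cc[[sd]]
    cp
  })
  glb <- defaultStudyConfig()$global
  glb[names(raw$global)] <- raw$global
  glb$perimeterSegments <- as.integer(glb$perimeterSegments)
  glb$nMice <- as.integer(glb$nMice)
  list(conditions = conditions, global = glb)
}

#' @rdname readStudyConfig
#' @param config configuration list to write.
#' @export
writeStudyConfig <- function(config, path) {
  strip <- function(cc) cc[c("condition", "nRois", "densityMean", "densitySem",
                             "densitySd", "diamMean", "diamSem", "diamSd",
                             "nGranulesExpected", "distMean", "distSem",
                             "distSd", "serPrev", "mitoPrev", "rankCorrs")]
  yaml::write_yaml(list(conditions = lapply(config$conditions, strip),
                        global = config$global), path)
  invisible(path)
}
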