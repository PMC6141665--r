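#' @include AllClasses.R geometry.R metrics.R stats.R
NULL

.sem <- function(x) stats::sd(x) / sqrt(length(x))

.condFactor <- function(x) factor(x, levels = .CONDITIONS)

.summaryRows <- function(stage, metric, grain, values, condition, group = "all") {
  cf <- .condFactor(condition)
  keep <- !is.na(values) & !is.na(cf)
  values <- values[keep]; cf <- droplevels(cf[keep])
  do.call(rbind, lapply(levels(cf), function(lv) {
    v <- values[cf == lv]
    data.frame(stage = stage, metric = metric, grain = grain,
               condition = lv, group = group, n = length(v),
               mean = mean(v), sem = .sem(v), stringsAsFactors = FALSE)
  }))
}

.omnibusRow <- function(stage, metric, grain, kw) {
  data.frame(stage = stage, metric = metric, grain = grain,
             test = "kruskal_wallis", statistic = kw$statistic,
             df = kw$df, p = kw$p.value, stringsAsFactors = FALSE)
}

.posthocRows <- function(stage, metric, ph) {
  cbind(data.frame(stage = stage, metric = metric, stringsAsFactors = FALSE),
        ph)
}

.corrRow <- function(stage, condition, xvar, yvar, grain, st, nExcluded = 0L) {
  data.frame(stage = stage, condition = condition, xvar = xvar, yvar = yvar,
             grain = grain, n = st$n, n_excluded = as.integer(nExcluded),
             rho = st$estimate, p = st$p.value, stringsAsFactors = FALSE)
}

#' Run the full perisynaptic-glycogen analysis
#'
#' Executes the complete analysis battery on a conforming
#' \linkS4class{StudyDataset} and returns a \linkS4class{StatReport}:
#' \enumerate{
#'   \item ROI-volume comparability across conditions (Kruskal-Wallis);
#'   \item normalized granule density per condition, omnibus + Dunn;
#'   \item per-condition Spearman correlation of (log2) density vs ASI
#'     area;
#'   \item density stratified by SER and by presynaptic mitochondrion:
#'     between-condition tests within each flag level, and two-group
#'     flag comparisons within each condition (Dunn on two groups,
#'     i.e. a tie-corrected rank test);
#'   \item granule diameter and estimated glucose residues per
#'     condition (granule grain), omnibus + Dunn;
#'   \item within-window per-ROI mean granule-to-ASI distance, omnibus
#'     + Dunn;
#'   \item granule-level diameter-vs-distance Spearman in S and CSR
#'     (within-window granules);
#'   \item ROI-level coverage-vs-mean-distance Spearman in S and CSR.
#' }
#' Every summary row records its grain (roi or granule) and every post
#' hoc row the adjustment method. Condition order is fixed to S, W, SD,
#' CSR throughout.
#'
#' @param dataset a \linkS4class{StudyDataset}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param skipMissingGeometry if TRUE, ROIs without a resolvable ASI
#'   mesh are dropped from the distance and coverage stages (with the
#'   offending ROIs recorded in the report metadata) instead of
#'   aborting the run; density/diameter/GR stages are unaffected.
#' @return a \linkS4class{StatReport}.
#' @export
runFullAnalysis <- function(dataset, config = pipelineConfig(),
                            skipMissingGeometry = FALSE) {
  r <- rois(dataset); g <- granules(dataset)
  win <- config@windowNm
  stageErrors <- list()
  missingMesh <- setdiff(r$asi_mesh_ref, names(meshes(dataset)))
  if (length(missingMesh) && !skipMissingGeometry)
    stop("distance stage aborted: no ASI mesh for ROI ",
         paste(utils::head(r$roi_id[r$asi_mesh_ref %in% missingMesh], 3L),
               collapse = ", "))
  if (length(missingMesh))
    stageErrors$geometry <- sprintf(
      "distance/coverage stages skipped ROI(s) without mesh: %s",
      paste(r$roi_id[r$asi_mesh_ref %in% missingMesh], collapse = ", "))
  distances <- granuleDistances(dataset, windowNm = win,
                                mode = config@distanceMode,
                                skipMissingGeometry = skipMissingGeometry)
  metrics <- computeRoiMetrics(dataset, distances, config@grParams, win)
  cf <- .condFactor(metrics$condition)
  summaries <- list(); omnibus <- list(); posthoc <- list(); corrs <- list()

  multiCond <- nlevels(droplevels(cf)) >= 2L && nrow(metrics) >= 3L

  ## (1) ROI-volume comparability
  summaries$vol <- .summaryRows("roi_volume", "roi_volume", "roi",
                                metrics$roi_volume_um3, metrics$condition)
  if (multiCond)
    omnibus$vol <- .omnibusRow("roi_volume", "roi_volume", "roi",
                               kruskalWallis(metrics$roi_volume_um3, cf))

  ## (2) density
  summaries$dens <- .summaryRows("density", "density", "roi",
                                 metrics$density, metrics$condition)
  if (multiCond) {
    omnibus$dens <- .omnibusRow("density", "density", "roi",
                                kruskalWallis(metrics$density, cf))
    posthoc$dens <- .posthocRows("density", "density",
                                 dunnPosthoc(metrics$density, cf,
                                             adjustment = config@adjustment))
  }

  ## (3) (log2) density vs ASI area, per condition
  for (cnd in levels(cf)) {
    sel <- metrics$condition == cnd
    dens <- metrics$density[sel]; area <- metrics$asi_area_um2[sel]
    if (config@log2DensityForAsiCorr) {
      keep <- dens > 0
      nEx <- sum(!keep)
      st <- try(spearmanTest(log2(dens[keep]), area[keep]), silent = TRUE)
      xvar <- "log2_density"
    } else {
      nEx <- 0L
      st <- try(spearmanTest(dens, area), silent = TRUE)
      xvar <- "density"
    }
    if (!inherits(st, "try-error"))
      corrs[[paste0("da_", cnd)]] <-
        .corrRow("density_vs_asi", cnd, xvar, "asi_area", "roi", st, nEx)
  }

  ## (4) stratified densities
  for (flag in c("ser_flag", "mito_flag")) {
    short <- sub("_flag", "", flag)
    parts <- stratifyMetrics(metrics, flag)
    for (side in c("positive", "negative")) {
      mm <- parts[[side]]
      lab <- paste0(short, ifelse(side == "positive", "_pos", "_neg"))
      stage <- paste0("density_by_", short)
      summaries[[paste0(lab, "_sum")]] <-
        .summaryRows(stage, "density", "roi", mm$density, mm$condition,
                     group = lab)
      cfSub <- droplevels(.condFactor(mm$condition))
      if (nlevels(cfSub) >= 2L && nrow(mm) >= 3L) {
        omnibus[[lab]] <- .omnibusRow(paste0(stage, "_", lab), "density",
                                      "roi", kruskalWallis(mm$density, cfSub))
      }
    }
    ## within-condition two-group comparison (flag+ vs flag-)
    for (cnd in levels(cf)) {
      mm <- metrics[metrics$condition == cnd, ]
      fl <- factor(ifelse(mm[[flag]], paste0(short, "+"), paste0(short, "-")),
                   levels = paste0(short, c("+", "-")))
      if (nlevels(droplevels(fl)) == 2L && nrow(mm) >= 3L) {
        ph <- dunnPosthoc(mm$density, droplevels(fl), adjustment = "none")
        posthoc[[paste0(flag, cnd)]] <-
          .posthocRows(paste0("density_by_", short, "_within_", cnd),
                       "density", ph)
      }
    }
  }

  ## (5) diameter and GR, granule grain
  if (nrow(g)) {
    gCond <- r$condition[match(g$roi_id, r$roi_id)]
    gr <- glucoseResidues(g$diameter_nm, config@grParams)
    gcf <- .condFactor(gCond)
    summaries$diam <- .summaryRows("diameter", "diameter", "granule",
                                   g$diameter_nm, gCond)
    summaries$gr <- .summaryRows("gr", "gr", "granule", gr, gCond)
    if (nlevels(droplevels(gcf)) >= 2L && nrow(g) >= 3L) {
      omnibus$diam <- .omnibusRow("diameter", "diameter", "granule",
                                  kruskalWallis(g$diameter_nm, gcf))
      posthoc$diam <- .posthocRows("diameter", "diameter",
                                   dunnPosthoc(g$diameter_nm, gcf,
                                               adjustment = config@adjustment))
      omnibus$gr <- .omnibusRow("gr", "gr", "granule", kruskalWallis(gr, gcf))
      posthoc$gr <- .posthocRows("gr", "gr",
                                 dunnPosthoc(gr, gcf,
                                             adjustment = config@adjustment))
    }
  }

  ## (6) within-window per-ROI mean distances
  hasDist <- !is.na(metrics$mean_distance)
  summaries$dist <- .summaryRows("distance", "mean_distance", "roi",
                                 metrics$mean_distance, metrics$condition)
  if (sum(hasDist) >= 3L &&
      nlevels(droplevels(cf[hasDist])) >= 2L) {
    dsub <- metrics$mean_distance[hasDist]
    csub <- droplevels(cf[hasDist])
    omnibus$dist <- .omnibusRow("distance", "mean_distance", "roi",
                                kruskalWallis(dsub, csub))
    posthoc$dist <- .posthocRows("distance", "mean_distance",
                                 dunnPosthoc(dsub, csub,
                                             adjustment = config@adjustment))
  }

  ## (7) granule-level diameter vs distance, S and CSR
  if (nrow(g) && NROW(distances)) {
    ww <- applyWindow(distances, win)
    wwCond <- r$condition[match(ww$roi_id, r$roi_id)]
    wwDiam <- g$diameter_nm[match(ww$granule_id, g$granule_id)]
    for (cnd in c("S", "CSR")) {
      sel <- wwCond == cnd
      if (sum(sel) >= 3L) {
        st <- try(spearmanTest(wwDiam[sel], ww$distance_nm[sel]), silent = TRUE)
        if (!inherits(st, "try-error"))
          corrs[[paste0("dd_", cnd)]] <-
            .corrRow("diam_vs_dist", cnd, "diameter", "distance", "granule", st)
      }
    }
  }

  ## (8) ROI-level coverage vs mean distance, S and CSR
  for (cnd in c("S", "CSR")) {
    sel <- metrics$condition == cnd & !is.na(metrics$mean_distance) &
      !is.na(metrics$coverage)
    if (sum(sel) >= 3L) {
      st <- try(spearmanTest(metrics$coverage[sel],
                             metrics$mean_distance[sel]), silent = TRUE)
      if (!inherits(st, "try-error"))
        corrs[[paste0("cd_", cnd)]] <-
          .corrRow("coverage_vs_dist", cnd, "coverage", "mean_distance",
                   "roi", st)
    }
  }

  rb <- function(lst, empty) {
    out <- do.call(rbind, unname(lst))
    if (is.null(out)) empty else { rownames(out) <- NULL; out }
  }
  StatReport(
    summaries = rb(summaries, .emptySummaries()),
    omnibus = rb(omnibus, .emptyOmnibus()),
    posthoc = rb(posthoc, .emptyPosthoc()),
    correlations = rb(corrs, .emptyCorrelations()),
    perRoi = metrics,
    meta = list(windowNm = win, alpha = config@alpha,
                adjustment = config@adjustment,
                distanceMode = config@distanceMode,
                log2DensityForAsiCorr = config@log2DensityForAsiCorr,
                datasetSeed = studyMeta(dataset)$seed,
                stage_errors = stageErrors))
}
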