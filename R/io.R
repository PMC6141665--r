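#' @include AllClasses.R
NULL

## Delimited-text I/O for every external artifact. All tables are TSV
## with a header row; numbers are written with 15 significant digits so
## write -> read round-trips are lossless well beyond 6 significant
## digits, and byte-reproducible given identical input.

.fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.15g", v)
  }, character(1L))
  out
}

.writeTsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.double(df2[[j]])) df2[[j]] <- .fmtNum(df2[[j]])
    else if (is.logical(df2[[j]])) df2[[j]] <- ifelse(df2[[j]], "TRUE", "FALSE")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df2), collapse = "\t"), con, sep = "\n")
  if (nrow(df2)) {
    lines <- do.call(paste, c(unname(as.list(df2)), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

.readTsv <- function(path, required, what, colClasses = NA) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path))
  if (!identical(colClasses, NA)) {
    hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
    colClasses <- colClasses[names(colClasses) %in% hdr]
    if (!length(colClasses)) colClasses <- NA
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = colClasses,
                          check.names = FALSE, comment.char = "")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s table %s lacks required column(s): %s",
                 what, path, paste(miss, collapse = ", ")))
  df
}

#' Read and write granule annotation tables
#'
#' Granule tables are tab-delimited text with a header row and columns
#' \code{granule_id}, \code{roi_id}, \code{x_nm}, \code{y_nm},
#' \code{z_nm}, \code{diameter_nm}. Coordinates and diameters are nm.
#'
#' @param path file path.
#' @return \code{readGranuleTable}: data.frame with one row per granule,
#'   row order as in the file.
#' @export
readGranuleTable <- function(path) {
  df <- .readTsv(path, .GRANULE_COLS, "granule",
                 colClasses = c(granule_id = "character", roi_id = "character",
                                x_nm = "numeric", y_nm = "numeric",
                                z_nm = "numeric", diameter_nm = "numeric"))
  bad <- which(!is.finite(df$diameter_nm) | df$diameter_nm <= 0)
  if (length(bad))
    stop(sprintf("non-positive or missing diameter_nm at row %d of %s",
                 bad[1L], path))
  df[.GRANULE_COLS]
}

#' @rdname readGranuleTable
#' @param granules granule data.frame to write.
#' @export
writeGranuleTable <- function(granules, path) {
  miss <- setdiff(.GRANULE_COLS, names(granules))
  if (length(miss))
    stop(sprintf("granule table lacks required column(s): %s",
                 paste(miss, collapse = ", ")))
  .writeTsv(granules[.GRANULE_COLS], path)
}

#' Read and write ROI record tables
#'
#' ROI tables are tab-delimited text with one row per cuboid region of
#' interest; see \linkS4class{StudyDataset} for the column schema.
#' Bounding-box corners and edge lengths are nm, volumes um^3, ASI areas
#' um^2.
#'
#' @param path file path.
#' @return \code{readRoiTable}: data.frame with one row per ROI.
#' @export
readRoiTable <- function(path) {
  num <- c("bbox_x_nm", "bbox_y_nm", "bbox_z_nm", "edge_x_nm", "edge_y_nm",
           "edge_z_nm", "roi_volume_um3", "astro_volume_um3", "asi_area_um2")
  cc <- c(roi_id = "character", condition = "character",
          mouse_id = "character", asi_mesh_ref = "character",
          ser_flag = "logical", mito_flag = "logical",
          stats::setNames(rep("numeric", length(num)), num))
  df <- .readTsv(path, .ROI_COLS, "ROI", colClasses = cc)
  df[.ROI_COLS]
}

#' @rdname readRoiTable
#' @param rois ROI data.frame to write.
#' @export
writeRoiTable <- function(rois, path) {
  miss <- setdiff(.ROI_COLS, names(rois))
  if (length(miss))
    stop(sprintf("ROI table lacks required column(s): %s",
                 paste(miss, collapse = ", ")))
  .writeTsv(rois[.ROI_COLS], path)
}

#' Read a triangulated ASI mesh with its perimeter sidecar
#'
#' Reads a triangle mesh from Wavefront OBJ (ASCII) or PLY (ASCII)
#' format, merges exactly coincident vertices to the unique-vertex set
#' (re-indexing faces), and attaches the ASI perimeter and PAP-contact
#' labels from a sidecar table. The sidecar is tab-delimited with
#' columns \code{v_from}, \code{v_to}, \code{contact}: one row per
#' perimeter segment in traversal order, vertex indices 0-based with
#' respect to the vertex order of the mesh file, and the chain must be
#' closed (\code{v_to} of the last row equals \code{v_from} of the
#' first).
#'
#' @param path mesh file (.obj or .ply, ASCII).
#' @param sidecarPath perimeter/contact sidecar; defaults to
#'   \code{<path>.perimeter.tsv} if that file exists, otherwise the mesh
#'   is returned with an empty perimeter.
#' @return an \linkS4class{AsiMesh}.
#' @export
readAsiMesh <- function(path, sidecarPath = NULL) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  parsed <- switch(ext,
    obj = .parseObj(path),
    ply = .parsePly(path),
    stop("unsupported mesh format '", ext, "' (expected .obj or .ply)"))
  if (is.null(sidecarPath)) {
    cand <- paste0(path, ".perimeter.tsv")
    if (file.exists(cand)) sidecarPath <- cand
  }
  perimeter <- integer(); labels <- logical()
  if (!is.null(sidecarPath)) {
    sc <- .readTsv(sidecarPath, c("v_from", "v_to", "contact"),
                   "perimeter sidecar")
    if (!nrow(sc)) stop("perimeter sidecar is empty: ", sidecarPath)
    vFrom <- as.integer(sc$v_from) + 1L   # sidecar indices are 0-based
    vTo <- as.integer(sc$v_to) + 1L
    if (any(vTo[-nrow(sc)] != vFrom[-1L]) || vTo[nrow(sc)] != vFrom[1L])
      stop("open perimeter in sidecar ", sidecarPath,
           ": segments do not form a closed chain")
    perimeter <- vFrom
    labels <- as.logical(sc$contact)
  }
  AsiMesh(parsed$vertices, parsed$faces, perimeter, labels)
}

.parseObj <- function(path) {
  lines <- readLines(path)
  vLines <- lines[startsWith(lines, "v ")]
  fLines <- lines[startsWith(lines, "f ")]
  vertices <- if (length(vLines)) {
    do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vLines)), "[ \t]+"),
                          function(p) as.numeric(p[1:3])))
  } else matrix(numeric(), 0L, 3L)
  faces <- if (length(fLines)) {
    idx <- lapply(strsplit(trimws(sub("^f", "", fLines)), "[ \t]+"),
                  function(p) as.integer(sub("/.*$", "", p)))
    nv <- lengths(idx)
    if (any(nv != 3L))
      stop("non-triangular face in OBJ file ", path,
           " (face with ", nv[nv != 3L][1L], " vertices)")
    do.call(rbind, idx)
  } else matrix(integer(), 0L, 3L)
  list(vertices = vertices, faces = faces)
}

.parsePly <- function(path) {
  lines <- readLines(path)
  endHdr <- match("end_header", trimws(lines))
  if (is.na(endHdr)) stop("not an ASCII PLY file (no end_header): ", path)
  hdr <- lines[seq_len(endHdr)]
  if (!any(grepl("^format\\s+ascii", hdr)))
    stop("only ASCII PLY is supported: ", path)
  nV <- as.integer(sub("^element\\s+vertex\\s+", "",
                       grep("^element\\s+vertex\\s", hdr, value = TRUE)[1L]))
  nF <- as.integer(sub("^element\\s+face\\s+", "",
                       grep("^element\\s+face\\s", hdr, value = TRUE)[1L]))
  if (is.na(nV)) stop("PLY header lacks a vertex element: ", path)
  if (is.na(nF)) nF <- 0L
  body <- lines[(endHdr + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vertices <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nV)]), "[ \t]+"),
                                    function(p) as.numeric(p[1:3])))
  faces <- matrix(integer(), 0L, 3L)
  if (nF > 0L) {
    fRows <- lapply(strsplit(trimws(body[nV + seq_len(nF)]), "[ \t]+"),
                    as.integer)
    cnt <- vapply(fRows, `[`, integer(1L), 1L)
    if (any(cnt != 3L))
      stop("non-triangular face in PLY file ", path)
    faces <- do.call(rbind, lapply(fRows, function(r) r[2:4] + 1L))
  }
  list(vertices = vertices, faces = faces)
}

#' Write an ASI mesh as OBJ with its perimeter sidecar
#'
#' @param mesh an \linkS4class{AsiMesh}.
#' @param path output .obj path.
#' @param sidecarPath output sidecar path (default
#'   \code{<path>.perimeter.tsv}); only written if the mesh carries a
#'   perimeter.
#' @return \code{path}, invisibly.
#' @export
writeAsiMesh <- function(mesh, path, sidecarPath = paste0(path, ".perimeter.tsv")) {
  v <- mesh@vertices; f <- mesh@faces
  con <- file(path, open = "wb")
  lines <- c(sprintf("v %.15g %.15g %.15g", v[, 1], v[, 2], v[, 3]),
             if (nrow(f)) sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
  writeLines(lines, con, sep = "\n")
  close(con)
  p <- mesh@perimeter
  if (length(p)) {
    sc <- data.frame(v_from = p - 1L, v_to = c(p[-1L], p[1L]) - 1L,
                     contact = mesh@contactLabels)
    .writeTsv(sc, sidecarPath)
  }
  invisible(path)
}

#' Read or write a full study dataset directory
#'
#' A study directory holds \code{granules.tsv}, \code{rois.tsv},
#' \code{meta.yaml} and a \code{meshes/} subdirectory with one OBJ (+
#' perimeter sidecar) per ASI, named by \code{asi_mesh_ref}.
#'
#' @param dir directory path.
#' @return \code{readStudyDataset}: a \linkS4class{StudyDataset}.
#' @export
readStudyDataset <- function(dir) {
  granules <- readGranuleTable(file.path(dir, "granules.tsv"))
  rois <- readRoiTable(file.path(dir, "rois.tsv"))
  metaPath <- file.path(dir, "meta.yaml")
  meta <- if (file.exists(metaPath)) yaml::read_yaml(metaPath) else list()
  refs <- unique(rois$asi_mesh_ref)
  meshes <- lapply(refs, function(ref)
    readAsiMesh(file.path(dir, "meshes", paste0(ref, ".obj"))))
  names(meshes) <- refs
  StudyDataset(granules, rois, meshes, meta)
}

#' @rdname readStudyDataset
#' @param dataset a \linkS4class{StudyDataset} to write.
#' @export
writeStudyDataset <- function(dataset, dir) {
  dir.create(file.path(dir, "meshes"), recursive = TRUE, showWarnings = FALSE)
  writeGranuleTable(granules(dataset), file.path(dir, "granules.tsv"))
  writeRoiTable(rois(dataset), file.path(dir, "rois.tsv"))
  meta <- studyMeta(dataset)
  if (length(meta)) yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  msh <- meshes(dataset)
  for (ref in names(msh))
    writeAsiMesh(msh[[ref]], file.path(dir, "meshes", paste0(ref, ".obj")))
  invisible(dir)
}

#' Write a StatReport as a set of delimited-text tables
#'
#' Writes one tab-delimited table per analysis block: per-condition ROI
#' volumes, densities, stratified densities, diameters, glucose
#' residues, distances, correlations, omnibus tests, post hoc pairs and
#' the per-ROI metric table. Output is deterministic: identical reports
#' produce byte-identical files.
#'
#' @param report a \linkS4class{StatReport}.
#' @param outDir output directory (created if absent).
#' @return character vector of written file paths, invisibly.
#' @export
writeReport <- function(report, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  s <- summaries(report)
  pick <- function(df, keep) df[keep, , drop = FALSE]
  files <- c(
    roi_volumes = "roi_volumes.tsv", densities = "densities.tsv",
    density_stratified = "density_stratified.tsv",
    diameters = "diameters.tsv", glucose_residues = "glucose_residues.tsv",
    distances = "distances.tsv", correlations = "correlations.tsv",
    omnibus = "omnibus.tsv", posthoc = "posthoc.tsv",
    roi_metrics = "roi_metrics.tsv")
  tables <- list(
    roi_volumes = pick(s, s$metric == "roi_volume"),
    densities = pick(s, s$metric == "density" & s$group == "all"),
    density_stratified = pick(s, s$metric == "density" & s$group != "all"),
    diameters = pick(s, s$metric == "diameter"),
    glucose_residues = pick(s, s$metric == "gr"),
    distances = pick(s, s$metric == "mean_distance"),
    correlations = correlationResults(report),
    omnibus = omnibusResults(report),
    posthoc = posthocResults(report),
    roi_metrics = perRoiMetrics(report))
  paths <- character(0L)
  for (nm in names(files)) {
    p <- file.path(outDir, files[[nm]])
    df <- tables[[nm]]
    if (is.null(df) || (nm == "roi_metrics" && !ncol(df)))
      df <- data.frame(roi_id = character())
    .writeTsv(df, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
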