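#' Write / read an ROI trace as CSV with JSON metadata sidecar
#'
#' The CSV holds the samples (columns \code{time_s}, \code{intensity_gu});
#' label and provenance travel in a \code{.json} sidecar next to it.
#'
#' @param trace an \linkS4class{ROITrace}.
#' @param path CSV file path.
#' @return \code{writeTraceCSV} returns \code{path} invisibly;
#'   \code{readTraceCSV} returns the \linkS4class{ROITrace}.
#' @export
writeTraceCSV <- function(trace, path) {
  write.csv(data.frame(time_s = trace@times, intensity_gu = trace@intensities),
            path, row.names = FALSE)
  meta <- list(roi_id = trace@roiId, patient_id = trace@patientId,
               label = trace@label, fps = trace@fps,
               n_samples = length(trace@times))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeTraceCSV
#' @export
readTraceCSV <- function(path) {
  df <- read.csv(path)
  metaPath <- paste0(path, ".json")
  meta <- if (file.exists(metaPath)) jsonlite::read_json(metaPath)
  else list(roi_id = "roi1", patient_id = "p1", label = "healthy", fps = NULL)
  fps <- if (!is.null(meta$fps)) meta$fps
  else 1 / median(diff(df$time_s))
  roiTrace(df$time_s, df$intensity_gu, fps = fps, label = meta$label,
           roiId = meta$roi_id, patientId = meta$patient_id)
}

#' Read / write ROI specifications as JSON
#'
#' The JSON format is an array of objects with fields \code{roi_id},
#' \code{patient_id}, \code{label}, \code{frame} and \code{polygon} (a
#' list of \code{[row, col]} pairs). On disk the coordinates and frame
#' index are 0-based (the interchange convention); in R they are
#' 1-based.
#'
#' @param path JSON file path.
#' @param rois list of \linkS4class{ROISpec} for writing.
#' @return \code{readROISpecs} returns a list of \linkS4class{ROISpec}.
#' @export
readROISpecs <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(r) {
    poly <- do.call(rbind, lapply(r$polygon, function(v)
      c(v[[1]], v[[2]]))) + 1
    roiSpec(poly, label = r$label, roiId = r$roi_id,
            patientId = r$patient_id, frame = r$frame + 1L)
  })
}

#' @rdname readROISpecs
#' @export
writeROISpecs <- function(rois, path) {
  out <- lapply(rois, function(r) list(
    roi_id = r@roiId, patient_id = r@patientId, label = r@label,
    frame = r@frame - 1L,
    polygon = lapply(seq_len(nrow(r@polygon)), function(i)
      as.numeric(r@polygon[i, ] - 1))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a feature table as CSV
#'
#' Missing features are encoded as empty fields.
#'
#' @param table feature table (see [computeFeatureTable()]).
#' @param path CSV file path.
#' @export
writeFeatureTable <- function(table, path) {
  write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .checkFeatureTable(df)
  df
}

#' Write a frame-sequence pair as multi-page TIFF
#'
#' One multi-page TIFF per channel (\code{white_light.tif} stores the
#' luminance of the white-light channel unless \code{rgb = TRUE} writes
#' per-frame RGB pages; \code{nir.tif} stores the NIR stack), 8-bit.
#'
#' @param pair a \linkS4class{FrameSequencePair}.
#' @param dir output directory (created if needed).
#' @param rgb write white-light RGB pages instead of luminance.
#' @return the directory, invisibly.
#' @export
writeSequenceTIFF <- function(pair, dir, rgb = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nFrames(pair)
  nirPages <- lapply(seq_len(n), function(i) pair@nir[i, , ] / 255)
  tiff::writeTIFF(nirPages, file.path(dir, "nir.tif"), bits.per.sample = 8L)
  wlPages <- lapply(seq_len(n), function(i) {
    if (rgb) pair@whiteLight[i, , , ] / 255
    else .luminance(pair@whiteLight[i, , , ]) / 255
  })
  tiff::writeTIFF(wlPages, file.path(dir, "white_light.tif"),
                  bits.per.sample = 8L)
  jsonlite::write_json(list(fps = pair@fps, overlay_mode = pair@overlayMode,
                            timestamps = pair@timestamps),
                       file.path(dir, "sequence.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a frame-sequence pair written by [writeSequenceTIFF()]
#'
#' @param dir directory holding \code{nir.tif}, \code{white_light.tif}
#'   and \code{sequence.json}.
#' @return a \linkS4class{FrameSequencePair}.
#' @export
readSequenceTIFF <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "sequence.json"),
                              simplifyVector = TRUE)
  nirPages <- tiff::readTIFF(file.path(dir, "nir.tif"), all = TRUE)
  wlPages <- tiff::readTIFF(file.path(dir, "white_light.tif"), all = TRUE)
  n <- length(nirPages)
  H <- nrow(nirPages[[1]]); W <- ncol(nirPages[[1]])
  nir <- array(0, c(n, H, W))
  wl <- array(0, c(n, H, W, 3))
  for (i in seq_len(n)) {
    nir[i, , ] <- round(nirPages[[i]] * 255)
    p <- wlPages[[i]]
    if (length(dim(p)) == 2L) for (ch in 1:3) wl[i, , , ch] <- round(p * 255)
    else wl[i, , , ] <- round(p[, , 1:3] * 255)
  }
  frameSequencePair(wl, nir, fps = meta$fps, timestamps = meta$timestamps,
                    overlayMode = isTRUE(meta$overlay_mode))
}

#' Write heatmap products of a stabilized field
#'
#' Writes the centre-of-mass and outflow-slope maps as 32-bit float
#' single-channel TIFFs, their color renderings ([renderMap()]) and the
#' cluster label map and validity mask as PNGs.
#'
#' @param field a \linkS4class{StabilizedField}.
#' @param dir output directory.
#' @param k,seed,featureMode clustering options (see [clusterField()]).
#' @return list of written file paths, invisibly.
#' @export
writeFieldMaps <- function(field, dir, k = 3L, seed = 1L,
                           featureMode = "pwc") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pm <- pixelMilestones(field)
  cl <- clusterField(field, k = k, seed = seed, featureMode = featureMode)
  paths <- list()
  scales <- list()
  wFloat <- function(m, name) {
    ## 32-bit float TIFF normalized to [0, 1]; the affine scale needed
    ## to recover physical units travels in maps.json
    m2 <- m; m2[!is.finite(m2)] <- NA
    lo <- min(m2, na.rm = TRUE); hi <- max(m2, na.rm = TRUE)
    rng <- if (hi > lo) hi - lo else 1
    m2 <- (m2 - lo) / rng
    m2[is.na(m2)] <- 0
    p <- file.path(dir, paste0(name, ".tif"))
    tiff::writeTIFF(m2, p, bits.per.sample = 32L)
    scales[[name]] <<- list(min = lo, max = hi)
    paths[[name]] <<- p
  }
  wFloat(pm$com, "com")
  wFloat(pm$slope, "slope")
  jsonlite::write_json(scales, file.path(dir, "maps.json"),
                       auto_unbox = TRUE, digits = NA)
  wPng <- function(img, name) {
    p <- file.path(dir, paste0(name, ".png"))
    png::writePNG(img, p)
    paths[[paste0(name, "_png")]] <<- p
  }
  wPng(renderMap(pm$com, "viridis"), "com_render")
  wPng(renderMap(pm$slope, "diverging"), "slope_render")
  wPng(renderMap(cl, "labels"), "clusters")
  wPng(field@mask * 1, "validity_mask")
  invisible(paths)
}

## Convert an rpart classification tree into a nested node list.
.rpartToNodes <- function(model) {
  fr <- model$frame
  nodeIds <- as.integer(rownames(fr))
  ylevels <- attr(model, "ylevels")
  splitVar <- as.character(fr$var)
  ## primary split rows of model$splits appear in frame order for
  ## non-leaf nodes (maxcompete = maxsurrogate = 0 at fit time)
  splitRows <- which(splitVar != "<leaf>")
  splitIdx <- integer(nrow(fr)); splitIdx[splitRows] <- seq_along(splitRows)
  build <- function(id) {
    i <- match(id, nodeIds)
    if (splitVar[i] == "<leaf>") {
      return(list(leaf = TRUE,
                  class = ylevels[fr$yval[i]],
                  n = fr$n[i]))
    }
    sp <- model$splits[splitIdx[i], ]
    thr <- unname(sp["index"])
    ## ncat = -1: left branch is < threshold; +1: left is >= threshold
    op <- if (sp["ncat"] < 0) "<" else ">="
    list(leaf = FALSE, feature = splitVar[i], threshold = thr,
         leftIf = op, n = fr$n[i],
         left = build(2L * id), right = build(2L * id + 1L))
  }
  build(1L)
}

#' Save a fitted tree classifier as JSON
#'
#' Serializes the decision tree structure (nodes with feature, threshold
#' and children, leaves with their class) together with the winning
#' hyperparameters and imputation medians.
#'
#' @param clf a \linkS4class{FittedClassifier} of family \code{"tree"}.
#' @param path JSON file path.
#' @export
writeModelJSON <- function(clf, path) {
  if (clf@family != "tree")
    .stopf("JSON export is defined for tree models")
  out <- list(family = clf@family, params = clf@params,
              cv_accuracy = clf@cvAccuracy,
              impute_medians = as.list(clf@imputeMedians),
              labels = clf@labels,
              tree = .rpartToNodes(clf@model))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save a classifier report as JSON
#'
#' @param report a \linkS4class{ClassifierReport}.
#' @param path JSON file path.
#' @export
writeReportJSON <- function(report, path) {
  out <- list(confusion = list(labels = rownames(report@confusion),
                               counts = unclass(report@confusion)),
              accuracy = report@accuracy, ppv = report@ppv,
              tpr = as.list(report@tpr), fnr = as.list(report@fnr))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
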