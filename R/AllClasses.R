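#' Gamma-variate bolus kinetic parameters
#'
#' Parameters of the gamma-variate inflow/washout model used by the
#' synthetic angiogram generator for one tissue class. The noise-free
#' curve sits at \code{baseline} until \code{arrivalDelay} seconds, then
#' follows a gamma-variate bolus that attains \code{baseline + amplitude}
#' exactly \code{timeToPeak} seconds after arrival; \code{shape} controls
#' how sharply the bolus rises and washes out.
#'
#' @slot baseline numeric, pre-arrival intensity in greyscale units (g.u.),
#'   within [0, 255].
#' @slot arrivalDelay numeric, seconds from injection to dye arrival (>= 0).
#' @slot timeToPeak numeric, seconds from arrival to peak (> 0).
#' @slot amplitude numeric, peak height above baseline in g.u. (> 0).
#' @slot shape numeric, unitless gamma-variate sharpness (> 0).
#' @seealso [gammaVariate()], [calibrateKinetics()]
#' @export
setClass("KineticParams", representation(
  baseline = "numeric", arrivalDelay = "numeric", timeToPeak = "numeric",
  amplitude = "numeric", shape = "numeric"
))

setValidity("KineticParams", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!one(object@baseline) || object@baseline < 0 || object@baseline > 255)
    msg <- c(msg, "baseline must be a scalar in [0, 255]")
  if (!one(object@arrivalDelay) || object@arrivalDelay < 0)
    msg <- c(msg, "arrivalDelay must be a scalar >= 0")
  if (!one(object@timeToPeak) || object@timeToPeak <= 0)
    msg <- c(msg, "timeToPeak must be a positive scalar")
  if (!one(object@amplitude) || object@amplitude < 0)
    msg <- c(msg, "amplitude must be a non-negative scalar")
  if (!one(object@shape) || object@shape <= 0)
    msg <- c(msg, "shape must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Construct kinetic parameters
#'
#' @param baseline,arrivalDelay,timeToPeak,amplitude,shape see
#'   \linkS4class{KineticParams}.
#' @return A \linkS4class{KineticParams} object.
#' @examples
#' kineticParams(0, 8, 16, 124, 0.07)
#' @export
kineticParams <- function(baseline = 0, arrivalDelay = 0, timeToPeak = 20,
                          amplitude = 100, shape = 3) {
  new("KineticParams", baseline = baseline, arrivalDelay = arrivalDelay,
      timeToPeak = timeToPeak, amplitude = amplitude, shape = shape)
}

setMethod("show", "KineticParams", function(object) {
  cat(sprintf(
    "KineticParams: baseline %.3g g.u., delay %.3g s, time-to-peak %.3g s, amplitude %.3g g.u., shape %.3g\n",
    object@baseline, object@arrivalDelay, object@timeToPeak,
    object@amplitude, object@shape))
})

#' Tissue class label image
#'
#' Integer label image partitioning the synthetic field of view into
#' tissue classes, with the class names carried alongside.
#'
#' @slot labels integer matrix (height x width); values index into
#'   \code{classes}.
#' @slot classes character vector of class names (subset of
#'   \code{"healthy"}, \code{"lesion"}, \code{"rim"}, \code{"cyst"},
#'   \code{"background"}).
#' @export
setClass("TissueClassMap", representation(
  labels = "matrix", classes = "character"
))

setValidity("TissueClassMap", function(object) {
  v <- object@labels
  if (!all(v %in% seq_along(object@classes)))
    return("labels must index into classes")
  if (!all(object@classes %in% c("healthy", "lesion", "rim", "cyst", "background")))
    return("unknown tissue class name")
  TRUE
})

#' @describeIn TissueClassMap character matrix of class names per pixel.
#' @param x,object a \code{TissueClassMap}.
#' @export
classLabels <- function(x) {
  m <- matrix(x@classes[x@labels], nrow(x@labels), ncol(x@labels))
  m
}

setMethod("show", "TissueClassMap", function(object) {
  tab <- table(factor(object@classes[object@labels], levels = object@classes))
  cat(sprintf("TissueClassMap %d x %d px\n", nrow(object@labels), ncol(object@labels)))
  print(tab)
})

#' Synchronized dual-channel frame sequence
#'
#' Container for a synchronized white-light (RGB) and near-infrared
#' (greyscale) video pair, the raw material of ICG perfusion analysis.
#'
#' @slot whiteLight numeric array T x H x W x 3, 8-bit values (0-255).
#' @slot nir numeric array T x H x W, 8-bit greyscale units (0-255).
#' @slot timestamps numeric vector of frame times in seconds, strictly
#'   increasing, length T.
#' @slot fps nominal frame rate (frames per second).
#' @slot overlayMode logical; TRUE when the NIR channel was recovered from
#'   a green-overlay video and no independent white-light tracking source
#'   exists (Firefly-style acquisition).
#' @seealso [frameSequencePair()], [renderSequence()], [trackROI()]
#' @export
setClass("FrameSequencePair", representation(
  whiteLight = "array", nir = "array", timestamps = "numeric",
  fps = "numeric", overlayMode = "logical"
))

setValidity("FrameSequencePair", function(object) {
  dw <- dim(object@whiteLight); dn <- dim(object@nir)
  msg <- character()
  if (length(dw) != 4L || dw[4] != 3L)
    msg <- c(msg, "whiteLight must be a T x H x W x 3 array")
  if (length(dn) != 3L)
    msg <- c(msg, "nir must be a T x H x W array")
  if (length(dw) == 4L && length(dn) == 3L && !all(dw[1:3] == dn))
    msg <- c(msg, "whiteLight and nir must agree in T, H, W")
  if (length(dn) == 3L && length(object@timestamps) != dn[1])
    msg <- c(msg, "timestamps must have one entry per frame")
  if (length(object@timestamps) > 1L && any(diff(object@timestamps) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (min(object@nir) < 0 || max(object@nir) > 255)
    msg <- c(msg, "nir intensities must lie in [0, 255]")
  if (length(msg)) msg else TRUE
})

#' Construct a frame-sequence pair
#'
#' @param whiteLight T x H x W x 3 array of 8-bit values.
#' @param nir T x H x W array of 8-bit greyscale units.
#' @param fps nominal frame rate; used to build timestamps when these are
#'   not given.
#' @param timestamps optional explicit frame times (seconds).
#' @param overlayMode logical, see \linkS4class{FrameSequencePair}.
#' @return A \linkS4class{FrameSequencePair}.
#' @export
frameSequencePair <- function(whiteLight, nir, fps = 30,
                              timestamps = NULL, overlayMode = FALSE) {
  if (is.null(timestamps))
    timestamps <- (seq_len(dim(nir)[1]) - 1) / fps
  new("FrameSequencePair", whiteLight = whiteLight, nir = nir,
      timestamps = timestamps, fps = fps, overlayMode = overlayMode)
}

#' @describeIn FrameSequencePair number of frames.
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname FrameSequencePair
#' @export
setMethod("nFrames", "FrameSequencePair", function(object) dim(object@nir)[1])

#' @describeIn FrameSequencePair nominal frame rate.
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))

#' @rdname FrameSequencePair
#' @export
setMethod("frameRate", "FrameSequencePair", function(object) object@fps)

setMethod("show", "FrameSequencePair", function(object) {
  d <- dim(object@nir)
  cat(sprintf(
    "FrameSequencePair: %d frames of %d x %d px at %g fps (%.1f s)%s\n",
    d[1], d[2], d[3], object@fps, diff(range(object@timestamps)),
    if (object@overlayMode) " [overlay mode]" else ""))
})

#' Region-of-interest specification
#'
#' A polygonal region drawn on a reference frame, annotated with a tissue
#' label and provenance identifiers.
#'
#' @slot polygon numeric n x 2 matrix of (row, col) vertices, 1-based pixel
#'   coordinates on the reference frame.
#' @slot label one of \code{"crlm"}, \code{"healthy"}, \code{"benign_cyst"}.
#' @slot roiId,patientId character identifiers.
#' @slot frame integer reference frame index (1-based).
#' @export
setClass("ROISpec", representation(
  polygon = "matrix", label = "character", roiId = "character",
  patientId = "character", frame = "integer"
))

.polygonArea <- function(p) {
  ## shoelace; p is n x 2 (row, col)
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

.segmentsIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

.polygonSelfIntersects <- function(p) {
  n <- nrow(p)
  if (n < 4) return(FALSE)
  segs <- cbind(seq_len(n), c(2:n, 1))
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through closure
      if (.segmentsIntersect(p[segs[i, 1], ], p[segs[i, 2], ],
                             p[segs[j, 1], ], p[segs[j, 2], ])) return(TRUE)
    }
  }
  FALSE
}

setValidity("ROISpec", function(object) {
  msg <- character()
  p <- object@polygon
  if (ncol(p) != 2L || nrow(p) < 3L)
    msg <- c(msg, "polygon must be an n x 2 matrix with n >= 3")
  else {
    if (.polygonArea(p) < 9)
      msg <- c(msg, "polygon area must be at least 9 pixels")
    if (.polygonSelfIntersects(p))
      msg <- c(msg, "polygon must not self-intersect")
  }
  if (!object@label %in% c("crlm", "healthy", "benign_cyst"))
    msg <- c(msg, "label must be one of crlm, healthy, benign_cyst")
  if (length(msg)) msg else TRUE
})

#' Construct an ROI specification
#'
#' @param polygon n x 2 matrix of (row, col) vertices.
#' @param label tissue label (\code{"crlm"}, \code{"healthy"} or
#'   \code{"benign_cyst"}).
#' @param roiId,patientId identifiers.
#' @param frame reference frame index.
#' @return An \linkS4class{ROISpec}.
#' @export
roiSpec <- function(polygon, label, roiId = "roi1", patientId = "p1",
                    frame = 1L) {
  new("ROISpec", polygon = polygon, label = label, roiId = roiId,
      patientId = patientId, frame = as.integer(frame))
}

setMethod("show", "ROISpec", function(object) {
  cat(sprintf("ROISpec %s (%s, patient %s): %d vertices, area %.0f px, frame %d\n",
              object@roiId, object@label, object@patientId,
              nrow(object@polygon), .polygonArea(object@polygon), object@frame))
})

#' Per-frame ROI track
#'
#' Result of template tracking an ROI through the white-light channel:
#' integer (row, col) offsets relative to the reference frame, with a
#' validity flag and normalized cross-correlation score per frame. Frames
#' whose match score fell below threshold carry the last valid offset.
#'
#' @slot offsets numeric T x 2 matrix of (row, col) offsets.
#' @slot valid logical vector length T.
#' @slot score numeric vector length T, match scores in [-1, 1].
#' @export
setClass("ROITrack", representation(
  offsets = "matrix", valid = "logical", score = "numeric"
))

setValidity("ROITrack", function(object) {
  n <- nrow(object@offsets)
  if (ncol(object@offsets) != 2L) return("offsets must be T x 2")
  if (length(object@valid) != n || length(object@score) != n)
    return("valid and score must have one entry per frame")
  if (any(is.na(object@offsets))) return("offsets must be defined for every frame")
  TRUE
})

setMethod("show", "ROITrack", function(object) {
  cat(sprintf("ROITrack: %d frames, %.1f%% valid, max |offset| %.1f px\n",
              nrow(object@offsets), 100 * mean(object@valid),
              max(abs(object@offsets))))
})

#' Region time-fluorescence trace
#'
#' One region's time-fluorescence curve: mean NIR intensity over the
#' (tracked) ROI at each frame of the analysis window.
#'
#' @slot times numeric, seconds from the first frame.
#' @slot intensities numeric, mean greyscale units over the ROI, in [0,255].
#' @slot fps frame rate of the trace.
#' @slot label,roiId,patientId provenance, as in \linkS4class{ROISpec}.
#' @seealso [extractTrace()], [computeFeatures()]
#' @export
setClass("ROITrace", representation(
  times = "numeric", intensities = "numeric", fps = "numeric",
  label = "character", roiId = "character", patientId = "character"
))

setValidity("ROITrace", function(object) {
  msg <- character()
  if (length(object@times) != length(object@intensities))
    msg <- c(msg, "times and intensities must have equal length")
  tol <- 1e-6  # tolerate floating-point drift from smoothing
  if (length(object@intensities) &&
      (min(object@intensities) < -tol || max(object@intensities) > 255 + tol))
    msg <- c(msg, "intensities must lie in [0, 255]")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct an ROI trace
#'
#' @param times,intensities numeric vectors of equal length.
#' @param fps frame rate (Hz).
#' @param label,roiId,patientId provenance strings.
#' @return An \linkS4class{ROITrace}.
#' @export
roiTrace <- function(times, intensities, fps = 30, label = "healthy",
                     roiId = "roi1", patientId = "p1") {
  new("ROITrace", times = times, intensities = intensities, fps = fps,
      label = label, roiId = roiId, patientId = patientId)
}

#' @describeIn ROITrace number of samples in the trace.
#' @param object an \code{ROITrace}.
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname ROITrace
#' @export
setMethod("nSamples", "ROITrace", function(object) length(object@times))

#' @describeIn ROITrace sample times (s).
#' @export
setGeneric("traceTimes", function(object) standardGeneric("traceTimes"))

#' @rdname ROITrace
#' @export
setMethod("traceTimes", "ROITrace", function(object) object@times)

#' @describeIn ROITrace intensity samples (g.u.).
#' @export
setGeneric("traceIntensities", function(object) standardGeneric("traceIntensities"))

#' @rdname ROITrace
#' @export
setMethod("traceIntensities", "ROITrace", function(object) object@intensities)

#' @describeIn ROITrace tissue label.
#' @export
setGeneric("traceLabel", function(object) standardGeneric("traceLabel"))

#' @rdname ROITrace
#' @export
setMethod("traceLabel", "ROITrace", function(object) object@label)

setMethod("show", "ROITrace", function(object) {
  cat(sprintf(
    "ROITrace %s (%s, patient %s): %d samples at %g fps, range [%.1f, %.1f] g.u.\n",
    object@roiId, object@label, object@patientId, length(object@times),
    object@fps, min(object@intensities), max(object@intensities)))
})

#' Thin-plate-spline warp model
#'
#' A 2-D thin-plate-spline mapping fitted to landmark correspondences:
#' an affine part plus radial kernel terms \eqn{U(r) = r^2 \log r} at the
#' control points. With regularization \code{lambda = 0} the warp
#' interpolates the correspondences exactly; purely affine correspondence
#' sets yield (numerically) zero kernel weights.
#'
#' @slot affine 3 x 2 coefficient matrix (intercept, row, col) for each
#'   output coordinate.
#' @slot weights n x 2 kernel weights.
#' @slot controlPoints n x 2 source landmark positions (row, col).
#' @slot lambda regularization (>= 0).
#' @seealso [fitTPS()], [warpPoints()]
#' @export
setClass("WarpModel", representation(
  affine = "matrix", weights = "matrix", controlPoints = "matrix",
  lambda = "numeric"
))

setValidity("WarpModel", function(object) {
  if (!all(dim(object@affine) == c(3L, 2L))) return("affine must be 3 x 2")
  if (nrow(object@weights) != nrow(object@controlPoints))
    return("one weight row per control point required")
  if (object@lambda < 0) return("lambda must be >= 0")
  TRUE
})

setMethod("show", "WarpModel", function(object) {
  cat(sprintf("WarpModel: %d control points, lambda %g, |kernel weights| max %.3g\n",
              nrow(object@controlPoints), object@lambda,
              if (nrow(object@weights)) max(abs(object@weights)) else 0))
})

#' Motion-compensated intensity field
#'
#' Whole-frame NIR intensity volume after video stabilization: every pixel
#' of the reference frame carries a full-length time-fluorescence curve.
#' Pixels that left the field of view in any frame are marked invalid (the
#' grey border of the rendered maps).
#'
#' @slot volume numeric T' x H x W array of g.u. at the post-processing
#'   frame rate.
#' @slot mask logical H x W; TRUE where the pixel was observed in every
#'   frame.
#' @slot times numeric length T', seconds.
#' @slot fps post-processing frame rate (default 7).
#' @slot referenceFrame index of the stabilization reference frame within
#'   the selected frames.
#' @seealso [stabilize()], [pixelMilestones()], [clusterField()]
#' @export
setClass("StabilizedField", representation(
  volume = "array", mask = "matrix", times = "numeric", fps = "numeric",
  referenceFrame = "integer"
))

setValidity("StabilizedField", function(object) {
  d <- dim(object@volume)
  if (length(d) != 3L) return("volume must be T x H x W")
  if (!all(dim(object@mask) == d[2:3])) return("mask must be H x W")
  if (length(object@times) != d[1]) return("times must match volume frames")
  TRUE
})

#' @describeIn StabilizedField validity mask accessor.
#' @param object a \code{StabilizedField}.
#' @export
setGeneric("validityMask", function(object) standardGeneric("validityMask"))

#' @rdname StabilizedField
#' @export
setMethod("validityMask", "StabilizedField", function(object) object@mask)

setMethod("show", "StabilizedField", function(object) {
  d <- dim(object@volume)
  cat(sprintf(
    "StabilizedField: %d frames of %d x %d px at %g fps, %.1f%% valid pixels\n",
    d[1], d[2], d[3], object@fps, 100 * mean(object@mask)))
})

#' Classifier evaluation report
#'
#' Confusion matrix and summary rates for a fitted ROI classifier on a
#' test set: overall accuracy, positive predictive value for the CRLM
#' class, and per-class true-positive / false-negative rates, all in
#' percent rounded to one decimal.
#'
#' @slot confusion integer matrix, rows = true labels, cols = predicted.
#' @slot accuracy overall percent correct.
#' @slot ppv positive predictive value (%) for the CRLM-positive class.
#' @slot tpr,fnr named numeric vectors of per-class rates (%).
#' @seealso [evaluateClassifier()]
#' @export
setClass("ClassifierReport", representation(
  confusion = "matrix", accuracy = "numeric", ppv = "numeric",
  tpr = "numeric", fnr = "numeric"
))

setValidity("ClassifierReport", function(object) {
  cm <- object@confusion
  if (is.null(dimnames(cm))) return("confusion matrix must carry dimnames")
  acc <- 100 * sum(diag(cm[rownames(cm), rownames(cm), drop = FALSE])) / sum(cm)
  if (abs(object@accuracy - round(acc, 1)) > 0.051)
    return("accuracy must equal trace/total of the confusion matrix")
  TRUE
})

setMethod("show", "ClassifierReport", function(object) {
  cat("ClassifierReport\n")
  cat(sprintf("  accuracy: %.1f%%   PPV (crlm): %s\n", object@accuracy,
              if (is.na(object@ppv)) "n/a" else sprintf("%.1f%%", object@ppv)))
  cat("  confusion matrix (rows = true, cols = predicted):\n")
  print(object@confusion)
  rates <- rbind(`TPR %` = object@tpr, `FNR %` = object@fnr)
  print(round(rates, 1))
})

#' Synthetic fluorescence microscopy section
#'
#' A synthetic fresh-frozen liver section imaged for ICG fluorescence,
#' with ground-truth lesion/healthy region masks. Staining (H&E plus
#' cover-slipping) attenuates the emitted signal by a known factor: the
#' stained rendering equals the unstained rendering divided by
#' \code{attenuation} before noise.
#'
#' @slot intensity numeric H x W matrix, arbitrary fluorescence units >= 0.
#' @slot masks list of logical H x W matrices \code{lesion} and
#'   \code{healthy}.
#' @slot stained logical flag.
#' @slot attenuation unitless attenuation factor (default 6.5).
#' @seealso [renderMicroscopySection()], [attenuationRatio()]
#' @export
setClass("SectionImage", representation(
  intensity = "matrix", masks = "list", stained = "logical",
  attenuation = "numeric"
))

setValidity("SectionImage", function(object) {
  msg <- character()
  if (!all(c("lesion", "healthy") %in% names(object@masks)))
    msg <- c(msg, "masks must contain 'lesion' and 'healthy'")
  if (min(object@intensity) < 0)
    msg <- c(msg, "intensities must be >= 0")
  if (object@attenuation <= 0)
    msg <- c(msg, "attenuation must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SectionImage", function(object) {
  cat(sprintf(
    "SectionImage %d x %d px (%s), attenuation %.2f, mean signal %.2f a.u.\n",
    nrow(object@intensity), ncol(object@intensity),
    if (object@stained) "stained" else "unstained",
    object@attenuation, mean(object@intensity)))
})

#' Perfusion milestone features of one trace
#'
#' The twelve milestone features summarizing one time-fluorescence curve,
#' plus the reference peak used for the outflow anchors. Features that are
#' undefined for the trace (e.g. a late peak leaving no room for the 60-s
#' outflow slope) are \code{NA}, never silent zeros.
#'
#' @slot tmax time to peak intensity (s).
#' @slot fmax peak intensity (g.u.).
#' @slot fEnd intensity at the window end (g.u.).
#' @slot upslope inflow slope (g.u./s).
#' @slot tHalf time to half-maximum (s).
#' @slot timeRatio tHalf / tmax (unitless).
#' @slot delta10 intensity change from the reference point to
#'   reference + 10 s (g.u.).
#' @slot slope10,slope20,slope60 outflow slopes over 10/20/60 s from the
#'   reference point (g.u./s).
#' @slot kurtosis,skew sample excess kurtosis and skewness of the
#'   intensity values over the window (unitless).
#' @slot com intensity-weighted centre of mass of the curve (s).
#' @slot tStar reference peak time used for the outflow anchors (s).
#' @slot provenance one of \code{"own_peak"}, \code{"single_crlm_peak"},
#'   \code{"mean_crlm_peaks"}.
#' @seealso [computeFeatures()]
#' @export
setClass("PerfusionFeatures", representation(
  tmax = "numeric", fmax = "numeric", fEnd = "numeric", upslope = "numeric",
  tHalf = "numeric", timeRatio = "numeric", delta10 = "numeric",
  slope10 = "numeric", slope20 = "numeric", slope60 = "numeric",
  kurtosis = "numeric", skew = "numeric", com = "numeric",
  tStar = "numeric", provenance = "character"
))

#' Feature names of the milestone set
#'
#' Column order follows the published milestone table: time to peak, peak
#' intensity, end intensity, upslope, time ratio, intensity change peak to
#' peak+10 s, outflow slopes at 10/20/60 s, kurtosis, skew, centre of mass.
#'
#' @return character vector of the 12 feature names.
#' @export
featureNames <- function() {
  c("tmax", "fmax", "fEnd", "upslope", "timeRatio", "delta10",
    "slope10", "slope20", "slope60", "kurtosis", "skew", "com")
}

#' Coerce perfusion features to a one-row data frame
#'
#' @param x a \linkS4class{PerfusionFeatures}.
#' @param row.names,optional,... ignored, present for generic consistency.
#' @return one-row \code{data.frame} with the 12 feature columns.
#' @export
as.data.frame.PerfusionFeatures <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  vals <- lapply(featureNames(), function(nm) slot(x, nm))
  names(vals) <- featureNames()
  as.data.frame(vals)
}

setMethod("show", "PerfusionFeatures", function(object) {
  df <- as.data.frame.PerfusionFeatures(object)
  cat(sprintf("PerfusionFeatures (reference peak %.2f s, %s)\n",
              object@tStar, object@provenance))
  print(round(unlist(df), 3))
})
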