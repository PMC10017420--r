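## Undefined-feature condition: raised when a milestone cannot be
## computed for a trace; computeFeatures() converts it to NA.
.undefinedFeature <- function(fmt, ...) {
  stop(structure(class = c("icgflow_undefined_feature", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

.smoothK <- function(fps, windowS) {
  if (windowS <= 0) return(1L)
  k <- round(windowS * fps)
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  k
}

#' Smooth a trace with a centered moving average
#'
#' Applies a centered moving average of width \code{windowS} seconds;
#' edge windows shrink symmetrically so the output has the same length.
#' \code{windowS = 0} is the identity.
#'
#' @param trace an \linkS4class{ROITrace}.
#' @param windowS smoothing window in seconds (>= 0, default 1).
#' @return smoothed \linkS4class{ROITrace}.
#' @export
smoothTrace <- function(trace, windowS = 1) {
  if (windowS < 0) .stopf("windowS must be >= 0")
  k <- .smoothK(trace@fps, windowS)
  roiTrace(trace@times, .movingAverage(trace@intensities, k),
           fps = trace@fps, label = trace@label, roiId = trace@roiId,
           patientId = trace@patientId)
}

## Baseline estimate: mean of the first `baselineS` seconds of the raw
## trace (used only for half-time and onset thresholds; peak/end
## intensities are reported unsubtracted).
.traceBaseline <- function(trace, baselineS = 1) {
  idx <- trace@times <= trace@times[1] + baselineS
  mean(trace@intensities[idx])
}

#' Peak milestones of a trace
#'
#' Peak intensity (maximum of the smoothed trace), time to peak (earliest
#' time attaining the maximum), and end intensity (final sample of the
#' smoothed trace).
#'
#' @param trace an \linkS4class{ROITrace}.
#' @param smoothWindow smoothing window in seconds before the argmax.
#' @return list with elements \code{tmax}, \code{fmax}, \code{fEnd}.
#' @export
peakMilestones <- function(trace, smoothWindow = 1) {
  if (!length(trace@times)) .stopf("empty trace")
  s <- smoothTrace(trace, smoothWindow)@intensities
  i <- which.max(s)  # earliest index attaining the max
  list(tmax = trace@times[i], fmax = s[i], fEnd = s[length(s)])
}

#' Half-rise time and time ratio
#'
#' Time at which the baseline-subtracted smoothed intensity first reaches
#' half of the peak amplitude, and its ratio to the time to peak. The
#' baseline is the mean of the first second of the raw trace.
#'
#' @param trace an \linkS4class{ROITrace}.
#' @param tmax,fmax peak milestones; computed via [peakMilestones()] when
#'   omitted.
#' @param smoothWindow smoothing window (s).
#' @param baselineS baseline window (s).
#' @return list with elements \code{tHalf} and \code{timeRatio}.
#' @export
halfTimeAndRatio <- function(trace, tmax = NULL, fmax = NULL,
                             smoothWindow = 1, baselineS = 1) {
  if (is.null(tmax) || is.null(fmax)) {
    pk <- peakMilestones(trace, smoothWindow)
    tmax <- pk$tmax; fmax <- pk$fmax
  }
  b <- .traceBaseline(trace, baselineS)
  amp <- fmax - b
  if (amp <= .Machine$double.eps^0.5 * max(1, fmax))
    .undefinedFeature("flat trace: no dynamic range above baseline")
  s <- smoothTrace(trace, smoothWindow)@intensities
  idx <- which(s - b >= amp / 2)
  if (!length(idx)) .undefinedFeature("half-maximum never reached")
  tHalf <- trace@times[idx[1]]
  list(tHalf = tHalf, timeRatio = tHalf / max(tmax, .Machine$double.eps))
}

#' Inflow upslope
#'
#' Mean inflow slope from curve onset to peak:
#' \eqn{(F_{max} - F(t_{onset})) / (t_{max} - t_{onset})}, where onset is
#' the first time the baseline-subtracted smoothed intensity exceeds 10\%
#' of the dynamic range (a documented convention; the onset threshold is
#' configurable).
#'
#' @param trace an \linkS4class{ROITrace}.
#' @param tmax,fmax peak milestones; computed when omitted.
#' @param onsetFraction onset threshold as a fraction of dynamic range.
#' @param smoothWindow,baselineS smoothing and baseline conventions.
#' @return inflow slope in g.u./s.
#' @export
traceUpslope <- function(trace, tmax = NULL, fmax = NULL,
                         onsetFraction = 0.1, smoothWindow = 1,
                         baselineS = 1) {
  if (is.null(tmax) || is.null(fmax)) {
    pk <- peakMilestones(trace, smoothWindow)
    tmax <- pk$tmax; fmax <- pk$fmax
  }
  b <- .traceBaseline(trace, baselineS)
  amp <- fmax - b
  if (amp <= .Machine$double.eps^0.5 * max(1, fmax))
    .undefinedFeature("flat trace: upslope undefined")
  s <- smoothTrace(trace, smoothWindow)@intensities
  idx <- which(s - b > onsetFraction * amp)
  if (!length(idx)) .undefinedFeature("onset never reached")
  tOn <- trace@times[idx[1]]
  if (tmax <= tOn)
    .undefinedFeature("peak coincides with onset: upslope undefined")
  (fmax - s[idx[1]]) / (tmax - tOn)
}

#' Reference peak for healthy-curve outflow anchoring
#'
#' Healthy liver lacks an early bolus peak, so its outflow slopes are
#' anchored at the peak time of the malignant lesion imaged in the same
#' video: the single CRLM peak time, or the arithmetic mean of the peak
#' times when several CRLM ROIs were tracked.
#'
#' @param crlmTraces list of CRLM \linkS4class{ROITrace} objects, or a
#'   numeric vector of their peak times.
#' @param smoothWindow smoothing window (s) for peak extraction.
#' @return list with elements \code{tStar} (s) and \code{provenance}
#'   (\code{"single_crlm_peak"} or \code{"mean_crlm_peaks"}).
#' @export
referencePeak <- function(crlmTraces, smoothWindow = 1) {
  if (is.numeric(crlmTraces)) {
    tmaxes <- crlmTraces
  } else {
    if (!length(crlmTraces)) .stopf("at least one CRLM trace is required")
    tmaxes <- vapply(crlmTraces, function(tr)
      peakMilestones(tr, smoothWindow)$tmax, numeric(1))
  }
  if (!length(tmaxes)) .stopf("at least one CRLM trace is required")
  list(tStar = mean(tmaxes),
       provenance = if (length(tmaxes) == 1L) "single_crlm_peak"
       else "mean_crlm_peaks")
}

## Linear interpolation of the smoothed trace at time t.
.traceAt <- function(times, values, t) {
  if (t < times[1] || t > times[length(times)]) return(NA_real_)
  approx(times, values, xout = t, rule = 1)$y
}

#' Outflow slope and intensity change after a reference point
#'
#' \code{slopeAfter} returns \eqn{(F(t_{ref}+k) - F(t_{ref}))/k} on the
#' smoothed trace; \code{deltaAfter} returns the raw intensity change
#' \eqn{F(t_{ref}+k) - F(t_{ref})}, so that \code{deltaAfter == k *
#' slopeAfter} holds exactly. CRLM traces anchor at their own peak;
#' healthy traces anchor at the mapped reference peak (see
#' [referencePeak()]).
#'
#' @param trace an \linkS4class{ROITrace}.
#' @param tRef reference time (s).
#' @param k horizon in seconds (10, 20 or 60 in the milestone set).
#' @param smoothWindow smoothing window (s).
#' @return slope in g.u./s (or change in g.u.).
#' @export
slopeAfter <- function(trace, tRef, k, smoothWindow = 1) {
  deltaAfter(trace, tRef, k, smoothWindow) / k
}

#' @rdname slopeAfter
#' @export
deltaAfter <- function(trace, tRef, k, smoothWindow = 1) {
  s <- smoothTrace(trace, smoothWindow)@intensities
  tEnd <- trace@times[length(trace@times)]
  if (tRef + k > tEnd + 1e-9)
    .undefinedFeature("reference + %g s falls outside the analysis window", k)
  f0 <- .traceAt(trace@times, s, tRef)
  f1 <- .traceAt(trace@times, s, tRef + k)
  if (is.na(f0) || is.na(f1))
    .undefinedFeature("reference point outside the analysis window")
  f1 - f0
}

#' Centre of mass of a trace
#'
#' Intensity-weighted mean sample time,
#' \eqn{\sum_i t_i F_i / \sum_i F_i}, computed on the raw (unsmoothed)
#' window samples. A later centre of mass indicates delayed or retained
#' dye.
#'
#' @param trace an \linkS4class{ROITrace}.
#' @return centre of mass in seconds.
#' @export
centreOfMass <- function(trace) {
  tot <- sum(trace@intensities)
  if (tot <= 0) .undefinedFeature("all-zero trace: centre of mass undefined")
  sum(trace@times * trace@intensities) / tot
}

#' Distributional shape moments of a trace
#'
#' Fisher-Pearson sample skewness (g1) and sample excess kurtosis (g2) of
#' the intensity values observed over the window (the values are treated
#' as a sample, not as a density over time).
#'
#' @param trace an \linkS4class{ROITrace}.
#' @return list with elements \code{skew} and \code{kurtosis}.
#' @export
shapeMoments <- function(trace) {
  x <- trace@intensities
  if (length(x) < 4L)
    .undefinedFeature("at least 4 samples required for shape moments")
  if (var(x) <= .Machine$double.eps)
    .undefinedFeature("zero variance: shape moments undefined")
  list(skew = e1071::skewness(x, type = 1),
       kurtosis = e1071::kurtosis(x, type = 1))
}

#' Compute the full milestone feature set of one trace
#'
#' Assembles the twelve milestone features. The outflow anchors
#' (\code{delta10}, \code{slope10/20/60}) use the trace's own peak for
#' CRLM (and benign/unknown) labels and the mapped reference peak
#' \code{tStar} for healthy labels. Undefined milestones (e.g.
#' \code{slope60} when the anchor lies within 60 s of the window end)
#' propagate as \code{NA}, never as silent zeros.
#'
#' @param trace an \linkS4class{ROITrace}.
#' @param tStar optional reference peak time (s) from [referencePeak()];
#'   required in spirit for healthy traces (falls back to the trace's own
#'   peak with a warning when absent).
#' @param smoothWindow,baselineS,onsetFraction extraction conventions.
#' @return a \linkS4class{PerfusionFeatures}.
#' @examples
#' tt <- (0:2699) / 30
#' p <- kineticParams(0, 8, 16, 124, 0.07)
#' tr <- roiTrace(tt, gammaVariate(tt, p), fps = 30, label = "crlm")
#' computeFeatures(tr)
#' @export
computeFeatures <- function(trace, tStar = NULL, smoothWindow = 1,
                            baselineS = 1, onsetFraction = 0.1) {
  maybe <- function(expr) {
    tryCatch(expr, icgflow_undefined_feature = function(e) NA_real_)
  }
  ## all milestones are relative to the window start: re-zero the clock
  if (trace@times[1] != 0)
    trace <- roiTrace(trace@times - trace@times[1], trace@intensities,
                      fps = trace@fps, label = trace@label,
                      roiId = trace@roiId, patientId = trace@patientId)
  pk <- peakMilestones(trace, smoothWindow)
  if (identical(trace@label, "healthy")) {
    if (is.null(tStar)) {
      warning("healthy trace without a mapped reference peak; using own peak")
      tRef <- pk$tmax; prov <- "own_peak"
    } else {
      tRef <- tStar
      prov <- "mean_crlm_peaks"
    }
  } else {
    tRef <- pk$tmax; prov <- "own_peak"
  }
  hr <- maybe(halfTimeAndRatio(trace, pk$tmax, pk$fmax, smoothWindow, baselineS))
  if (is.numeric(hr) && is.na(hr)) hr <- list(tHalf = NA_real_, timeRatio = NA_real_)
  up <- maybe(traceUpslope(trace, pk$tmax, pk$fmax, onsetFraction,
                           smoothWindow, baselineS))
  d10 <- maybe(deltaAfter(trace, tRef, 10, smoothWindow))
  s20 <- maybe(slopeAfter(trace, tRef, 20, smoothWindow))
  s60 <- maybe(slopeAfter(trace, tRef, 60, smoothWindow))
  mom <- maybe(shapeMoments(trace))
  if (is.numeric(mom) && is.na(mom)) mom <- list(skew = NA_real_, kurtosis = NA_real_)
  com <- maybe(centreOfMass(trace))
  new("PerfusionFeatures",
      tmax = pk$tmax, fmax = pk$fmax, fEnd = pk$fEnd,
      upslope = up, tHalf = hr$tHalf, timeRatio = hr$timeRatio,
      delta10 = d10, slope10 = if (is.na(d10)) NA_real_ else d10 / 10,
      slope20 = s20, slope60 = s60,
      kurtosis = mom$kurtosis, skew = mom$skew, com = com,
      tStar = tRef, provenance = prov)
}

#' Build a feature table from a set of traces
#'
#' Computes [computeFeatures()] for every trace, mapping the healthy-curve
#' reference peak per patient: each healthy trace is anchored at the mean
#' peak time of the CRLM traces of the same patient (the single peak when
#' only one lesion ROI was tracked). Patients without a CRLM trace fall
#' back to the trace's own peak.
#'
#' @param traces list of \linkS4class{ROITrace} objects.
#' @param smoothWindow smoothing window (s).
#' @return data.frame with columns \code{roiId}, \code{patientId},
#'   \code{label} and the twelve feature columns of [featureNames()];
#'   missing features are \code{NA}.
#' @export
computeFeatureTable <- function(traces, smoothWindow = 1) {
  pats <- vapply(traces, function(tr) tr@patientId, character(1))
  labs <- vapply(traces, function(tr) tr@label, character(1))
  tStarByPatient <- new.env(parent = emptyenv())
  for (p in unique(pats)) {
    crlm <- traces[pats == p & labs == "crlm"]
    if (length(crlm))
      assign(p, referencePeak(crlm, smoothWindow)$tStar, tStarByPatient)
  }
  rows <- lapply(traces, function(tr) {
    ts <- if (tr@label == "healthy" &&
              !is.null(tStarByPatient[[tr@patientId]]))
      tStarByPatient[[tr@patientId]] else NULL
    fe <- suppressWarnings(
      computeFeatures(tr, tStar = ts, smoothWindow = smoothWindow))
    cbind(data.frame(roiId = tr@roiId, patientId = tr@patientId,
                     label = tr@label, stringsAsFactors = FALSE),
          as.data.frame.PerfusionFeatures(fe))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyDuplicated(out$roiId)) .stopf("duplicated roiId in feature table")
  out
}
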