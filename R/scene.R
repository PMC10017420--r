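#' Synthetic angiogram scene configuration
#'
#' Parameters of the synthetic dual-channel ICG angiogram generator. The
#' defaults emulate the acquisition conditions of the motivating cohort:
#' 30 fps recordings of at least 90 s after a 0.05 mg/kg intravenous ICG
#' bolus, rendered to 8-bit with clipping at 255 (the saturation concern
#' that motivated the low dose), with camera motion modelled as a global
#' affine random walk plus a single-frequency respiration deformation.
#'
#' @slot width,height frame size in pixels.
#' @slot fps frame rate (nominally 30).
#' @slot duration recording length in seconds (>= 90).
#' @slot kinetics named list of \linkS4class{KineticParams} for classes
#'   \code{healthy}, \code{lesion}, \code{rim}, \code{cyst}.
#' @slot pixelJitter named numeric: per-pixel multiplicative log-normal
#'   jitter CVs for \code{amplitude}, \code{time}, \code{shape}.
#' @slot motion named list: \code{stepSD} (px/frame translation random
#'   walk), \code{rotStepSD} (rad/frame), \code{respAmplitude} (px),
#'   \code{respPeriod} (s).
#' @slot noiseSD additive sensor noise SD in g.u.
#' @slot overlayMode render the NIR channel as a green overlay.
#' @slot lesionClass \code{"lesion"} (CRLM scene) or \code{"cyst"}.
#' @slot lesionRadiusFrac lesion radius as a fraction of frame height.
#' @slot rimWidth rim annulus width in pixels (0 disables the rim).
#' @slot borderPx width of the non-perfused background border.
#' @slot dose informational ICG dose (mg/kg).
#' @export
setClass("SceneConfig", representation(
  width = "numeric", height = "numeric", fps = "numeric",
  duration = "numeric", kinetics = "list", pixelJitter = "numeric",
  motion = "list", noiseSD = "numeric", overlayMode = "logical",
  lesionClass = "character", lesionRadiusFrac = "numeric",
  rimWidth = "numeric", borderPx = "numeric", dose = "numeric"
))

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@fps * object@duration < 2698)
    msg <- c(msg, "fps * duration must cover at least 2698 frames")
  if (object@duration < 90)
    msg <- c(msg, "duration must be at least 90 s")
  if (object@width < 16 || object@height < 16)
    msg <- c(msg, "frame must be at least 16 x 16 px")
  if (!all(c("healthy", "lesion", "rim", "cyst") %in% names(object@kinetics)))
    msg <- c(msg, "kinetics must name healthy, lesion, rim and cyst")
  if (!object@lesionClass %in% c("lesion", "cyst"))
    msg <- c(msg, "lesionClass must be 'lesion' or 'cyst'")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a scene configuration
#'
#' @param width,height,fps,duration,kinetics,pixelJitter,motion,noiseSD,
#'   overlayMode,lesionClass,lesionRadiusFrac,rimWidth,borderPx,dose see
#'   \linkS4class{SceneConfig}.
#' @return a \linkS4class{SceneConfig}.
#' @export
sceneConfig <- function(width = 64, height = 48, fps = 30, duration = 90,
                        kinetics = kineticDefaults(fps = fps,
                                                   windowS = duration),
                        pixelJitter = c(amplitude = 0.05, time = 0.03,
                                        shape = 0),
                        motion = list(stepSD = 0, rotStepSD = 0,
                                      respAmplitude = 0, respPeriod = 4),
                        noiseSD = 2, overlayMode = FALSE,
                        lesionClass = "lesion", lesionRadiusFrac = 0.28,
                        rimWidth = 0, borderPx = 3, dose = 0.05) {
  ## basic geometry checks before the (lazy) kinetics default is forced,
  ## since calibration itself needs a plausible window
  if (duration < 90) .stopf("duration must be at least 90 s")
  if (fps * duration < 2698) .stopf("fps * duration must cover at least 2698 frames")
  if (noiseSD < 0) .stopf("noiseSD must be >= 0")
  mot <- list(stepSD = 0, rotStepSD = 0, respAmplitude = 0, respPeriod = 4)
  mot[names(motion)] <- motion
  new("SceneConfig", width = width, height = height, fps = fps,
      duration = duration, kinetics = kinetics, pixelJitter = pixelJitter,
      motion = mot, noiseSD = noiseSD, overlayMode = overlayMode,
      lesionClass = lesionClass, lesionRadiusFrac = lesionRadiusFrac,
      rimWidth = rimWidth, borderPx = borderPx, dose = dose)
}

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(
    "SceneConfig: %d x %d px, %g fps x %g s, %s scene (rim %g px), noise SD %g g.u.\n",
    object@width, object@height, object@fps, object@duration,
    object@lesionClass, object@rimWidth, object@noiseSD))
})

## Build the tissue class label image for a scene.
.sceneClassMap <- function(config) {
  H <- config@height; W <- config@width
  classes <- c("healthy", "lesion", "rim", "cyst", "background")
  lab <- matrix(1L, H, W)
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  ctrR <- H / 2 + 0.5; ctrC <- W / 2 + 0.5
  rad <- config@lesionRadiusFrac * H
  d <- sqrt((rr - ctrR)^2 + ((cc - ctrC) / 1.2)^2)
  inner <- d <= rad
  lab[inner] <- if (config@lesionClass == "cyst") 4L else 2L
  if (config@rimWidth > 0 && config@lesionClass == "lesion")
    lab[!inner & d <= rad + config@rimWidth] <- 3L
  b <- config@borderPx
  if (b > 0) {
    lab[c(seq_len(b), H - seq_len(b) + 1L), ] <- 5L
    lab[, c(seq_len(b), W - seq_len(b) + 1L)] <- 5L
  }
  new("TissueClassMap", labels = lab, classes = classes)
}

## Static white-light liver texture with trackable landmarks.
.sceneTexture <- function(H, W) {
  base <- matrix(rnorm(H * W), H, W)
  ## smooth twice with a 7-wide separable moving average
  sm <- function(m) {
    m <- apply(m, 2, .movingAverage, k = 7L)
    t(apply(t(m), 2, .movingAverage, k = 7L))
  }
  low <- sm(sm(base))
  low <- (low - min(low)) / diff(range(low))      # 0..1 large-scale shading
  ## mid-scale blobs survive bilinear resampling at fractional shifts,
  ## which washes out single-pixel speckle
  mid <- matrix(rnorm(H * W), H, W)
  mid <- apply(mid, 2, .movingAverage, k = 3L)
  mid <- t(apply(t(mid), 2, .movingAverage, k = 3L))
  speck <- matrix(runif(H * W, -1, 1), H, W)      # fine trackable speckle
  tex <- 90 + 90 * low + 55 * mid + 15 * speck
  pmin(pmax(tex, 0), 255)
}

## Forward motion map: tissue coordinates seen at camera pixel (r, c) in
## frame i. pts is n x 2 (row, col).
.sceneSource <- function(truth, frameIdx, pts) {
  i <- frameIdx
  th <- truth$motion$rot[i]
  tr <- truth$motion$trans[i, ]
  ctr <- truth$motion$center
  dr <- pts[, 1] - ctr[1]; dc <- pts[, 2] - ctr[2]
  r <- ctr[1] + cos(th) * dr - sin(th) * dc + tr[1]
  c <- ctr[2] + sin(th) * dr + cos(th) * dc + tr[2]
  if (truth$motion$respAmplitude > 0) {
    ph <- sin(2 * pi * truth$times[i] / truth$motion$respPeriod)
    w <- .bilinearSample(truth$motion$respWeight, pts[, 1], pts[, 2], fill = 0)
    amp <- truth$motion$respAmplitude * ph * w
    r <- r + amp * truth$motion$respDir[1]
    c <- c + amp * truth$motion$respDir[2]
  }
  cbind(r, c)
}

#' Ground-truth motion queries for a synthetic scene
#'
#' \code{trueSourceCoords} maps camera pixels of one frame to tissue
#' coordinates under the scene's true motion. \code{trueDisplacement}
#' returns, for content under reference-frame pixels, its displacement in
#' a target frame (the quantity a tracker or stabilizer estimates).
#'
#' @param truth the ground-truth record returned by [renderSequence()].
#' @param frameIdx frame index (1-based).
#' @param pts n x 2 matrix of (row, col) pixel positions.
#' @param refFrame reference frame index for \code{trueDisplacement}.
#' @return n x 2 matrix of coordinates (or displacements).
#' @export
trueSourceCoords <- function(truth, frameIdx, pts) {
  .sceneSource(truth, frameIdx, pts)
}

#' @rdname trueSourceCoords
#' @export
trueDisplacement <- function(truth, frameIdx, pts, refFrame = 1L) {
  target <- .sceneSource(truth, refFrame, pts)  # tissue coords of content
  x <- pts
  for (k in 1:12) {                              # invert the near-identity map
    err <- .sceneSource(truth, frameIdx, x) - target
    x <- x - err
    if (max(abs(err)) < 1e-9) break
  }
  x - pts
}

#' Render a synthetic dual-channel ICG angiogram
#'
#' Generates a synchronized white-light / NIR frame pair with known
#' ground truth. The white-light channel carries a static liver-like
#' texture with trackable speckle; the NIR channel renders per-pixel
#' gamma-variate perfusion curves according to the tissue class map, with
#' per-pixel biological jitter, additive sensor noise, clipping and 8-bit
#' quantization. Both channels share the same motion (affine random walk
#' plus respiration deformation). Output is bit-identical for a fixed
#' seed and configuration.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @param seed integer seed.
#' @return list with elements \code{pair} (a
#'   \linkS4class{FrameSequencePair}) and \code{truth} (ground-truth
#'   record: class map, per-pixel kinetic parameter matrices, motion
#'   trajectory, noise-free curve closure \code{curveAt(times, idx)}).
#' @export
renderSequence <- function(config, seed = 1L) {
  validObject(config)
  .withSeed(.deriveSeed(seed, "icgflow-scene"), {
    H <- config@height; W <- config@width
    n <- round(config@fps * config@duration)
    times <- (seq_len(n) - 1) / config@fps
    cmap <- .sceneClassMap(config)
    lab <- cmap@labels
    npx <- H * W

    ## per-pixel kinetic parameter fields
    getp <- function(slot) vapply(config@kinetics, function(p)
      methods::slot(p, slot), numeric(1))
    clsOf <- c(healthy = "healthy", lesion = "lesion", rim = "rim",
               cyst = "cyst", background = "healthy")
    kcls <- clsOf[cmap@classes[lab]]
    b <- getp("baseline")[kcls]
    d0 <- getp("arrivalDelay")[kcls]
    tp0 <- getp("timeToPeak")[kcls]
    A0 <- getp("amplitude")[kcls]
    a0 <- getp("shape")[kcls]
    A0[lab == 5L] <- 0                       # background does not perfuse
    jA <- .rlnormMean1(npx, config@pixelJitter["amplitude"])
    jT <- .rlnormMean1(npx, config@pixelJitter["time"])
    jS <- .rlnormMean1(npx, config@pixelJitter["shape"])
    A <- A0 * jA; d <- d0 * jT; tp <- tp0 * jT; a <- a0 * jS

    ## motion trajectory
    mot <- config@motion
    trans <- apply(matrix(rnorm(2 * n, sd = mot$stepSD), n, 2), 2, cumsum)
    if (n == 1L) trans <- matrix(trans, 1, 2)
    rot <- cumsum(rnorm(n, sd = mot$rotStepSD))
    rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    respWeight <- sin(pi * rr / (H + 1)) * sin(pi * cc / (W + 1))
    truth <- list(
      classMap = cmap, times = times, fps = config@fps,
      pixelParams = list(baseline = matrix(b, H, W), delay = matrix(d, H, W),
                         timeToPeak = matrix(tp, H, W),
                         amplitude = matrix(A, H, W), shape = matrix(a, H, W)),
      motion = list(trans = trans, rot = rot, center = c((H + 1) / 2, (W + 1) / 2),
                    respAmplitude = mot$respAmplitude,
                    respPeriod = mot$respPeriod,
                    respDir = c(0.96, 0.28), respWeight = respWeight),
      noiseSD = config@noiseSD, seed = seed)
    truth$curveAt <- function(tt, idx = seq_len(npx)) {
      vapply(tt, function(one)
        .gammaVariateVec(rep(one, length(idx)), b[idx], d[idx], tp[idx],
                         A[idx], a[idx]), numeric(length(idx)))
    }

    ## white-light texture (static, in tissue coordinates)
    tex <- .sceneTexture(H, W)
    texRGB <- list(tex, tex * 0.55, tex * 0.45)

    moving <- mot$stepSD > 0 || mot$rotStepSD > 0 || mot$respAmplitude > 0
    grid <- cbind(as.vector(rr), as.vector(cc))
    nir <- array(0, c(n, H, W))
    wl <- array(0, c(n, H, W, 3))
    for (i in seq_len(n)) {
      tiss <- .gammaVariateVec(rep(times[i], npx), b, d, tp, A, a)
      if (moving) {
        src <- .sceneSource(truth, i, grid)
        tissImg <- matrix(tiss, H, W)
        nv <- .bilinearSample(tissImg, src[, 1], src[, 2], fill = 0)
        wv <- lapply(texRGB, function(ch)
          .bilinearSample(ch, src[, 1], src[, 2], fill = 0))
      } else {
        nv <- tiss
        wv <- lapply(texRGB, as.vector)
      }
      if (config@noiseSD > 0) {
        nv <- nv + rnorm(npx, sd = config@noiseSD)
        wv <- lapply(wv, function(v) v + rnorm(npx, sd = config@noiseSD))
      }
      nir[i, , ] <- .quantize8(nv)
      for (ch in 1:3) wl[i, , , ch] <- .quantize8(wv[[ch]])
    }
    if (config@overlayMode) {
      ## green-overlay rendering: NIR encoded in the green channel
      wl[, , , 1] <- .quantize8(wl[, , , 1] * 0.3)
      wl[, , , 2] <- nir
      wl[, , , 3] <- .quantize8(wl[, , , 3] * 0.3)
    }
    pair <- frameSequencePair(wl, nir, fps = config@fps,
                              timestamps = times,
                              overlayMode = config@overlayMode)
    list(pair = pair, truth = truth)
  })
}

## Per-ROI biological variability: multiplicative log-normal jitter CVs
## per tissue class, tuned so extracted milestone spreads approximate the
## reference cohort SDs (time jitter scales delay and time-to-peak
## together, preserving the time-ratio; amplitude jitter scales the bolus
## height).
#' @rdname simulateTraces
#' @export
classVariability <- function() {
  ref <- referenceMilestones()
  g <- function(gr, f) {
    ref[[paste0(gr, "SD")]][ref$feature == f] /
      ref[[paste0(gr, "Mean")]][ref$feature == f]
  }
  list(
    crlm = c(amplitude = g("crlm", "fmax"), time = g("crlm", "tmax"),
             shape = 0.15),
    healthy = c(amplitude = g("healthy", "fmax"), time = g("healthy", "tmax"),
                shape = 0.15),
    benign_cyst = c(amplitude = 0.15, time = g("healthy", "tmax"),
                    shape = 0.15)
  )
}

## Window-cap correction for the time-scale jitter: the extracted time
## to peak of a curve whose true peak falls beyond the analysis window
## is capped at the window end, so the mean of min(a * J, m) over the
## mean-one log-normal jitter J is below a. Solve for the pre-cap scale
## a such that E[min(a * J, m)] equals the nominal class peak time
## (closed form for the censored log-normal mean).
.capAdjustedTimeScale <- function(T0, cv, wEnd) {
  if (cv <= 0) return(1)
  s2 <- log(1 + cv^2); sdl <- sqrt(s2); mu <- -s2 / 2
  capMean <- function(a) {
    k <- wEnd / a
    z <- (log(k) - mu) / sdl
    a * stats::pnorm(z - sdl) + wEnd * (1 - stats::pnorm(z))
  }
  if (capMean(T0) >= T0 - 1e-9) return(1)
  up <- T0
  while (capMean(up) < T0 && up < 20 * T0) up <- up * 1.5
  a <- uniroot(function(x) capMean(x) - T0, c(T0, up), tol = 1e-8)$root
  a / T0
}

## Saturation-aware amplitude jitter: peaks are kept below the 8-bit
## ceiling (the low-dose protocol is designed to avoid saturation), so
## the jitter is a log-normal truncated at `cap`, rescaled in closed
## form so its truncated mean is one.
.truncAdjustedAmpScale <- function(cv, cap) {
  if (cv <= 0 || !is.finite(cap)) return(1)
  s2 <- log(1 + cv^2); sdl <- sqrt(s2); mu <- -s2 / 2
  truncMean <- function(a) {
    z <- (log(cap / a) - mu) / sdl
    a * stats::pnorm(z - sdl) / stats::pnorm(z)
  }
  if (cap <= 1 || truncMean(cap) <= 1) {
    warning("amplitude target unreachable below the saturation ceiling")
    return(min(cap, 1))
  }
  uniroot(function(a) truncMean(a) - 1, c(0.5, cap), tol = 1e-9)$root
}

#' Simulate ROI time-fluorescence traces
#'
#' Draws per-ROI realizations of a tissue class's calibrated kinetics:
#' multiplicative log-normal jitter (mean one) on the amplitude, the time
#' scale (arrival delay and time-to-peak jointly) and the washout shape,
#' plus additive measurement noise on the ROI-mean trace. Because an
#' extracted time-to-peak is capped at the window end for realizations
#' peaking beyond the window, the time-scale jitter is rescaled in closed
#' form so the mean \emph{extracted} peak time matches the nominal class
#' value (this matters for the late-peaking healthy class). This is the
#' generative model behind the synthetic classifier cohorts.
#'
#' @param label tissue label: \code{"crlm"}, \code{"healthy"} or
#'   \code{"benign_cyst"}.
#' @param n number of traces.
#' @param seed integer seed.
#' @param fps,windowS sampling rate and window length; the default window
#'   holds 2700 samples at 30 fps.
#' @param kinetics named list of class kinetics (see [kineticDefaults()]).
#' @param variability per-class jitter CVs (see \code{classVariability}).
#' @param noiseSD additive noise SD on the ROI-mean trace (g.u.). The
#'   default 0.2 is the residual noise of averaging a >= 100-pixel ROI
#'   with ~2 g.u. per-pixel sensor noise.
#' @param patientId,roiPrefix provenance strings.
#' @return list of \linkS4class{ROITrace}.
#' @export
simulateTraces <- function(label = c("crlm", "healthy", "benign_cyst"),
                           n = 1L, seed = 1L, fps = 30, windowS = 90,
                           kinetics = kineticDefaults(fps = fps,
                                                      windowS = windowS),
                           variability = classVariability(),
                           noiseSD = 0.2, patientId = "p1",
                           roiPrefix = NULL) {
  label <- match.arg(label)
  kin <- switch(label, crlm = kinetics$lesion, healthy = kinetics$healthy,
                benign_cyst = kinetics$cyst)
  cv <- variability[[label]]
  if (is.null(roiPrefix)) roiPrefix <- paste0(label, "_")
  nS <- round(windowS * fps)
  times <- (seq_len(nS) - 1) / fps
  tScale <- .capAdjustedTimeScale(kin@arrivalDelay + kin@timeToPeak,
                                  unname(cv["time"]), times[nS])
  ampCap <- (250 - kin@baseline) / max(kin@amplitude, 1e-9)
  aScale <- .truncAdjustedAmpScale(unname(cv["amplitude"]), ampCap)
  .withSeed(.deriveSeed(seed, paste0("icgflow-traces-", label)), {
    jA <- aScale * .rlnormMean1(n, cv["amplitude"])
    for (r in 1:50) {        # truncated draw: redraw saturating peaks
      bad <- jA > ampCap
      if (!any(bad)) break
      jA[bad] <- aScale * .rlnormMean1(sum(bad), cv["amplitude"])
    }
    jA[jA > ampCap] <- ampCap
    jT <- tScale * .rlnormMean1(n, cv["time"])
    jS <- .rlnormMean1(n, cv["shape"])
    lapply(seq_len(n), function(i) {
      v <- .gammaVariateVec(times, kin@baseline, kin@arrivalDelay * jT[i],
                            kin@timeToPeak * jT[i], kin@amplitude * jA[i],
                            kin@shape * jS[i])
      if (noiseSD > 0) v <- v + rnorm(nS, sd = noiseSD)
      roiTrace(times, pmin(pmax(v, 0), 255), fps = fps, label = label,
               roiId = sprintf("%s%03d", roiPrefix, i),
               patientId = patientId)
    })
  })
}

#' Simulate a multi-patient ROI cohort
#'
#' Builds a synthetic cohort mirroring the clinical study design: CRLM
#' patients each contribute several lesion ROIs and one healthy-liver
#' reference ROI; one additional patient contributes the benign-cyst
#' ROIs. The healthy traces of each patient are later anchored at that
#' patient's mean CRLM peak time by [computeFeatureTable()].
#'
#' @param nCrlm,nHealthy,nCyst ROI counts (defaults 132 / 24 / 6, the
#'   cohort sizes of the motivating study).
#' @param seed integer seed.
#' @param ... passed to [simulateTraces()].
#' @return list of \linkS4class{ROITrace}.
#' @export
simulateCohort <- function(nCrlm = 132, nHealthy = 24, nCyst = 6,
                           seed = 1L, ...) {
  nPat <- nHealthy
  per <- rep(nCrlm %/% nPat, nPat)
  extra <- nCrlm - sum(per)
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  traces <- list()
  for (p in seq_len(nPat)) {
    pid <- sprintf("p%02d", p)
    if (per[p] > 0)
      traces <- c(traces, simulateTraces(
        "crlm", n = per[p], seed = .deriveSeed(seed, paste0("crlm", pid)),
        patientId = pid, roiPrefix = paste0(pid, "_crlm_"), ...))
    traces <- c(traces, simulateTraces(
      "healthy", n = 1L, seed = .deriveSeed(seed, paste0("heal", pid)),
      patientId = pid, roiPrefix = paste0(pid, "_healthy_"), ...))
  }
  if (nCyst > 0) {
    pid <- sprintf("p%02d", nPat + 1L)
    traces <- c(traces, simulateTraces(
      "benign_cyst", n = nCyst, seed = .deriveSeed(seed, paste0("cyst", pid)),
      patientId = pid, roiPrefix = paste0(pid, "_cyst_"), ...))
  }
  traces
}

#' Render a synthetic fluorescence microscopy section
#'
#' Synthetic fresh-frozen liver section containing a lesion within
#' healthy parenchyma. Healthy tissue emits strongly (ICG-concentrating
#' parenchyma) while the lesion emits near-nothing; H&E staining with
#' cover-slipping attenuates the whole emission field by
#' \code{attenuation} before (multiplicative, mean-one) acquisition
#' noise. The noise field depends on the seed but not on the stained
#' flag, so a stained/unstained pair rendered with one seed differs
#' exactly by the attenuation factor before noise.
#'
#' @param stained logical; render the stained preparation.
#' @param seed integer seed.
#' @param width,height section size in pixels.
#' @param healthyMean,lesionMean mean emission per region (arbitrary
#'   units); defaults follow the reported cohort signal/area scale.
#' @param attenuation staining attenuation factor (default 6.5).
#' @param noiseCV coefficient of variation of the multiplicative noise.
#' @param lesionRadiusFrac lesion radius as a fraction of section height.
#' @return a \linkS4class{SectionImage}.
#' @export
renderMicroscopySection <- function(stained = FALSE, seed = 1L,
                                    width = 160, height = 120,
                                    healthyMean = 507.43,
                                    lesionMean = 2.46,
                                    attenuation = 6.5, noiseCV = 0.3,
                                    lesionRadiusFrac = 0.3) {
  if (attenuation <= 0) .stopf("attenuation must be > 0")
  H <- height; W <- width
  rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  dd <- sqrt((rr - H / 2)^2 + ((cc - W / 2) / 1.3)^2)
  lesion <- dd <= lesionRadiusFrac * H
  if (!any(lesion) || all(lesion)) .stopf("lesion mask must be a proper subset")
  emission <- matrix(healthyMean, H, W)
  emission[lesion] <- lesionMean
  if (stained) emission <- emission / attenuation
  noise <- .withSeed(.deriveSeed(seed, "icgflow-section"),
                     matrix(.rlnormMean1(H * W, noiseCV), H, W))
  new("SectionImage", intensity = emission * noise,
      masks = list(lesion = lesion, healthy = !lesion),
      stained = stained, attenuation = attenuation)
}
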