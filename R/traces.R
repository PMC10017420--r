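#' Convert a green-overlay NIR frame to greyscale
#'
#' Overlay-style systems (Firefly) present the ICG signal as a green
#' overlay on the white-light image rather than as a separate NIR
#' channel. The fluorescence intensity is therefore recovered as the
#' green channel (luminance would mix white-light anatomy into the
#' signal).
#'
#' @param frame H x W x 3 array (one frame) or T x H x W x 3 stack of
#'   8-bit values.
#' @return H x W matrix (or T x H x W array) of 8-bit greyscale units.
#' @examples
#' overlayToGrayscale(array(c(0, 255, 0), c(1, 1, 3)))  # 255
#' @export
overlayToGrayscale <- function(frame) {
  d <- dim(frame)
  if (length(d) == 3L && d[3] == 3L) return(frame[, , 2])
  if (length(d) == 4L && d[4] == 3L) return(frame[, , , 2])
  .stopf("frame must be a 3-channel image or image stack")
}

#' Build a frame-sequence pair from an overlay-only video
#'
#' For systems that emit only the green-overlay composite (no separate
#' white-light source), the NIR channel is recovered with
#' [overlayToGrayscale()] and the pair is marked \code{overlayMode} so
#' downstream tracking is skipped (fixed ROIs).
#'
#' @param stack T x H x W x 3 array of 8-bit overlay frames.
#' @param fps frame rate.
#' @param timestamps optional frame times.
#' @return a \linkS4class{FrameSequencePair} with \code{overlayMode = TRUE}.
#' @export
overlayPair <- function(stack, fps = 30, timestamps = NULL) {
  frameSequencePair(stack, overlayToGrayscale(stack), fps = fps,
                    timestamps = timestamps, overlayMode = TRUE)
}

## Luminance of one white-light frame (used for tracking).
.luminance <- function(rgb) {
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

## Rasterize a polygon (n x 2, row/col vertices) to a pixel mask of pixel
## centers inside the polygon.
.polygonMask <- function(polygon, H, W) {
  rlim <- range(polygon[, 1]); clim <- range(polygon[, 2])
  rows <- max(1L, floor(rlim[1])):min(H, ceiling(rlim[2]))
  cols <- max(1L, floor(clim[1])):min(W, ceiling(clim[2]))
  if (!length(rows) || !length(cols)) return(matrix(FALSE, H, W))
  pts <- cbind(rep(cols, each = length(rows)), rep(rows, length(cols)))
  bnd <- rbind(polygon[, c(2, 1)], polygon[1, c(2, 1)])
  inside <- mgcv::in.out(bnd, pts)
  m <- matrix(FALSE, H, W)
  m[cbind(pts[inside, 2], pts[inside, 1])] <- TRUE
  m
}

## Normalized cross-correlation of a template against a search
## neighborhood. Returns the best integer offset and its score.
## region geometry is precomputed by the caller.
.nccBest <- function(img, template, center, radius) {
  th <- nrow(template); tw <- ncol(template)
  hh <- (th - 1L) %/% 2L; hw <- (tw - 1L) %/% 2L
  H <- nrow(img); W <- ncol(img)
  ## clamp the search center so the full search region fits the frame
  cr <- min(max(center[1], 1 + hh + radius), H - hh - radius)
  cc <- min(max(center[2], 1 + hw + radius), W - hw - radius)
  if (cr < 1 + hh + radius || cc < 1 + hw + radius)
    return(list(dr = 0, dc = 0, score = -Inf))
  region <- img[(cr - hh - radius):(cr + hh + radius),
                (cc - hw - radius):(cc + hw + radius)]
  side <- 2L * radius + 1L
  tv <- as.vector(template); tv <- tv - mean(tv)
  tn <- sqrt(sum(tv^2))
  if (tn < 1e-9) return(list(dr = 0, dc = 0, score = -Inf))
  ## index matrix: one column per candidate offset
  rh <- nrow(region)
  baseIdx <- as.vector(outer(seq_len(th), (seq_len(tw) - 1L) * rh, `+`))
  offIdx <- as.vector(outer(seq_len(side) - 1L, (seq_len(side) - 1L) * rh, `+`))
  P <- matrix(region[outer(baseIdx, offIdx, `+`)], nrow = th * tw)
  Pm <- colMeans(P)
  Pc <- sweep(P, 2, Pm)
  num <- as.vector(crossprod(tv, Pc))
  den <- tn * sqrt(colSums(Pc^2))
  sc <- ifelse(den < 1e-9, -Inf, num / den)
  k <- which.max(sc)
  dro <- (k - 1L) %% side - radius
  dco <- (k - 1L) %/% side - radius
  list(dr = dro + (cr - center[1]), dc = dco + (cc - center[2]),
       score = sc[k],
       subR = .parabolic(sc, k, side, "r"), subC = .parabolic(sc, k, side, "c"))
}

## One-dimensional parabolic sub-pixel refinement of an NCC score grid
## around its maximum; returns the fractional correction in [-0.5, 0.5].
.parabolic <- function(sc, k, side, which = "r") {
  r <- (k - 1L) %% side; c <- (k - 1L) %/% side
  get <- function(rr, cc) {
    if (rr < 0 || rr >= side || cc < 0 || cc >= side) return(NA_real_)
    sc[rr + cc * side + 1L]
  }
  if (which == "r") { y0 <- get(r - 1L, c); y2 <- get(r + 1L, c) }
  else { y0 <- get(r, c - 1L); y2 <- get(r, c + 1L) }
  y1 <- get(r, c)
  if (y1 >= 1 - 1e-9) return(0)  # perfect integer alignment: peak is here
  if (is.na(y0) || is.na(y2) || !is.finite(y0) || !is.finite(y2)) return(0)
  den <- y0 - 2 * y1 + y2
  if (abs(den) < 1e-12) return(0)
  delta <- 0.5 * (y0 - y2) / den
  max(min(delta, 0.5), -0.5)
}

#' Track an ROI through the white-light channel
#'
#' Normalized cross-correlation template tracking of the region's
#' white-light appearance, with a translation-only motion model: the
#' template is the luminance patch around the ROI on its reference
#' frame, matched in each frame within a search window centered on the
#' previous frame's offset. The template is refreshed (at most every
#' \code{refreshEvery} frames, and only when the match score has dropped
#' below \code{refreshBelow}) to tolerate slow appearance change without
#' accumulating rebasing drift. Frames
#' whose best match score falls below \code{minScore} are flagged
#' invalid and carry the last valid offset. In overlay mode (no
#' independent white-light source) tracking is skipped and the fixed ROI
#' is used for every frame.
#'
#' @param pair a \linkS4class{FrameSequencePair}.
#' @param roi an \linkS4class{ROISpec}.
#' @param cfg list of options: \code{searchRadius} (px, default 6),
#'   \code{margin} (template margin around the ROI bounding box, default
#'   3), \code{refreshEvery} (frames, default 30), \code{minScore}
#'   (default 0.6), \code{refreshBelow} (default 0.8).
#' @return an \linkS4class{ROITrack}.
#' @export
trackROI <- function(pair, roi, cfg = list()) {
  validObject(roi)
  n <- nFrames(pair)
  if (roi@frame < 1L || roi@frame > n)
    .stopf("reference frame %d outside the sequence", roi@frame)
  if (pair@overlayMode)
    return(new("ROITrack", offsets = matrix(0, n, 2),
               valid = rep(TRUE, n), score = rep(1, n)))
  opt <- list(searchRadius = 6L, margin = 3L, refreshEvery = 30L,
              minScore = 0.6, refreshBelow = 0.8)
  opt[names(cfg)] <- cfg
  H <- dim(pair@nir)[2]; W <- dim(pair@nir)[3]
  rlim <- range(roi@polygon[, 1]); clim <- range(roi@polygon[, 2])
  r0 <- max(1L, floor(rlim[1]) - opt$margin)
  r1 <- min(H, ceiling(rlim[2]) + opt$margin)
  c0 <- max(1L, floor(clim[1]) - opt$margin)
  c1 <- min(W, ceiling(clim[2]) + opt$margin)
  ## odd template side so it has a well-defined center pixel
  if ((r1 - r0) %% 2L == 1L) r1 <- r1 - 1L
  if ((c1 - c0) %% 2L == 1L) c1 <- c1 - 1L
  ctr <- c((r0 + r1) %/% 2L, (c0 + c1) %/% 2L)
  lum <- function(i) .luminance(pair@whiteLight[i, , , ])
  template <- lum(roi@frame)[r0:r1, c0:c1]
  offsets <- matrix(NA_real_, n, 2)
  valid <- rep(FALSE, n); score <- rep(NA_real_, n)
  offsets[roi@frame, ] <- 0; valid[roi@frame] <- TRUE; score[roi@frame] <- 1
  trackDir <- function(idx) {
    tpl <- template
    prev <- c(0, 0); lastRefresh <- roi@frame
    for (i in idx) {
      img <- lum(i)
      m <- .nccBest(img, tpl, ctr + round(prev), opt$searchRadius)
      if (is.finite(m$score) && m$score >= opt$minScore) {
        prev <- c(round(prev)[1] + m$dr, round(prev)[2] + m$dc)
        offsets[i, ] <<- prev
        valid[i] <<- TRUE
        ## refresh only when the match against the current template has
        ## degraded: unconditional refresh accumulates sub-pixel rebasing
        ## drift, while refresh-on-demand still tracks slow appearance
        ## change
        if (abs(i - lastRefresh) >= opt$refreshEvery &&
            m$score < opt$refreshBelow) {
          tr0 <- ctr[1] + prev[1] - (nrow(tpl) - 1L) %/% 2L
          tc0 <- ctr[2] + prev[2] - (ncol(tpl) - 1L) %/% 2L
          if (tr0 >= 1 && tc0 >= 1 && tr0 + nrow(tpl) - 1 <= H &&
              tc0 + ncol(tpl) - 1 <= W) {
            tpl <- img[tr0:(tr0 + nrow(tpl) - 1L), tc0:(tc0 + ncol(tpl) - 1L)]
            lastRefresh <- i
          }
        }
      } else {
        offsets[i, ] <<- prev
        valid[i] <<- FALSE
      }
      score[i] <<- if (is.finite(m$score)) m$score else NA_real_
    }
  }
  if (roi@frame < n) trackDir((roi@frame + 1L):n)
  if (roi@frame > 1L) trackDir((roi@frame - 1L):1L)
  if (sum(valid) <= 1L && n > 1L)
    .stopf("tracking failure: no frame matched above score %.2f", opt$minScore)
  new("ROITrack", offsets = offsets, valid = valid,
      score = ifelse(is.na(score), -1, score))
}

#' Extract a time-fluorescence trace for a tracked ROI
#'
#' Per-frame mean NIR intensity over the ROI polygon, displaced by the
#' tracked per-frame offset, truncated (or padded with the last value) to
#' the configured analysis window.
#'
#' @param pair a \linkS4class{FrameSequencePair}.
#' @param track an \linkS4class{ROITrack} covering all frames; omit to
#'   use a fixed (untracked) ROI.
#' @param roi an \linkS4class{ROISpec}.
#' @param windowS analysis window length in seconds (default 90; the
#'   window is half-open, the first sample at time 0).
#' @return an \linkS4class{ROITrace}.
#' @export
extractTrace <- function(pair, track = NULL, roi, windowS = 90) {
  n <- nFrames(pair)
  H <- dim(pair@nir)[2]; W <- dim(pair@nir)[3]
  if (is.null(track))
    track <- new("ROITrack", offsets = matrix(0, n, 2),
                 valid = rep(TRUE, n), score = rep(1, n))
  if (nrow(track@offsets) != n)
    .stopf("track must cover all %d frames", n)
  mask <- .polygonMask(roi@polygon, H, W)
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) .stopf("extraction error: ROI rasterizes to no pixels")
  nOut <- round(windowS * pair@fps)
  nUse <- min(n, nOut)
  vals <- numeric(nUse)
  for (i in seq_len(nUse)) {
    r <- idx[, 1] + track@offsets[i, 1]
    c <- idx[, 2] + track@offsets[i, 2]
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    if (!any(ok)) .stopf("extraction error: ROI empty after clipping at frame %d", i)
    vals[i] <- mean(pair@nir[cbind(i, r[ok], c[ok])])
  }
  if (nUse < nOut) vals <- c(vals, rep(vals[nUse], nOut - nUse))
  times <- (seq_len(nOut) - 1) / pair@fps
  roiTrace(times, vals, fps = pair@fps, label = roi@label,
           roiId = roi@roiId, patientId = roi@patientId)
}
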