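#' Stabilize a frame sequence and extract the per-pixel intensity field
#'
#' Whole-frame motion compensation for 2-D perfusion mapping. Frames are
#' selected at the post-processing rate (default 7 fps, by nearest-index
#' selection so 8-bit values are preserved), landmarks detected on the
#' reference frame (the middle selected frame, minimizing composed
#' drift) are tracked outward through the selected frames with
#' frame-to-frame prediction, and a thin-plate-spline warp from
#' reference coordinates to each frame is fitted to the matched
#' landmarks ([fitTPS()]). Applying the estimated motion in reverse, the
#' NIR channel is resampled into reference coordinates (bilinear), so
#' every reference pixel carries a full time-fluorescence curve. Pixels
#' that fall outside the field of view in any frame are flagged invalid
#' and form the border region of the rendered maps.
#'
#' @param pair a \linkS4class{FrameSequencePair} covering at least 90 s.
#' @param cfg list of options: \code{outputFps} (7), \code{lambda} (TPS
#'   regularization, 1), \code{maxLandmarks} (48), \code{patch} (9),
#'   \code{searchRadius} (6), \code{minScore} (0.6), \code{minMatches}
#'   (6), \code{consensusThreshold} (2), \code{maxGap} (maximum run of
#'   frames allowed to reuse the previous warp, 5), \code{returnWarps}
#'   (attach the fitted warp models as an attribute, FALSE).
#' @return a \linkS4class{StabilizedField}. With \code{returnWarps =
#'   TRUE} the attribute \code{"warps"} holds the per-frame
#'   \linkS4class{WarpModel}s and \code{"frames"} the selected frame
#'   indices.
#' @export
stabilize <- function(pair, cfg = list()) {
  opt <- list(outputFps = 7, lambda = 1, maxLandmarks = 48L, patch = 9L,
              searchRadius = 6L, minScore = 0.6, minMatches = 6L,
              consensusThreshold = 2, maxGap = 5L, returnWarps = FALSE)
  opt[names(cfg)] <- cfg
  ts <- pair@timestamps
  if (ts[length(ts)] - ts[1] < 90 - 1 / pair@fps)
    .stopf("stabilization requires at least 90 s of video")
  ## nearest-index frame selection at the output rate
  want <- seq(ts[1], ts[length(ts)], by = 1 / opt$outputFps)
  sel <- unique(vapply(want, function(w) which.min(abs(ts - w)), integer(1)))
  nSel <- length(sel)
  refPos <- (nSel + 1L) %/% 2L
  refIdx <- sel[refPos]
  H <- dim(pair@nir)[2]; W <- dim(pair@nir)[3]
  lum <- function(i) .luminance(pair@whiteLight[i, , , ])
  refLum <- lum(refIdx)
  kp <- .detectKeypoints(refLum, opt$maxLandmarks, opt$patch)
  if (nrow(kp) < opt$minMatches)
    .stopf("insufficient landmarks on the reference frame")
  grid <- cbind(rep(seq_len(H), W), rep(seq_len(W), each = H))
  volume <- array(NA_real_, c(nSel, H, W))
  warps <- vector("list", nSel)
  identityWarp <- new("WarpModel",
                      affine = rbind(c(0, 0), c(1, 0), c(0, 1)),
                      weights = matrix(0, 0, 2),
                      controlPoints = matrix(0, 0, 2), lambda = opt$lambda)

  sampleFrame <- function(pos, warp) {
    srcPts <- warpPoints(warp, grid)
    ## snap float-noise excursions at the frame boundary back inside
    eps <- 1e-6
    r <- srcPts[, 1]; c <- srcPts[, 2]
    r[r > 1 - eps & r < 1] <- 1; r[r > H & r < H + eps] <- H
    c[c > 1 - eps & c < 1] <- 1; c[c > W & c < W + eps] <- W
    vals <- .bilinearSample(pair@nir[sel[pos], , ], r, c)
    volume[pos, , ] <<- matrix(vals, H, W)
  }
  warps[[refPos]] <- identityWarp
  sampleFrame(refPos, identityWarp)

  trackDir <- function(positions) {
    prevDisp <- matrix(0, nrow(kp), 2)   # per-landmark predicted displacement
    lastWarp <- identityWarp
    gap <- 0L
    for (pos in positions) {
      img <- lum(sel[pos])
      m <- tryCatch(
        detectAndMatch(refLum, img, list(
          keypoints = kp, patch = opt$patch,
          searchRadius = opt$searchRadius, minScore = opt$minScore,
          minMatches = opt$minMatches,
          consensusThreshold = opt$consensusThreshold,
          predicted = prevDisp)),
        error = function(e) NULL)
      if (is.null(m)) {
        gap <- gap + 1L
        if (gap > opt$maxGap)
          .stopf("stabilization failure: insufficient landmarks for more than %d consecutive frames",
                 opt$maxGap)
        warp <- lastWarp
      } else {
        gap <- 0L
        warp <- fitTPS(m, lambda = opt$lambda)
        ## update per-landmark prediction from the fitted warp
        prevDisp <- warpPoints(warp, kp) - kp
        lastWarp <- warp
      }
      warps[[pos]] <<- warp
      sampleFrame(pos, warp)
    }
  }
  if (refPos < nSel) trackDir((refPos + 1L):nSel)
  if (refPos > 1L) trackDir((refPos - 1L):1L)

  mask <- matrix(TRUE, H, W)
  for (i in seq_len(nSel)) mask <- mask & !is.na(volume[i, , ])
  volume[is.na(volume)] <- 0
  out <- new("StabilizedField", volume = volume, mask = mask,
             times = ts[sel] - ts[1], fps = opt$outputFps,
             referenceFrame = as.integer(refPos))
  if (opt$returnWarps) {
    attr(out, "warps") <- warps
    attr(out, "frames") <- sel
  }
  out
}
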