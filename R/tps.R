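## TPS radial kernel U(r) = r^2 log r, with U(0) = 0.
.tpsKernel <- function(r) {
  out <- numeric(length(r))
  pos <- r > 0
  out[pos] <- r[pos]^2 * log(r[pos])
  out
}

.tpsKernelMatrix <- function(A, B) {
  d2 <- outer(A[, 1], B[, 1], `-`)^2 + outer(A[, 2], B[, 2], `-`)^2
  r <- sqrt(d2)
  K <- matrix(0, nrow(A), nrow(B))
  pos <- r > 0
  K[pos] <- d2[pos] * log(r[pos])
  K
}

#' Fit a thin-plate-spline warp to landmark correspondences
#'
#' Standard 2-D thin-plate spline with kernel \eqn{U(r) = r^2 \log r}:
#' an affine part plus kernel terms at the source landmarks, solving the
#' bordered linear system with regularization \code{lambda} on the
#' kernel block. With \code{lambda = 0} the warp interpolates the
#' correspondences exactly, and purely affine correspondence sets yield
#' zero kernel weights, so affine motion is reproduced exactly at every
#' point.
#'
#' @param matches correspondence set: a list with matrices \code{src}
#'   and \code{dst} (n x 2, row/col), as produced by [detectAndMatch()],
#'   or an n x 4 matrix \code{(r1, c1, r2, c2)}.
#' @param lambda regularization (>= 0); default 0.
#' @return a \linkS4class{WarpModel} mapping source to destination
#'   coordinates.
#' @export
fitTPS <- function(matches, lambda = 0) {
  m <- .asMatches(matches)
  src <- m$src; dst <- m$dst
  n <- nrow(src)
  if (n < 3L) .stopf("at least 3 correspondences are required")
  P <- cbind(1, src)
  if (qr(P)$rank < 3L)
    .stopf("degenerate configuration: control points are collinear")
  if (lambda < 0) .stopf("lambda must be >= 0")
  K <- .tpsKernelMatrix(src, src)
  L <- rbind(cbind(K + diag(lambda, n), P),
             cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(dst, matrix(0, 3, 2))
  sol <- solve(L, rhs)
  new("WarpModel", affine = sol[(n + 1):(n + 3), , drop = FALSE],
      weights = sol[seq_len(n), , drop = FALSE],
      controlPoints = src, lambda = lambda)
}

#' Apply a thin-plate-spline warp to points
#'
#' @param model a \linkS4class{WarpModel}.
#' @param pts n x 2 matrix of (row, col) coordinates.
#' @return n x 2 matrix of warped coordinates.
#' @export
warpPoints <- function(model, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  out <- cbind(1, pts) %*% model@affine
  if (nrow(model@controlPoints))
    out <- out + .tpsKernelMatrix(pts, model@controlPoints) %*% model@weights
  out
}

.asMatches <- function(matches) {
  if (is.matrix(matches) && ncol(matches) == 4L)
    return(list(src = matches[, 1:2, drop = FALSE],
                dst = matches[, 3:4, drop = FALSE],
                score = rep(1, nrow(matches))))
  if (is.list(matches) && all(c("src", "dst") %in% names(matches)))
    return(matches)
  .stopf("matches must be a list(src, dst) or an n x 4 matrix")
}

## Least-squares similarity transform (rotation + scale + translation)
## from src to dst; returns fitted dst positions.
.similarityFit <- function(src, dst) {
  ## complex-number formulation: dst = a * src + b
  zs <- complex(real = src[, 1], imaginary = src[, 2])
  zd <- complex(real = dst[, 1], imaginary = dst[, 2])
  zsm <- mean(zs); zdm <- mean(zd)
  num <- sum(Conj(zs - zsm) * (zd - zdm))
  den <- sum(Mod(zs - zsm)^2)
  a <- if (den > 1e-12) num / den else complex(real = 1)
  fit <- a * (zs - zsm) + zdm
  cbind(Re(fit), Im(fit))
}

## Detect corner-like keypoints as local maxima of patch variance.
.detectKeypoints <- function(img, maxPoints = 48L, patch = 9L, minSep = 8L) {
  H <- nrow(img); W <- ncol(img)
  m1 <- apply(img, 2, .movingAverage, k = patch)
  m1 <- t(apply(t(m1), 2, .movingAverage, k = patch))
  m2 <- apply(img^2, 2, .movingAverage, k = patch)
  m2 <- t(apply(t(m2), 2, .movingAverage, k = patch))
  v <- pmax(m2 - m1^2, 0)
  marg <- patch + 2L
  v[c(seq_len(marg), (H - marg + 1L):H), ] <- -Inf
  v[, c(seq_len(marg), (W - marg + 1L):W)] <- -Inf
  ord <- order(v, decreasing = TRUE)
  pts <- matrix(0, 0, 2)
  for (k in ord) {
    if (!is.finite(v[k]) || v[k] <= 1e-6) break
    r <- (k - 1L) %% H + 1L; c <- (k - 1L) %/% H + 1L
    if (nrow(pts) &&
        any((pts[, 1] - r)^2 + (pts[, 2] - c)^2 < minSep^2)) next
    pts <- rbind(pts, c(r, c))
    if (nrow(pts) >= maxPoints) break
  }
  pts
}

#' Detect and match landmarks between two frames
#'
#' Corner-like keypoints (local maxima of local patch variance) are
#' detected on frame A and matched into frame B by normalized
#' cross-correlation within a search window, with parabolic sub-pixel
#' refinement. Outliers are rejected by iterated consensus against a
#' similarity-transform motion model (correspondences with residual
#' above \code{consensusThreshold} pixels are dropped and the model
#' refitted).
#'
#' @param frameA,frameB greyscale matrices of equal size (for a
#'   white-light RGB frame, pass its luminance).
#' @param cfg list of options: \code{maxLandmarks} (48), \code{patch}
#'   (9), \code{searchRadius} (8), \code{minScore} (0.6),
#'   \code{minMatches} (6), \code{consensusThreshold} (2 px),
#'   \code{predicted} (n x 2 or 1 x 2 predicted displacement),
#'   \code{keypoints} (reuse previously detected keypoints).
#' @return list with matrices \code{src}, \code{dst} (n x 2 row/col) and
#'   vector \code{score}.
#' @export
detectAndMatch <- function(frameA, frameB, cfg = list()) {
  if (!all(dim(frameA) == dim(frameB)))
    .stopf("frames must have identical size")
  opt <- list(maxLandmarks = 48L, patch = 9L, searchRadius = 8L,
              minScore = 0.6, minMatches = 6L, consensusThreshold = 2,
              predicted = NULL, keypoints = NULL)
  opt[names(cfg)] <- cfg
  kp <- if (is.null(opt$keypoints))
    .detectKeypoints(frameA, opt$maxLandmarks, opt$patch) else opt$keypoints
  if (nrow(kp) < opt$minMatches)
    .stopf("insufficient landmarks: only %d keypoints detected", nrow(kp))
  half <- (opt$patch - 1L) %/% 2L
  pred <- opt$predicted
  if (is.null(pred)) pred <- matrix(0, nrow(kp), 2)
  if (nrow(pred) == 1L) pred <- pred[rep(1L, nrow(kp)), , drop = FALSE]
  src <- dst <- matrix(0, 0, 2); sc <- numeric(0)
  for (i in seq_len(nrow(kp))) {
    tpl <- frameA[(kp[i, 1] - half):(kp[i, 1] + half),
                  (kp[i, 2] - half):(kp[i, 2] + half)]
    m <- .nccBest(frameB, tpl, kp[i, ] + round(pred[i, ]), opt$searchRadius)
    if (is.finite(m$score) && m$score >= opt$minScore) {
      src <- rbind(src, kp[i, ])
      dst <- rbind(dst, c(kp[i, 1] + round(pred[i, 1]) + m$dr + m$subR,
                          kp[i, 2] + round(pred[i, 2]) + m$dc + m$subC))
      sc <- c(sc, m$score)
    }
  }
  if (nrow(src) < opt$minMatches)
    .stopf("insufficient landmarks: only %d matches above score %.2f",
           nrow(src), opt$minScore)
  ## consensus filtering against a similarity model
  keep <- seq_len(nrow(src))
  for (it in 1:3) {
    fit <- .similarityFit(src[keep, , drop = FALSE], dst[keep, , drop = FALSE])
    res <- sqrt(rowSums((dst[keep, , drop = FALSE] - fit)^2))
    inl <- res <= opt$consensusThreshold
    if (all(inl) || sum(inl) < max(3L, opt$minMatches)) break
    keep <- keep[inl]
  }
  if (length(keep) < opt$minMatches)
    .stopf("insufficient landmarks: only %d consensus inliers", length(keep))
  list(src = src[keep, , drop = FALSE], dst = dst[keep, , drop = FALSE],
       score = sc[keep])
}
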