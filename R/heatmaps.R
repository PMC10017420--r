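## Column-wise centered moving average of a T x npx matrix.
.movingAverageMat <- function(X, k) {
  if (k <= 1L) return(X)
  n <- nrow(X)
  h <- (k - 1L) %/% 2L
  cs <- rbind(0, apply(X, 2, cumsum))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L); hi <- pmin(i + h, n)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

#' Per-pixel perfusion milestone maps
#'
#' For every valid pixel of a stabilized field, computes the centre of
#' mass of its time-fluorescence curve (raw samples) and the outflow
#' slope between the pixel's own smoothed peak and peak + 10 s. Pixels
#' whose peak lies within 10 s of the window end get a missing slope.
#'
#' @param field a \linkS4class{StabilizedField}.
#' @param smoothWindow smoothing window (s) before the per-pixel argmax.
#' @param slopeHorizon outflow horizon in seconds (default 10).
#' @param tRef optional global reference time (s) anchoring the outflow
#'   slope of every pixel (the field-wide analogue of the mapped
#'   reference peak used for healthy ROI curves); the default anchors
#'   each pixel at its own peak.
#' @return list with matrices \code{com} (s), \code{slope} (g.u./s) and
#'   \code{tmax} (s); \code{NA} outside the validity mask (and for
#'   missing slopes).
#' @export
pixelMilestones <- function(field, smoothWindow = 1, slopeHorizon = 10,
                            tRef = NULL) {
  d <- dim(field@volume)
  nT <- d[1]; H <- d[2]; W <- d[3]
  idx <- which(field@mask)
  if (!length(idx)) .stopf("no valid pixels in the field")
  X <- matrix(aperm(field@volume, c(1, 2, 3)), nT, H * W)[, idx, drop = FALSE]
  tt <- field@times
  S <- .movingAverageMat(X, .smoothK(field@fps, smoothWindow))
  iPeak <- max.col(t(S), ties.method = "first")
  tot <- colSums(X)
  com <- rep(NA_real_, length(idx))
  okc <- tot > 0
  com[okc] <- colSums(tt * X)[okc] / tot[okc]
  hz <- round(slopeHorizon * field@fps)
  iAnchor <- if (is.null(tRef)) iPeak
  else rep(which.min(abs(tt - tRef)), length(iPeak))
  i10 <- iAnchor + hz
  slope <- rep(NA_real_, length(idx))
  ok <- i10 <= nT
  if (any(ok)) {
    cols <- which(ok)
    f0 <- S[cbind(iAnchor[cols], cols)]
    f1 <- S[cbind(i10[cols], cols)]
    slope[cols] <- (f1 - f0) / (tt[i10[cols]] - tt[iAnchor[cols]])
  }
  wrap <- function(v) {
    m <- matrix(NA_real_, H, W); m[idx] <- v; m
  }
  list(com = wrap(com), slope = wrap(slope), tmax = wrap(tt[iPeak]))
}

#' Optimal piecewise-constant approximation of a curve
#'
#' Exact minimum-squared-error segmentation of a signal into
#' \code{nSegments} contiguous constant-level segments, solved by
#' dynamic programming over all segment boundaries (not a heuristic):
#' the returned segmentation attains the global SSE minimum.
#'
#' @param x numeric signal.
#' @param nSegments number of segments (>= 1, <= length(x)).
#' @return list with \code{breaks} (1-based index of the last sample of
#'   each segment except the final one), \code{levels} (segment means)
#'   and \code{sse} (total squared error).
#' @examples
#' pwcFit(c(0, 0, 0, 10, 10, 10), 2)  # break after sample 3, levels 0/10
#' @export
pwcFit <- function(x, nSegments) {
  n <- length(x)
  if (nSegments < 1L || nSegments > n)
    .stopf("nSegments must be between 1 and length(x)")
  s1 <- c(0, cumsum(x)); s2 <- c(0, cumsum(x^2))
  cost <- function(i, j) {  # segment x[i..j]
    s <- s1[j + 1L] - s1[i]
    (s2[j + 1L] - s2[i]) - s^2 / (j - i + 1L)
  }
  K <- nSegments
  dp <- matrix(Inf, K, n)
  choice <- matrix(0L, K, n)
  for (j in seq_len(n)) dp[1L, j] <- cost(1L, j)
  if (K > 1L) for (k in 2:K) {
    for (j in k:n) {
      best <- Inf; arg <- 0L
      for (i in k:j) {
        v <- dp[k - 1L, i - 1L] + cost(i, j)
        if (v < best) { best <- v; arg <- i }
      }
      dp[k, j] <- best; choice[k, j] <- arg
    }
  }
  ## traceback
  breaks <- integer(0); levels <- numeric(K)
  j <- n
  for (k in K:1) {
    i <- if (k == 1L) 1L else choice[k, j]
    levels[k] <- (s1[j + 1L] - s1[i]) / (j - i + 1L)
    if (k > 1L) breaks <- c(i - 1L, breaks)
    j <- i - 1L
  }
  list(breaks = breaks, levels = levels, sse = dp[K, n])
}

## Batched exact PWC dynamic program: X is n x npx; returns levels
## (nSegments x npx). Same recurrence as pwcFit, vectorized over pixels.
.pwcBatch <- function(X, K) {
  n <- nrow(X); npx <- ncol(X)
  S1 <- rbind(0, apply(X, 2, cumsum))
  S2 <- rbind(0, apply(X^2, 2, cumsum))
  segCost <- function(i, j)
    (S2[j + 1L, ] - S2[i, ]) - (S1[j + 1L, ] - S1[i, ])^2 / (j - i + 1L)
  dpPrev <- matrix(0, n, npx)
  for (j in seq_len(n)) dpPrev[j, ] <- segCost(1L, j)
  choices <- vector("list", K)
  for (k in 2:K) {
    dpCur <- matrix(Inf, n, npx)
    ch <- matrix(0L, n, npx)
    for (j in k:n) {
      best <- rep(Inf, npx); arg <- integer(npx)
      for (i in k:j) {
        v <- dpPrev[i - 1L, ] + segCost(i, j)
        upd <- v < best
        if (any(upd)) { best[upd] <- v[upd]; arg[upd] <- i }
      }
      dpCur[j, ] <- best; ch[j, ] <- arg
    }
    choices[[k]] <- ch
    dpPrev <- dpCur
  }
  levels <- matrix(0, K, npx)
  jv <- rep(n, npx)
  for (k in K:1) {
    iv <- if (k == 1L) rep(1L, npx) else choices[[k]][cbind(jv, seq_len(npx))]
    levels[k, ] <- (S1[cbind(jv + 1L, seq_len(npx))] - S1[cbind(iv, seq_len(npx))]) /
      (jv - iv + 1L)
    jv <- iv - 1L
  }
  levels
}

#' Cluster a stabilized field by perfusion profile
#'
#' Unsupervised delineation of the field: each valid pixel is summarized
#' either by the levels of an optimal piecewise-constant approximation
#' of its curve (\code{featureMode = "pwc"}) or by its (centre of mass,
#' outflow slope) pair, and the summaries are clustered by k-means.
#' Cluster labels are relabeled by ascending cluster-mean centre of
#' mass, so labels are deterministic up to the fixed seed.
#'
#' @param field a \linkS4class{StabilizedField}.
#' @param k number of clusters (>= 2; default 3: lesion / rim /
#'   background).
#' @param seed integer seed for the k-means restarts.
#' @param featureMode \code{"pwc"} or \code{"milestones"}.
#' @param nSegments segments of the PWC summary (default 5).
#' @param pwcSamples the curve is block-averaged to at most this many
#'   samples before the PWC fit (keeps the exact DP affordable).
#' @param nstart k-means restarts.
#' @return integer H x W cluster map (NA outside the validity mask),
#'   with attribute \code{"singular"} TRUE when all profiles were
#'   identical and only one effective cluster exists.
#' @export
clusterField <- function(field, k = 3L, seed = 1L,
                         featureMode = c("pwc", "milestones"),
                         nSegments = 5L, pwcSamples = 90L, nstart = 10L) {
  featureMode <- match.arg(featureMode)
  if (k < 2L) .stopf("k must be >= 2")
  d <- dim(field@volume)
  idx <- which(field@mask)
  if (length(idx) < k) .stopf("fewer valid pixels than clusters")
  nT <- d[1]
  X <- matrix(field@volume, nT, d[2] * d[3])[, idx, drop = FALSE]
  tt <- field@times
  com <- colSums(tt * X) / pmax(colSums(X), .Machine$double.eps)
  if (featureMode == "pwc") {
    if (nT > pwcSamples) {
      bins <- ceiling(seq_len(nT) / (nT / pwcSamples))
      Xc <- rowsum(X, bins) / as.vector(table(bins))
    } else Xc <- X
    feats <- t(.pwcBatch(Xc, as.integer(nSegments)))
  } else {
    pm <- pixelMilestones(field)
    sl <- pm$slope[idx]
    sl[is.na(sl)] <- median(sl, na.rm = TRUE)
    feats <- scale(cbind(com, sl))
  }
  if (nrow(unique(round(feats, 8))) < k) {
    warning("fewer distinct perfusion profiles than clusters; returning a single cluster")
    cm <- matrix(NA_integer_, d[2], d[3]); cm[idx] <- 1L
    attr(cm, "singular") <- TRUE
    return(cm)
  }
  km <- .withSeed(.deriveSeed(seed, "icgflow-kmeans"),
                  kmeans(feats, centers = k, nstart = nstart,
                         iter.max = 50))
  ## relabel by ascending cluster-mean centre of mass
  comByCl <- vapply(seq_len(k), function(cl)
    mean(com[km$cluster == cl]), numeric(1))
  relabel <- match(seq_len(k), order(comByCl))
  cm <- matrix(NA_integer_, d[2], d[3])
  cm[idx] <- relabel[km$cluster]
  attr(cm, "singular") <- FALSE
  cm
}

#' Render a milestone map as a color image
#'
#' Centre-of-mass maps use the viridis scale with delayed (late) values
#' at the yellow end; outflow-slope maps use a diverging scale centered
#' at zero with negative slopes red and positive slopes blue; cluster
#' maps use a qualitative palette. Invalid pixels are grey.
#'
#' @param map numeric (or integer) H x W matrix; NA marks invalid
#'   pixels.
#' @param palette \code{"viridis"}, \code{"diverging"} or
#'   \code{"labels"}.
#' @param center center value of the diverging palette (default 0).
#' @param invalidGrey grey level for invalid pixels.
#' @return H x W x 3 array of RGB values in [0, 1].
#' @export
renderMap <- function(map, palette = c("viridis", "diverging", "labels"),
                      center = 0, invalidGrey = 0.5) {
  palette <- match.arg(palette)
  H <- nrow(map); W <- ncol(map)
  out <- array(invalidGrey, c(H, W, 3))
  ok <- is.finite(map)
  if (!any(ok)) return(out)
  v <- map[ok]
  if (palette == "labels") {
    cols <- grDevices::hcl(h = seq(15, 375, length.out = max(v, na.rm = TRUE) + 1L)[seq_len(max(v))],
                           c = 100, l = 65)
    rgb <- grDevices::col2rgb(cols[v]) / 255
  } else if (palette == "viridis") {
    pal <- grDevices::hcl.colors(256, "viridis")  # index 256 = yellow
    rng <- range(v)
    i <- if (diff(rng) > 0) 1L + round(255 * (v - rng[1]) / diff(rng))
    else rep(128L, length(v))
    rgb <- grDevices::col2rgb(pal[i]) / 255
  } else {
    pal <- grDevices::colorRampPalette(
      c("#b2182b", "#f4a582", "#f7f7f7", "#92c5de", "#2166ac"))(256)
    M <- max(abs(v - center), 1e-12)
    i <- 1L + round(255 * ((v - center) / M + 1) / 2)
    rgb <- grDevices::col2rgb(pal[i]) / 255
  }
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[ok] <- rgb[ch, ]
    out[, , ch] <- plane
  }
  out
}
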