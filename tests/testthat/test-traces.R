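## Minimal hand-built pair: T frames of constant NIR with flat texture.
flatPair <- function(n = 30L, H = 20L, W = 24L, value = 42) {
  wl <- array(128, c(n, H, W, 3))
  nir <- array(value, c(n, H, W))
  frameSequencePair(wl, nir, fps = 30)
}

squareROI <- function(r0, c0, r1, c1, label = "healthy") {
  roiSpec(rbind(c(r0, c0), c(r0, c1), c(r1, c1), c(r1, c0)), label)
}

test_that("overlay frames reduce to their green channel", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_equal(as.vector(overlayToGrayscale(px(0, 255, 0))), 255)
  expect_equal(as.vector(overlayToGrayscale(px(0, 0, 0))), 0)
  expect_equal(as.vector(overlayToGrayscale(px(10, 128, 10))), 128)
  expect_error(overlayToGrayscale(matrix(0, 4, 4)), "3-channel")
})

test_that("ROI validity rules reject malformed polygons", {
  expect_error(squareROI(1, 1, 2, 2), "area")          # below 9 px
  bow <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10)) # self-intersecting
  expect_error(roiSpec(bow, "crlm"), "self-intersect")
  expect_error(roiSpec(rbind(c(0, 0), c(0, 10), c(10, 10)), "tumour"),
               "label")
})

test_that("tracking a static scene yields zero offsets", {
  sc <- staticScene()
  trk <- trackROI(sc$pair, centerROI(sc))
  expect_true(all(trk@offsets == 0))
  expect_true(all(trk@valid))
  expect_gt(min(trk@score), 0.9)
})

test_that("tracking recovers a known motion walk within one pixel", {
  sc <- movingScene()
  roi <- centerROI(sc)
  trk <- trackROI(sc$pair, roi)
  d <- dim(sc$pair@nir)
  ctr <- matrix(c(d[2] / 2, d[3] / 2), 1)
  tru <- t(sapply(seq_len(d[1]), function(i)
    trueDisplacement(sc$truth, i, ctr, refFrame = 1)))
  err <- sqrt(rowSums((trk@offsets - tru)^2))
  expect_gte(mean(err <= 1), 0.95)
})

test_that("overlay mode skips tracking and uses the fixed ROI", {
  cfg <- sceneConfig(width = 24, height = 20, overlayMode = TRUE)
  sc <- renderSequence(cfg, seed = 6)
  trk <- trackROI(sc$pair, centerROI(sc))
  expect_true(all(trk@valid))
  expect_true(all(trk@offsets == 0))
})

test_that("extraction means the NIR intensity over the tracked polygon", {
  pair <- flatPair(value = 42)
  tr <- extractTrace(pair, roi = squareROI(5, 5, 12, 12), windowS = 1)
  expect_equal(length(traceTimes(tr)), 30L)
  expect_true(all(traceIntensities(tr) == 42))

  ## window arithmetic: 90 s at 30 fps -> 2700 samples; 2698 configurable
  sc <- cleanScene()
  expect_equal(nSamples(extractTrace(sc$pair, roi = centerROI(sc))), 2700L)
  expect_equal(nSamples(extractTrace(sc$pair, roi = centerROI(sc),
                                     windowS = 2698 / 30)), 2698L)
})

test_that("a monotone scene yields a monotone trace", {
  n <- 60L
  nir <- array(rep(seq(0, 118, by = 2), each = 1), c(n, 10, 12))
  pair <- frameSequencePair(array(100, c(n, 10, 12, 3)), nir, fps = 30)
  tr <- extractTrace(pair, roi = squareROI(3, 3, 7, 8), windowS = 2)
  expect_true(all(diff(traceIntensities(tr)) >= 0))
})

test_that("tracked extraction on a moving scene matches the static scene", {
  ## same seed => identical tissue, different motion only
  cfgS <- sceneConfig(width = 48, height = 36, noiseSD = 0,
                      pixelJitter = c(amplitude = 0, time = 0, shape = 0),
                      borderPx = 0)
  cfgM <- sceneConfig(width = 48, height = 36, noiseSD = 0,
                      pixelJitter = c(amplitude = 0, time = 0, shape = 0),
                      borderPx = 0,
                      motion = list(stepSD = 0.1, respAmplitude = 1.5,
                                    respPeriod = 4))
  scS <- cleanScene()
  scM <- renderSequence(cfgM, seed = 2)
  roi <- centerROI(scS)
  trS <- extractTrace(scS$pair, roi = roi)
  trM <- extractTrace(scM$pair, trackROI(scM$pair, roi), roi)
  mad <- mean(abs(traceIntensities(trS) - traceIntensities(trM)))
  expect_lt(mad, 1)
})

test_that("degenerate extraction inputs raise errors", {
  pair <- flatPair()
  roi <- squareROI(5, 5, 12, 12)
  badTrack <- new("ROITrack", offsets = matrix(0, 3, 2),
                  valid = rep(TRUE, 3), score = rep(1, 3))
  expect_error(extractTrace(pair, badTrack, roi), "cover all")
  offTrack <- new("ROITrack", offsets = matrix(500, 30, 2),
                  valid = rep(TRUE, 30), score = rep(1, 30))
  expect_error(extractTrace(pair, offTrack, roi), "clipping")
  ## featureless (uniform) frames cannot be tracked at all
  expect_error(trackROI(pair, squareROI(5, 5, 12, 12)), "tracking failure")
})

test_that("trace CSV and ROI JSON round-trip through disk", {
  dir <- withr::local_tempdir()
  tr <- classTrace("lesion")
  p <- file.path(dir, "trace.csv")
  writeTraceCSV(tr, p)
  back <- readTraceCSV(p)
  expect_equal(traceIntensities(back), traceIntensities(tr))
  expect_equal(traceLabel(back), "crlm")

  rois <- list(squareROI(5, 5, 12, 12), squareROI(2, 2, 8, 9, "crlm"))
  rp <- file.path(dir, "rois.json")
  writeROISpecs(rois, rp)
  back <- readROISpecs(rp)
  expect_equal(back[[2]]@polygon, rois[[2]]@polygon)
  expect_equal(back[[1]]@label, "healthy")
  expect_equal(back[[1]]@frame, 1L)
})

test_that("sequence TIFF export round-trips the 8-bit stacks", {
  dir <- withr::local_tempdir()
  cfg <- sceneConfig(width = 20, height = 16)
  sc <- renderSequence(cfg, seed = 8)
  sub <- frameSequencePair(sc$pair@whiteLight[1:5, , , , drop = FALSE],
                           sc$pair@nir[1:5, , , drop = FALSE], fps = 30)
  writeSequenceTIFF(sub, dir)
  back <- readSequenceTIFF(dir)
  expect_equal(back@nir, sub@nir)
  expect_equal(frameRate(back), 30)
})
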