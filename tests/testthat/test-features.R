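rampTrace <- function(n = 2700L, fps = 30, top = 100) {
  tt <- (seq_len(n) - 1) / fps
  roiTrace(tt, top * tt / tt[n], fps = fps, label = "crlm")
}

test_that("smoothing is a shrinking-window centered moving average", {
  tr <- classTrace("lesion")
  expect_equal(smoothTrace(tr, 0)@intensities, tr@intensities)
  const <- roiTrace((0:99) / 30, rep(7, 100), fps = 30)
  expect_equal(smoothTrace(const, 1)@intensities, rep(7, 100))
  ## impulse of height h spread over a k-sample window -> peak h / k
  imp <- roiTrace((0:299) / 30, c(rep(0, 150), 93, rep(0, 149)), fps = 30)
  sm <- smoothTrace(imp, 1)@intensities       # k = 31 samples
  expect_equal(max(sm), 93 / 31)
})

test_that("peak milestones use the earliest smoothed maximum", {
  mono <- rampTrace()
  pk <- peakMilestones(mono)
  expect_equal(pk$tmax, traceTimes(mono)[2700])
  ## two equal maxima: earliest wins (flat plateau)
  tt <- (0:299) / 30
  v <- c(rep(0, 100), rep(50, 100), rep(0, 100))
  pk2 <- peakMilestones(roiTrace(tt, v, fps = 30), smoothWindow = 0)
  expect_equal(pk2$tmax, tt[101])
  ## calibrated CRLM curve peaks at the reference time
  pk3 <- peakMilestones(classTrace("lesion"))
  expect_lt(abs(pk3$tmax - 23.931), 0.5)
})

test_that("half-time and ratio follow the baseline-subtracted rise", {
  ramp <- rampTrace()
  hr <- halfTimeAndRatio(ramp)
  expect_lt(abs(hr$timeRatio - 0.5), 0.02)
  ## calibrated CRLM curve reproduces the reference time ratio
  tr <- classTrace("lesion")
  pk <- peakMilestones(tr)
  hr2 <- halfTimeAndRatio(tr, pk$tmax, pk$fmax)
  expect_lt(abs(hr2$timeRatio - 0.341), 0.02)
  ## flat trace: undefined
  flat <- roiTrace((0:99) / 30, rep(10, 100), fps = 30)
  expect_error(halfTimeAndRatio(flat), class = "icgflow_undefined_feature")
})

test_that("upslope equals the onset-to-peak mean slope", {
  ramp <- rampTrace()
  m <- 100 / traceTimes(ramp)[2700]
  up <- traceUpslope(ramp)
  expect_lt(abs(up - m) / m, 0.03)
  flat <- roiTrace((0:99) / 30, rep(10, 100), fps = 30)
  expect_error(traceUpslope(flat), class = "icgflow_undefined_feature")
  expect_gt(traceUpslope(classTrace("lesion")), 0)
})

test_that("reference peak maps single or averaged CRLM peaks", {
  one <- referencePeak(list(classTrace("lesion")))
  expect_lt(abs(one$tStar - 23.931), 0.5)
  expect_equal(one$provenance, "single_crlm_peak")
  expect_equal(referencePeak(c(20, 30))$tStar, 25)
  expect_equal(referencePeak(c(24, 24, 24))$tStar, 24)
  expect_equal(referencePeak(c(24, 24, 24))$provenance, "mean_crlm_peaks")
  expect_error(referencePeak(numeric(0)), "at least one")
})

test_that("outflow slopes and deltas anchor as specified", {
  tr <- classTrace("lesion")
  pk <- peakMilestones(tr)
  expect_equal(deltaAfter(tr, pk$tmax, 10), 10 * slopeAfter(tr, pk$tmax, 10))
  ## constant trace: zero slope
  const <- roiTrace((0:299) / 30, rep(50, 300), fps = 30)
  expect_equal(slopeAfter(const, 1, 5), 0)
  ## healthy curve is still rising at the mapped CRLM peak: positive slope
  heal <- classTrace("healthy", label = "healthy")
  expect_gt(slopeAfter(heal, 24, 10), 0)
  ## CRLM washes out after its own peak: negative slope
  expect_lt(slopeAfter(tr, pk$tmax, 10), 0)
  ## horizon beyond the window is undefined
  expect_error(slopeAfter(tr, 85, 10), class = "icgflow_undefined_feature")
})

test_that("centre of mass weighs time by intensity", {
  tt <- (0:2699) / 30
  const <- roiTrace(tt, rep(5, 2700), fps = 30)
  expect_equal(centreOfMass(const), mean(tt))
  spike <- roiTrace(tt, c(rep(0, 300), 77, rep(0, 2399)), fps = 30)
  expect_equal(centreOfMass(spike), 10)
  expect_error(centreOfMass(roiTrace(tt, rep(0, 2700), fps = 30)),
               class = "icgflow_undefined_feature")
  ## early CRLM bolus -> earlier centre of mass than healthy accumulation
  expect_lt(centreOfMass(classTrace("lesion")),
            centreOfMass(classTrace("healthy")))
})

test_that("shape moments follow the Fisher-Pearson sample conventions", {
  tt <- (0:3) / 30
  ## symmetric sample: zero skewness
  expect_equal(shapeMoments(roiTrace(tt, c(1, 2, 2, 3), fps = 30))$skew, 0)
  ## independent oracle: direct moment computation for {0, 0, 0, 10}
  x <- c(0, 0, 0, 10)
  m2 <- mean((x - mean(x))^2); m3 <- mean((x - mean(x))^3)
  m4 <- mean((x - mean(x))^4)
  mom <- shapeMoments(roiTrace(tt, x, fps = 30))
  expect_equal(mom$skew, m3 / m2^1.5, tolerance = 1e-12)
  expect_equal(mom$kurtosis, m4 / m2^2 - 3, tolerance = 1e-12)
  ## saturating monotone curve: mass near the maximum, tail to the left
  tt2 <- (0:2699) / 30
  sat <- roiTrace(tt2, 200 * (1 - exp(-tt2 / 10)), fps = 30)
  expect_lt(shapeMoments(sat)$skew, 0)
  ## the early-saturating CRLM bolus shares that sign
  expect_lt(shapeMoments(classTrace("lesion"))$skew, 0)
  expect_error(shapeMoments(roiTrace(tt, rep(1, 4), fps = 30)),
               class = "icgflow_undefined_feature")
})

test_that("computeFeatures assembles the full milestone vector", {
  tr <- classTrace("lesion")
  fe <- computeFeatures(tr)
  df <- as.data.frame(fe)
  expect_named(df, featureNames())
  expect_false(anyNA(df))                     # early peak: all defined
  expect_equal(df$delta10, 10 * df$slope10)
  expect_equal(fe@provenance, "own_peak")

  ## healthy trace anchored at the mapped reference peak
  heal <- classTrace("healthy", label = "healthy")
  feh <- computeFeatures(heal, tStar = 24)
  expect_gt(feh@slope10, 0)
  expect_equal(feh@tStar, 24)
  expect_warning(computeFeatures(heal), "reference peak")

  ## a 30 s trace cannot carry a 60 s outflow slope
  short <- roiTrace((0:899) / 30, traceIntensities(tr)[1:900], fps = 30,
                    label = "crlm")
  expect_true(is.na(computeFeatures(short)@slope60))
})

test_that("features are invariant to a constant time shift", {
  tr <- classTrace("lesion")
  shifted <- roiTrace(traceTimes(tr) + 17.3, traceIntensities(tr),
                      fps = 30, label = "crlm")
  a <- as.data.frame(computeFeatures(tr))
  b <- as.data.frame(computeFeatures(shifted))
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("intensity scaling acts on amplitudes and spares shape features", {
  tr <- classTrace("lesion")
  half <- roiTrace(traceTimes(tr), traceIntensities(tr) / 2,
                   fps = 30, label = "crlm")
  a <- as.data.frame(computeFeatures(tr))
  b <- as.data.frame(computeFeatures(half))
  for (f in c("fmax", "fEnd", "upslope", "delta10", "slope10", "slope20",
              "slope60"))
    expect_equal(b[[f]], a[[f]] / 2, tolerance = 1e-9)
  for (f in c("tmax", "timeRatio", "com", "skew", "kurtosis"))
    expect_equal(b[[f]], a[[f]], tolerance = 1e-9)
})

test_that("feature tables map the per-patient reference peak", {
  traces <- c(
    simulateTraces("crlm", n = 2, seed = 31, patientId = "pA",
                   roiPrefix = "pA_crlm_"),
    simulateTraces("healthy", n = 1, seed = 32, patientId = "pA",
                   roiPrefix = "pA_healthy_"),
    simulateTraces("benign_cyst", n = 1, seed = 33, patientId = "pB",
                   roiPrefix = "pB_cyst_"))
  tab <- computeFeatureTable(traces)
  expect_equal(nrow(tab), 4L)
  expect_named(tab, c("roiId", "patientId", "label", featureNames()))
  ## healthy slope10 anchored at the patient's mean CRLM peak: positive
  expect_gt(tab$slope10[tab$label == "healthy"], 0)
})
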