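test_that("thin-plate splines reproduce affine motion exactly", {
  ## pure translation of the four corners moves every pixel identically
  src <- rbind(c(1, 1), c(1, 40), c(30, 1), c(30, 40))
  w <- fitTPS(cbind(src, src + matrix(rep(c(2, 5), each = 4), 4)), lambda = 0)
  pts <- cbind(runif(50, 1, 30), runif(50, 1, 40))
  expect_lt(max(abs(warpPoints(w, pts) - (pts + rep(c(2, 5), each = 50)))),
            1e-6)
  ## identity correspondences give the identity warp
  wi <- fitTPS(cbind(src, src), lambda = 0)
  expect_lt(max(abs(warpPoints(wi, pts) - pts)), 1e-6)
  ## random affine maps: zero kernel weights, exact everywhere
  set.seed(7)
  for (rep in 1:5) {
    A <- matrix(rnorm(4, sd = 0.2), 2) + diag(2)
    b <- rnorm(2, sd = 3)
    cp <- cbind(runif(8, 0, 50), runif(8, 0, 50))
    dst <- t(A %*% t(cp)) + rep(b, each = 8)
    wa <- fitTPS(cbind(cp, dst), lambda = 0)
    expect_lt(max(abs(wa@weights)), 1e-6)
    expect_lt(max(abs(warpPoints(wa, pts) -
                        (t(A %*% t(pts)) + rep(b, each = 50)))), 1e-6)
  }
})

test_that("interpolating splines bend exactly through control points", {
  src <- rbind(c(5, 5), c(5, 35), c(25, 35), c(25, 5), c(15, 20))
  dst <- src; dst[5, ] <- dst[5, ] + c(3, -2)   # bend one interior point
  w <- fitTPS(cbind(src, dst), lambda = 0)
  expect_lt(max(abs(warpPoints(w, src) - dst)), 1e-6)
  expect_gt(max(abs(w@weights)), 1e-9)          # genuinely non-affine
  ## collinear control points are degenerate
  col <- rbind(c(1, 1), c(2, 2), c(3, 3))
  expect_error(fitTPS(cbind(col, col)), "collinear")
  expect_error(fitTPS(cbind(src, dst), lambda = -1), "lambda")
})

test_that("landmark matching recovers known displacements", {
  set.seed(3)
  img <- icgflow:::.sceneTexture(60, 70)
  ## identical frames: zero displacement
  m0 <- detectAndMatch(img, img)
  expect_lt(max(abs(m0$dst - m0$src)), 0.1)
  ## integer 3 px translation (content moves +3 rows)
  imgB <- matrix(0, 60, 70)
  imgB[4:60, ] <- img[1:57, ]
  m3 <- detectAndMatch(img, imgB)
  disp <- m3$dst - m3$src
  expect_lt(abs(median(disp[, 1]) - 3), 0.5)
  expect_lt(abs(median(disp[, 2])), 0.5)
  ## featureless frames cannot be matched
  expect_error(detectAndMatch(matrix(5, 60, 70), matrix(5, 60, 70)),
               "insufficient landmarks")
})

test_that("zero-motion stabilization returns the raw field, fully valid", {
  sc <- cleanScene()
  fld <- stabilize(sc$pair, cfg = list(returnWarps = TRUE))
  expect_true(all(validityMask(fld)))
  frames <- attr(fld, "frames")
  raw <- sc$pair@nir[frames, , ]
  expect_equal(fld@volume, raw, tolerance = 1e-8)
  expect_equal(fld@fps, 7)
  ## 7 fps selection across >= 90 s
  expect_gte(length(frames), 7 * 90)
})

test_that("stabilization tracks known motion to sub-pixel residuals", {
  sc <- movingScene()
  fld <- movingField()
  warps <- attr(fld, "warps"); frames <- attr(fld, "frames")
  ref <- frames[fld@referenceFrame]
  H <- dim(sc$pair@nir)[2]
  idx <- which(validityMask(fld))
  set.seed(1)
  idx <- sample(idx, 250)
  pts <- cbind((idx - 1) %% H + 1, (idx - 1) %/% H + 1)
  res2 <- vapply(seq_along(frames), function(i) {
    est <- warpPoints(warps[[i]], pts)
    tru <- pts + trueDisplacement(sc$truth, frames[i], pts, refFrame = ref)
    mean(rowSums((est - tru)^2))
  }, numeric(1))
  expect_lt(sqrt(mean(res2)), 1)
  ## drift invalidates the border but keeps the interior
  m <- validityMask(fld)
  expect_false(all(m))
  inner <- m[10:(H - 10), 10:(dim(m)[2] - 10)]
  expect_gt(mean(inner), 0.95)
})

test_that("stabilization improves per-pixel time-to-peak fidelity", {
  sc <- movingScene()
  fld <- movingField()
  frames <- attr(fld, "frames")
  ## uncompensated field: same frames, no motion correction
  rawFld <- new("StabilizedField", volume = sc$pair@nir[frames, , ],
                mask = validityMask(fld), times = fld@times, fps = 7,
                referenceFrame = fld@referenceFrame)
  truthTmax <- sc$truth$pixelParams$delay + sc$truth$pixelParams$timeToPeak
  ## cap the truth at the window end, as extraction does
  truthTmax <- pmin(truthTmax, max(fld@times))
  m <- validityMask(fld)
  errStab <- abs(pixelMilestones(fld)$tmax - truthTmax)[m]
  errRaw <- abs(pixelMilestones(rawFld)$tmax - truthTmax)[m]
  expect_lt(mean(errStab), mean(errRaw))
})

test_that("per-pixel milestone maps carry the class contrast", {
  sc <- staticScene()
  fld <- staticField()
  lab <- classLabels(sc$truth$classMap)
  m <- validityMask(fld)
  pm <- pixelMilestones(fld)
  ## identical curves everywhere -> constant maps
  curve <- gammaVariate(fld@times, kineticDefaults()$lesion)
  one <- new("StabilizedField",
             volume = array(rep(curve, 40 * 6), c(length(curve), 8, 30)),
             mask = matrix(TRUE, 8, 30), times = fld@times, fps = 7,
             referenceFrame = 1L)
  pm1 <- pixelMilestones(one)
  expect_equal(max(pm1$com) - min(pm1$com), 0)
  expect_equal(max(pm1$slope) - min(pm1$slope), 0)
  ## early bolus: lesion COM below healthy COM
  expect_lt(mean(pm$com[lab == "lesion" & m]),
            mean(pm$com[lab == "healthy" & m]))
  ## own-peak outflow: lesion washes out; late healthy peaks have no
  ## 10 s headroom and are flagged missing
  expect_lt(mean(pm$slope[lab == "lesion" & m], na.rm = TRUE), 0)
  expect_gt(mean(is.na(pm$slope[lab == "healthy" & m])), 0.5)
  ## anchored at the lesion reference peak, healthy tissue still rises
  pmr <- pixelMilestones(fld, tRef = mean(pm$tmax[lab == "lesion" & m]))
  expect_lt(mean(pmr$slope[lab == "lesion" & m]), 0)
  expect_gt(mean(pmr$slope[lab == "healthy" & m]), 0)
})

test_that("piecewise-constant fits are exactly optimal", {
  ## worked example: one step, two segments
  fit <- pwcFit(c(0, 0, 0, 10, 10, 10), 2)
  expect_equal(fit$breaks, 3L)
  expect_equal(fit$levels, c(0, 10))
  expect_equal(fit$sse, 0)
  ## single segment: the mean, SSE = n * population variance
  x <- c(2, 4, 9, 1)
  f1 <- pwcFit(x, 1)
  expect_equal(f1$levels, mean(x))
  expect_equal(f1$sse, sum((x - mean(x))^2))
  expect_error(pwcFit(x, 5), "between")

  ## brute-force oracle: enumerate all segmentations, lengths <= 20
  bruteSSE <- function(x, K) {
    n <- length(x)
    if (K == 1) return(sum((x - mean(x))^2))
    min(apply(utils::combn(n - 1, K - 1), 2, function(br) {
      seg <- findInterval(seq_len(n), c(0, br) + 1)
      sum(unlist(lapply(split(x, seg), function(s) sum((s - mean(s))^2))))
    }))
  }
  set.seed(42)
  for (rep in 1:6) {
    n <- sample(8:20, 1)
    K <- sample(2:4, 1)
    x <- round(rnorm(n, 50, 20), 1)
    expect_equal(pwcFit(x, K)$sse, bruteSSE(x, K), tolerance = 1e-9)
  }
  ## batched dynamic program agrees with the single-curve fit
  X <- replicate(5, rnorm(30))
  lv <- icgflow:::.pwcBatch(X, 3L)
  for (j in 1:5) expect_equal(lv[, j], pwcFit(X[, j], 3)$levels)
})

test_that("profile clustering delineates the lesion", {
  sc <- staticScene()
  fld <- staticField()
  lesion <- classLabels(sc$truth$classMap) == "lesion"
  m <- validityMask(fld)
  cl <- clusterField(fld, k = 2, seed = 1)
  ## lesion = earliest-COM cluster (label 1 after relabeling)
  pred <- !is.na(cl) & cl == 1
  jac <- sum(pred & lesion & m) / sum((pred | lesion) & m)
  expect_gte(jac, 0.8)
  ## determinism under a fixed seed
  expect_identical(cl, clusterField(fld, k = 2, seed = 1))
  ## identical curves everywhere: flagged singular
  curve <- gammaVariate(fld@times, kineticDefaults()$healthy)
  one <- new("StabilizedField",
             volume = array(rep(curve, 100), c(length(curve), 10, 10)),
             mask = matrix(TRUE, 10, 10), times = fld@times, fps = 7,
             referenceFrame = 1L)
  expect_warning(c1 <- clusterField(one, k = 2, seed = 1), "single")
  expect_true(attr(c1, "singular"))
  expect_error(clusterField(fld, k = 1), "k must be")
})

test_that("heatmap products round-trip through disk", {
  dir <- withr::local_tempdir()
  fld <- staticField()
  paths <- writeFieldMaps(fld, dir, k = 2, seed = 1)
  expect_true(all(file.exists(unlist(paths))))
  ## physical units recoverable from the normalized float TIFF
  sc <- jsonlite::read_json(file.path(dir, "maps.json"))
  m <- tiff::readTIFF(file.path(dir, "com.tif"))
  rec <- m * (sc$com$max - sc$com$min) + sc$com$min
  pm <- pixelMilestones(fld)
  ok <- is.finite(pm$com)
  expect_lt(max(abs(rec[ok] - pm$com[ok])), 1e-6)
  ## renderings are valid RGB images
  img <- png::readPNG(file.path(dir, "com_render.png"))
  expect_equal(dim(img)[1:2], dim(pm$com))
})

test_that("rendered maps follow the documented palettes", {
  ## all-invalid map: uniform grey
  allNA <- matrix(NA_real_, 4, 5)
  img <- renderMap(allNA, "viridis")
  expect_true(all(img == 0.5))
  ## zero slopes: uniform diverging midpoint (near-white)
  zero <- matrix(0, 4, 5)
  imgz <- renderMap(zero, "diverging")
  expect_lte(length(unique(as.vector(imgz))), 3L)    # a single colour
  expect_true(all(imgz > 0.9))                       # near-white midpoint
  ## COM endpoints hit the palette ends: late = yellow (high R+G, low B)
  com <- matrix(c(10, 50, 30, 40), 2)
  imgc <- renderMap(com, "viridis")
  late <- imgc[2, 1, ]; early <- imgc[1, 1, ]
  expect_gt(late[2], 0.85)            # green-yellow end
  expect_lt(late[3], 0.25)
  expect_gt(early[3], late[3])        # early end is the blue-violet side
  expect_lt(early[2], 0.3)
  ## negative slope red, positive blue
  sl <- matrix(c(-5, 5, 0, NA), 2)
  imgs <- renderMap(sl, "diverging")
  expect_gt(imgs[1, 1, 1], imgs[1, 1, 3])   # negative: red dominates
  expect_gt(imgs[2, 1, 3], imgs[2, 1, 1])   # positive: blue dominates
  expect_equal(imgs[2, 2, ], rep(0.5, 3))   # invalid grey
})
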