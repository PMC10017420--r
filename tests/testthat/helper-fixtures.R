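## Shared fixtures, built once per test session. Scenes are kept small
## (the methods vignette documents the problem sizes used for
## validation) but always span the full >= 90 s acquisition window.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

## Noise- and jitter-free two-region scene: exact round-trip checks.
cleanScene <- function() fixture("clean", function() {
  cfg <- sceneConfig(width = 48, height = 36, noiseSD = 0,
                     pixelJitter = c(amplitude = 0, time = 0, shape = 0),
                     borderPx = 0)
  renderSequence(cfg, seed = 2)
})

## Two-region static scene with sensor noise: clustering / milestones.
staticScene <- function() fixture("static", function() {
  cfg <- sceneConfig(borderPx = 0)
  renderSequence(cfg, seed = 3)
})

## Scene with camera walk + respiration: tracking and stabilization.
movingScene <- function() fixture("moving", function() {
  cfg <- sceneConfig(noiseSD = 1,
                     motion = list(stepSD = 0.12, rotStepSD = 1e-4,
                                   respAmplitude = 2, respPeriod = 4))
  renderSequence(cfg, seed = 5)
})

movingField <- function() fixture("movingField", function() {
  stabilize(movingScene()$pair, cfg = list(returnWarps = TRUE))
})

staticField <- function() fixture("staticField", function() {
  stabilize(staticScene()$pair)
})

## Synthetic study cohort (132 CRLM / 24 healthy / 6 cyst) and its
## feature table.
cohortTable <- function() fixture("cohortTable", function() {
  computeFeatureTable(simulateCohort(seed = 1))
})

cohortClassifier <- function() fixture("cohortClassifier", function() {
  suppressWarnings(optimizeTree(cohortTable(), folds = 10, seed = 1))
})

## Noise-free calibrated class traces on the default 90 s / 30 fps grid.
classTrace <- function(class = c("lesion", "healthy", "cyst"),
                       label = "crlm") {
  class <- match.arg(class)
  kin <- kineticDefaults()[[class]]
  tt <- (0:2699) / 30
  roiTrace(tt, pmin(pmax(gammaVariate(tt, kin), 0), 255), fps = 30,
           label = label, roiId = paste0(class, "_ref"))
}

## Small centered square ROI (row/col polygon).
centerROI <- function(scene, label = "crlm", half = 4L) {
  d <- dim(scene$pair@nir)
  r <- d[2] / 2; c <- d[3] / 2
  roiSpec(rbind(c(r - half, c - half), c(r - half, c + half),
                c(r + half, c + half), c(r + half, c - half)),
          label, roiId = "roi_center", patientId = "p1", frame = 1L)
}
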