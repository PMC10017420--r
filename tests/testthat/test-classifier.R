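## Feature table with one informative feature (tmax) and the remaining
## milestones held constant.
toyTable <- function(x, labels, ids = sprintf("r%03d", seq_along(x))) {
  tab <- data.frame(roiId = ids, patientId = "p1", label = labels,
                    stringsAsFactors = FALSE)
  for (f in featureNames()) tab[[f]] <- 0
  tab$tmax <- x
  tab
}

test_that("stratified split honours fractions, labels and the seed", {
  tab <- toyTable(seq_len(100), rep(c("crlm", "healthy"), each = 50))
  sp <- stratifiedSplit(tab, 0.2, seed = 4)
  expect_equal(nrow(sp$train), 80L)
  expect_equal(nrow(sp$test), 20L)
  expect_identical(sp, stratifiedSplit(tab, 0.2, seed = 4))
  expect_false(identical(sp$test$roiId,
                         stratifiedSplit(tab, 0.2, seed = 5)$test$roiId))
  ## 132 + 6 cohort: at least one of each label in the test split
  tab2 <- toyTable(seq_len(138), c(rep("crlm", 132), rep("benign_cyst", 6)))
  sp2 <- stratifiedSplit(tab2, 0.2, seed = 1)
  expect_true(all(c("crlm", "benign_cyst") %in% sp2$test$label))
  ## singleton label cannot be stratified
  tab3 <- toyTable(1:11, c(rep("crlm", 10), "healthy"))
  expect_error(stratifiedSplit(tab3, 0.2, 1), "stratification")
})

test_that("a linearly separable toy problem is solved perfectly", {
  tab <- toyTable(c(seq(0, 1, length.out = 40), seq(2, 3, length.out = 40)),
                  rep(c("crlm", "healthy"), each = 40))
  clf <- suppressWarnings(optimizeTree(tab, folds = 5, seed = 1))
  expect_equal(clf@cvAccuracy, 100)
  expect_equal(unname(predict(clf, tab[c(1, 80), ])), c("crlm", "healthy"))
})

test_that("overlap fraction q caps accuracy at 1 - q/2, found by a stump", {
  ## class A uniform on [0, 1], class B on [1 - q, 2 - q]: any threshold
  ## within the overlap errs on half the overlapping mass
  q <- 0.3
  n <- 200L
  xa <- seq(0, 1, length.out = n)
  xb <- seq(1 - q, 2 - q, length.out = n)
  tab <- toyTable(c(xa, xb), rep(c("crlm", "healthy"), each = n))
  ## brute-force oracle over all thresholds
  xs <- sort(unique(c(xa, xb)))
  cuts <- c(xs[1] - 1, (xs[-1] + xs[-length(xs)]) / 2, xs[length(xs)] + 1)
  best <- max(sapply(cuts, function(ct)
    (sum(xa < ct) + sum(xb >= ct)) / (2 * n)))
  expect_equal(best, 1 - q / 2, tolerance = 1 / n)
  clf <- suppressWarnings(optimizeTree(tab, folds = 10, seed = 2))
  expect_lt(abs(clf@cvAccuracy / 100 - best), 0.05)
  expect_equal(clf@params$maxdepth, 1)        # tie-break: smallest depth
})

test_that("cross-validation is invariant to row order", {
  tab <- cohortTable()
  perm <- tab[rev(seq_len(nrow(tab))), ]
  a <- suppressWarnings(optimizeTree(tab, folds = 10, seed = 1))
  b <- suppressWarnings(optimizeTree(perm, folds = 10, seed = 1))
  expect_equal(a@cvAccuracy, b@cvAccuracy)
  expect_equal(a@cvPredictions[names(b@cvPredictions)], b@cvPredictions)
})

test_that("degenerate training inputs are rejected or warned about", {
  tab <- toyTable(1:20, rep("crlm", 20))
  expect_error(optimizeTree(tab, folds = 5, seed = 1), "two classes")
  small <- toyTable(c(1:20, 31:34), c(rep("crlm", 20), rep("healthy", 4)))
  expect_warning(optimizeTree(small, folds = 10, seed = 1), "fewer rows")
})

test_that("a depth-1 tree on time-to-peak alone separates the cohort", {
  tab <- cohortTable()
  tab$label <- ifelse(tab$label == "crlm", "crlm", "other")
  fit <- rpart::rpart(label ~ tmax, data = tab, method = "class",
                      control = rpart::rpart.control(maxdepth = 1, cp = 0,
                                                     xval = 0))
  acc <- mean(predict(fit, type = "class") == tab$label)
  expect_gt(acc, 0.95)
})

test_that("evaluation reports match direct confusion-matrix arithmetic", {
  ## stump with known threshold: crlm iff tmax < 1.5
  train <- toyTable(c(seq(0, 1, length.out = 30), seq(2, 3, length.out = 30)),
                    rep(c("crlm", "healthy"), each = 30))
  clf <- suppressWarnings(optimizeTree(train, folds = 5, seed = 1))
  ## perfect test set
  perfect <- toyTable(c(0.4, 0.6, 2.2, 2.8), c("crlm", "crlm", "healthy",
                                               "healthy"),
                      ids = paste0("t", 1:4))
  rp <- evaluateClassifier(clf, perfect)
  expect_equal(rp@accuracy, 100)
  expect_equal(unname(rp@fnr), c(0, 0))

  ## crafted 9/1 vs 0/10 confusion: PPV 100 %, TPR(crlm) 90 %
  test <- toyTable(c(rep(0.5, 9), 2.5, rep(2.5, 10)),
                   c(rep("crlm", 10), rep("healthy", 10)),
                   ids = paste0("u", 1:20))
  rp2 <- evaluateClassifier(clf, test)
  expect_equal(unname(rp2@confusion["crlm", ]), c(9L, 1L))
  expect_equal(unname(rp2@confusion["healthy", ]), c(0L, 10L))
  expect_equal(rp2@ppv, 100)
  expect_equal(unname(rp2@tpr["crlm"]), 90)
  expect_equal(rp2@accuracy, 95)
  ## accuracy from the matrix equals the direct fraction (validity check)
  expect_equal(rp2@accuracy,
               round(100 * sum(diag(rp2@confusion)) / sum(rp2@confusion), 1))
})

test_that("an uninformative majority predictor scores 50 % on balanced data", {
  train <- toyTable(rep(0, 30), c(rep("crlm", 18), rep("healthy", 12)))
  clf <- suppressWarnings(optimizeTree(train, folds = 5, seed = 1))
  balanced <- toyTable(rep(0, 20), rep(c("crlm", "healthy"), 10),
                       ids = paste0("b", 1:20))
  expect_equal(evaluateClassifier(clf, balanced)@accuracy, 50)
})

test_that("labels unseen in training are flagged as an error class", {
  train <- toyTable(c(seq(0, 1, length.out = 20), seq(2, 3, length.out = 20)),
                    rep(c("crlm", "healthy"), each = 20))
  clf <- suppressWarnings(optimizeTree(train, folds = 5, seed = 1))
  test <- toyTable(c(0.5, 2.5, 0.7), c("crlm", "healthy", "benign_cyst"),
                   ids = paste0("v", 1:3))
  expect_warning(rp <- evaluateClassifier(clf, test), "unseen")
  expect_true("benign_cyst" %in% rownames(rp@confusion))
  expect_equal(sum(rp@confusion["benign_cyst", ]), 1L)
})

test_that("the exported JSON tree reproduces the fitted predictions", {
  dir <- withr::local_tempdir()
  tab <- cohortTable()
  clf <- cohortClassifier()
  p <- file.path(dir, "model.json")
  writeModelJSON(clf, p)
  js <- jsonlite::read_json(p)
  ## independent interpreter for the serialized tree
  predJSON <- function(node, row) {
    while (!isTRUE(node$leaf)) {
      v <- row[[node$feature]]
      goLeft <- if (node$leftIf == "<") v < node$threshold
      else v >= node$threshold
      node <- if (goLeft) node$left else node$right
    }
    node$class
  }
  full <- icgflow:::.applyImpute(tab, clf@imputeMedians)
  fromJSON <- vapply(seq_len(nrow(full)), function(i)
    predJSON(js$tree, full[i, ]), character(1))
  expect_equal(fromJSON, unname(predict(clf, tab)))
})

test_that("roster mode can prefer a non-tree family when it wins", {
  tab <- toyTable(c(seq(0, 1, length.out = 30), seq(2, 3, length.out = 30)),
                  rep(c("crlm", "healthy"), each = 30))
  clf <- suppressWarnings(optimizeTree(tab, folds = 5, seed = 1,
                                       roster = TRUE))
  expect_true(clf@family %in% c("tree", "lda", "knn"))
  expect_equal(clf@cvAccuracy, 100)
})
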