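#' Fitted ROI classifier
#'
#' A classifier selected by exhaustive hyperparameter search under
#' cross-validation on an ROI feature table.
#'
#' @slot model the fitted model object (an \code{rpart} tree, or the
#'   winning model of the roster search).
#' @slot family \code{"tree"}, \code{"lda"} or \code{"knn"}.
#' @slot params named list of winning hyperparameters.
#' @slot cvAccuracy cross-validated overall accuracy (%).
#' @slot cvPredictions named character vector of out-of-fold predicted
#'   labels, keyed by \code{roiId}.
#' @slot imputeMedians named numeric of training medians used to fill
#'   missing features.
#' @slot labels class labels seen in training.
#' @slot trainData training feature table (needed by the knn family).
#' @export
setClass("FittedClassifier", representation(
  model = "ANY", family = "character", params = "list",
  cvAccuracy = "numeric", cvPredictions = "character",
  imputeMedians = "numeric", labels = "character", trainData = "data.frame"
))

setMethod("show", "FittedClassifier", function(object) {
  ps <- paste(names(object@params), unlist(object@params), sep = "=",
              collapse = ", ")
  cat(sprintf("FittedClassifier (%s): %s\n  CV accuracy %.1f%% over labels: %s\n",
              object@family, ps, object@cvAccuracy,
              paste(object@labels, collapse = ", ")))
})

.checkFeatureTable <- function(table) {
  need <- c("roiId", "label", featureNames())
  miss <- setdiff(need, names(table))
  if (length(miss))
    .stopf("feature table lacks columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(table$roiId)) .stopf("duplicated roiId in feature table")
  invisible(table)
}

#' Stratified train/test split of a feature table
#'
#' Splits ROI rows into train and test sets, stratified by label (every
#' label contributes at least one test row), deterministic for a fixed
#' seed. An optional group-by-patient mode keeps all ROIs of a patient
#' on the same side (off by default, mirroring an ROI-level split).
#'
#' @param table feature table (see [computeFeatureTable()]).
#' @param testFraction fraction of rows held out (default 0.2).
#' @param seed integer seed.
#' @param byPatient logical; split whole patients instead of ROIs.
#' @return list with data.frames \code{train} and \code{test}.
#' @export
stratifiedSplit <- function(table, testFraction = 0.2, seed = 1L,
                            byPatient = FALSE) {
  .checkFeatureTable(table)
  counts <- table(table$label)
  if (any(counts < 2L))
    .stopf("stratification error: label '%s' has fewer than 2 rows",
           names(counts)[which(counts < 2L)[1]])
  .withSeed(.deriveSeed(seed, "icgflow-split"), {
    testIdx <- integer(0)
    for (lb in names(counts)) {
      rows <- which(table$label == lb)
      if (byPatient) {
        pats <- unique(table$patientId[rows])
        nTest <- max(1L, round(testFraction * length(pats)))
        testPats <- sample(pats, nTest)
        testIdx <- c(testIdx, rows[table$patientId[rows] %in% testPats])
      } else {
        nTest <- max(1L, round(testFraction * length(rows)))
        testIdx <- c(testIdx, sample(rows, nTest))
      }
    }
    list(train = table[-testIdx, , drop = FALSE],
         test = table[testIdx, , drop = FALSE])
  })
}

## Reproducible fold assignment: hash of roiId and seed, independent of
## row order.
.foldAssign <- function(roiIds, seed, folds) {
  as.integer(.fnv1a(paste0(roiIds, "#", seed)) %% folds) + 1L
}

.imputeMedians <- function(train) {
  med <- vapply(featureNames(), function(f)
    median(train[[f]], na.rm = TRUE), numeric(1))
  med[is.na(med)] <- 0
  med
}

.applyImpute <- function(tab, med) {
  for (f in featureNames()) {
    v <- tab[[f]]
    v[is.na(v)] <- med[[f]]
    tab[[f]] <- v
  }
  tab
}

.fitOne <- function(family, params, train) {
  fml <- stats::as.formula(paste("label ~", paste(featureNames(), collapse = "+")))
  train$label <- factor(train$label)
  switch(family,
    tree = rpart::rpart(
      fml, data = train, method = "class",
      parms = list(split = params$split),
      control = rpart::rpart.control(
        maxdepth = params$maxdepth, minbucket = params$minbucket,
        minsplit = max(2L, 2L * params$minbucket), cp = 0, xval = 0,
        maxcompete = 0, maxsurrogate = 0)),
    lda = {
      ## lda cannot take features constant within every group
      keep <- featureNames()[vapply(featureNames(), function(f)
        max(tapply(train[[f]], train$label, var)) > 1e-12, logical(1))]
      if (!length(keep)) .stopf("no non-constant features for lda")
      MASS::lda(stats::as.formula(
        paste("label ~", paste(keep, collapse = "+"))), data = train)
    },
    knn = train   # lazy learner: the training data is the model
  )
}

.predictOne <- function(family, model, params, newdata) {
  switch(family,
    tree = as.character(predict(model, newdata = newdata, type = "class")),
    lda = as.character(predict(model, newdata = newdata)$class),
    knn = as.character(class::knn(
      train = scale(model[, featureNames()]),
      test = scale(newdata[, featureNames()],
                   center = attr(scale(model[, featureNames()]), "scaled:center"),
                   scale = attr(scale(model[, featureNames()]), "scaled:scale")),
      cl = factor(model$label), k = params$k))
  )
}

## Cross-validated out-of-fold predictions for one (family, params).
.cvPredict <- function(family, params, table, fold) {
  pred <- character(nrow(table))
  for (f in sort(unique(fold))) {
    inTr <- fold != f
    if (length(unique(table$label[inTr])) < 2L) {
      pred[!inTr] <- NA_character_
      next
    }
    med <- .imputeMedians(table[inTr, , drop = FALSE])
    trI <- .applyImpute(table[inTr, , drop = FALSE], med)
    teI <- .applyImpute(table[!inTr, , drop = FALSE], med)
    mod <- .fitOne(family, params, trI)
    pred[!inTr] <- .predictOne(family, mod, params, teI)
  }
  pred
}

#' Hyperparameter-optimized classifier for ROI feature tables
#'
#' Exhaustive grid search over decision-tree hyperparameters (maximum
#' depth 1-10, minimum leaf size {1, 2, 5, 10, 20}, split criterion gini
#' or information gain), selecting the candidate with the highest mean
#' cross-validated accuracy; ties prefer the smaller depth, then the
#' larger leaf size. Folds are assigned by a hash of \code{roiId} and
#' the seed, so the assignment is reproducible and independent of row
#' order. Missing features are imputed with training-fold medians, never
#' across the train/validation boundary. The winning configuration is
#' refitted on the full table. With \code{roster = TRUE} the search
#' additionally covers linear discriminant analysis and k-nearest
#' neighbours and returns the best candidate overall.
#'
#' @param train feature table (see [computeFeatureTable()]).
#' @param folds number of cross-validation folds (default 10). Labels
#'   with fewer rows than folds are tolerated with a warning (some folds
#'   simply lack that label).
#' @param seed integer seed (drives the fold hash).
#' @param roster also search non-tree families.
#' @return a \linkS4class{FittedClassifier}.
#' @export
optimizeTree <- function(train, folds = 10L, seed = 1L, roster = FALSE) {
  .checkFeatureTable(train)
  counts <- table(train$label)
  if (length(counts) < 2L)
    .stopf("training data must contain at least two classes")
  if (any(counts < folds))
    warning(sprintf(
      "label(s) %s have fewer rows than folds; some folds will lack them",
      paste(names(counts)[counts < folds], collapse = ", ")))
  fold <- .foldAssign(train$roiId, seed, folds)
  ## grid ordered so the first best row realizes the tie-break:
  ## smaller depth first, then larger leaf
  grid <- expand.grid(minbucket = c(20L, 10L, 5L, 2L, 1L),
                      maxdepth = 1:10,
                      split = c("gini", "information"),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$maxdepth, -grid$minbucket), ]
  cands <- lapply(seq_len(nrow(grid)), function(i)
    list(family = "tree", params = as.list(grid[i, ])))
  if (roster) {
    if (!requireNamespace("MASS", quietly = TRUE) ||
        !requireNamespace("class", quietly = TRUE))
      .stopf("roster mode requires the MASS and class packages")
    cands <- c(cands, list(list(family = "lda", params = list())),
               lapply(c(1L, 3L, 5L, 7L), function(k)
                 list(family = "knn", params = list(k = k))))
  }
  best <- NULL; bestAcc <- -Inf; bestPred <- NULL
  for (cand in cands) {
    ## a roster family may be infeasible for this table (e.g. singular
    ## lda); such candidates simply drop out of the search
    pred <- tryCatch(.cvPredict(cand$family, cand$params, train, fold),
                     error = function(e) NULL)
    if (is.null(pred)) next
    acc <- mean(pred == train$label, na.rm = TRUE)
    if (acc > bestAcc + 1e-12) {
      bestAcc <- acc; best <- cand; bestPred <- pred
    }
  }
  med <- .imputeMedians(train)
  full <- .applyImpute(train, med)
  model <- .fitOne(best$family, best$params, full)
  names(bestPred) <- train$roiId
  new("FittedClassifier", model = model, family = best$family,
      params = best$params, cvAccuracy = 100 * bestAcc,
      cvPredictions = bestPred, imputeMedians = med,
      labels = sort(unique(train$label)), trainData = full)
}

#' Per-class cross-validated accuracy
#'
#' Fraction (%) of ROIs of one class whose out-of-fold prediction during
#' the hyperparameter search matched the true label.
#'
#' @param clf a \linkS4class{FittedClassifier}.
#' @param table the feature table the classifier was optimized on.
#' @param label class of interest.
#' @return percentage correct.
#' @export
cvClassAccuracy <- function(clf, table, label) {
  truth <- table$label[match(names(clf@cvPredictions), table$roiId)]
  sel <- truth == label
  if (!any(sel)) .stopf("label '%s' absent from the table", label)
  100 * mean(clf@cvPredictions[sel] == label, na.rm = TRUE)
}

#' Predict labels for new feature rows
#'
#' @param object a \linkS4class{FittedClassifier}.
#' @param newdata feature table rows.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
setMethod("predict", "FittedClassifier", function(object, newdata, ...) {
  nd <- .applyImpute(newdata, object@imputeMedians)
  .predictOne(object@family,
              if (object@family == "knn") object@trainData else object@model,
              object@params, nd)
})

#' Evaluate a classifier on a held-out test set
#'
#' Builds the confusion matrix (rows = true labels, columns = predicted)
#' and summary rates: overall accuracy, positive predictive value for
#' the CRLM class (TP / (TP + FP) with \code{"crlm"} positive), and
#' per-class true-positive and false-negative rates, all in percent to
#' one decimal. Labels present in the test set but unseen in training
#' are counted as an error class and flagged with a warning.
#'
#' @param clf a \linkS4class{FittedClassifier}.
#' @param test feature table rows.
#' @param positive label treated as positive for the PPV (default
#'   \code{"crlm"}).
#' @return a \linkS4class{ClassifierReport}.
#' @export
evaluateClassifier <- function(clf, test, positive = "crlm") {
  if (!nrow(test)) .stopf("test set is empty")
  pred <- predict(clf, test)
  unseen <- setdiff(unique(test$label), clf@labels)
  if (length(unseen))
    warning(sprintf("label(s) unseen in training counted as errors: %s",
                    paste(unseen, collapse = ", ")))
  levs <- union(clf@labels, unique(test$label))
  cm <- table(factor(test$label, levels = levs),
              factor(pred, levels = levs))
  cm <- unclass(cm)
  storage.mode(cm) <- "integer"
  acc <- 100 * sum(diag(cm)) / sum(cm)
  ppv <- if (positive %in% levs && sum(cm[, positive]) > 0)
    100 * cm[positive, positive] / sum(cm[, positive]) else NA_real_
  rs <- rowSums(cm)
  tpr <- ifelse(rs > 0, 100 * diag(cm) / rs, NA_real_)
  names(tpr) <- levs
  new("ClassifierReport", confusion = cm, accuracy = round(acc, 1),
      ppv = if (is.na(ppv)) NA_real_ else round(ppv, 1),
      tpr = round(tpr, 1), fnr = round(100 - tpr, 1))
}
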