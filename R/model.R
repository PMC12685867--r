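## Gradient-boosted classification with grid-searched hyperparameters,
## confusion-matrix metrics with rank-based AUC, and exact tree-SHAP
## feature / family attribution.

#' Stratified train/test split
#'
#' Per class, `floor(testFrac * n_class)` samples go to the test split
#' (the committed deterministic rounding rule); the rest train. Disjoint
#' and reproducible by seed.
#'
#' @param fm a labeled [FeatureMatrix-class].
#' @param testFrac test fraction, default 0.2.
#' @param seed integer seed.
#' @return list with `train` and `test` [FeatureMatrix-class] objects.
#' @export
splitTrainTest <- function(fm, testFrac = 0.2, seed = 1L) {
  stopifnot(is(fm, "FeatureMatrix"), testFrac > 0, testFrac < 1)
  labels <- featureLabels(fm)
  if (is.null(labels)) stop("labels required for a stratified split")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  set.seed(seed)
  test_idx <- integer(0)
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    n_test <- floor(testFrac * length(idx))
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  list(train = fm[-test_idx, ], test = fm[sort(test_idx), ])
}

#' The committed hyperparameter grid
#'
#' max_depth {3, 5, 7} x eta {0.05, 0.1, 0.3} x nrounds {100, 300} x
#' subsample {0.8, 1.0} — 36 configurations, searched by stratified 5-fold
#' cross-validated accuracy in [trainModel()].
#'
#' @return data.frame, one row per configuration.
#' @export
defaultGrid <- function() {
  expand.grid(max_depth = c(3L, 5L, 7L), eta = c(0.05, 0.1, 0.3),
              nrounds = c(100L, 300L), subsample = c(0.8, 1.0),
              KEEP.OUT.ATTRS = FALSE)
}

xgbFit <- function(X, y, max_depth, eta, nrounds, subsample, seed) {
  params <- list(objective = "binary:logistic", max_depth = max_depth,
                 eta = eta, subsample = subsample, nthread = 1,
                 seed = as.integer(seed))
  d <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(params = params, data = d, nrounds = nrounds,
                     verbose = 0)
}

#' Train the gradient-boosted classifier with grid search
#'
#' Restricts the training data to `selected` features, searches the
#' hyperparameter grid by stratified k-fold cross-validated accuracy on
#' the training data only (no test leakage), breaks ties toward the
#' smaller model (fewer rounds, then shallower trees, then grid order),
#' and refits the winning configuration on the full training data. The
#' result is deterministic given the seed: training twice yields
#' byte-identical serialized boosters.
#'
#' @param train a labeled [FeatureMatrix-class].
#' @param selected feature names to train on (default: all columns).
#' @param grid data.frame of configurations, see [defaultGrid()].
#' @param nfolds stratified CV folds (default 5).
#' @param seed integer seed.
#' @return A [ModelBundle-class].
#' @export
trainModel <- function(train, selected = NULL, grid = defaultGrid(),
                       nfolds = 5L, seed = 1L) {
  stopifnot(is(train, "FeatureMatrix"))
  labels <- featureLabels(train)
  if (is.null(labels)) stop("labels required to train")
  if (any(table(factor(labels, levels = c(0, 1))) < 2))
    stop("need at least 2 samples per class")
  if (is.null(selected)) selected <- featureSchema(train)$name
  if (length(selected) == 0) stop("empty selected feature set")
  missing <- setdiff(selected, featureSchema(train)$name)
  if (length(missing))
    stop("unknown feature name(s): ", paste(missing, collapse = ", "))
  train <- train[, selected]
  X <- featureValues(train); y <- featureLabels(train)
  fold <- stratifiedFolds(y, nfolds, seed)
  cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
    accs <- vapply(seq_len(nfolds), function(k) {
      tr <- fold != k
      if (length(unique(y[tr])) < 2 || !any(!tr)) return(NA_real_)
      bst <- xgbFit(X[tr, , drop = FALSE], y[tr],
                    grid$max_depth[g], grid$eta[g], grid$nrounds[g],
                    grid$subsample[g], seed)
      p <- stats::predict(bst,
                          xgboost::xgb.DMatrix(X[!tr, , drop = FALSE],
                                               nthread = 1))
      mean(as.integer(p >= 0.5) == y[!tr])
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }, numeric(1))
  ord <- order(-cv_acc, grid$nrounds, grid$max_depth,
               seq_len(nrow(grid)))
  best <- ord[1]
  bst <- xgbFit(X, y, grid$max_depth[best], grid$eta[best],
                grid$nrounds[best], grid$subsample[best], seed)
  new("ModelBundle",
      booster = xgboost::xgb.save.raw(bst),
      featureNames = selected,
      bestParams = as.list(grid[best, , drop = FALSE]),
      searchInfo = list(grid = grid, cvAccuracy = cv_acc,
                        nfolds = as.integer(nfolds)),
      seed = as.integer(seed), schemaVersion = SCHEMA_VERSION)
}

#' Predict bacteriocin probabilities
#'
#' @param bundle a [ModelBundle-class].
#' @param newdata a [FeatureMatrix-class] (any superset of the bundle's
#'   feature subset) or numeric matrix with matching column names.
#' @return named numeric vector of probabilities in [0, 1].
#' @export
predictProb <- function(bundle, newdata) {
  stopifnot(is(bundle, "ModelBundle"))
  X <- if (is(newdata, "FeatureMatrix")) {
    avail <- featureSchema(newdata)$name
    miss <- setdiff(bundle@featureNames, avail)
    if (length(miss))
      stop("feature schema mismatch: data lacks ",
           paste(utils::head(miss, 3), collapse = ", "))
    featureValues(newdata[, bundle@featureNames])
  } else {
    miss <- setdiff(bundle@featureNames, colnames(newdata))
    if (length(miss)) stop("feature schema mismatch")
    newdata[, bundle@featureNames, drop = FALSE]
  }
  bst <- xgboost::xgb.load.raw(bundle@booster)
  p <- stats::predict(bst, xgboost::xgb.DMatrix(X, nthread = 1))
  stats::setNames(p, rownames(X))
}

#' Metric suite from confusion counts
#'
#' Accuracy, precision, recall, F1 and the Matthews correlation
#' coefficient from TP/TN/FP/FN. A metric whose denominator is zero is
#' reported as 0 and listed in the report's `degenerate` slot rather than
#' propagating NaN.
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @param auc optional AUC to carry into the report (`NA` if unknown).
#' @return A [MetricsReport-class].
#' @export
#' @examples
#' metricValues(confusionMetrics(55, 56, 0, 1))
confusionMetrics <- function(tp, tn, fp, fn, auc = NA_real_) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  degenerate <- character(0)
  total <- tp + tn + fp + fn
  safe <- function(num, den, name) {
    if (den == 0) { degenerate <<- c(degenerate, name); return(0) }
    num / den
  }
  acc <- safe(tp + tn, total, "accuracy")
  prec <- safe(tp, tp + fp, "precision")
  rec <- safe(tp, tp + fn, "recall")
  f1 <- safe(2 * prec * rec, prec + rec, "f1")
  mcc_den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (mcc_den == 0) { degenerate <- c(degenerate, "mcc"); 0 }
         else (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  new("MetricsReport",
      confusion = c(TP = as.integer(tp), TN = as.integer(tn),
                    FP = as.integer(fp), FN = as.integer(fn)),
      metrics = c(accuracy = acc, precision = prec, recall = rec,
                  f1 = f1, mcc = mcc, auc = auc),
      degenerate = degenerate)
}

#' Rank-based AUC (Mann-Whitney formulation)
#'
#' AUC = (R_pos - n_pos (n_pos + 1) / 2) / (n_pos * n_neg), where R_pos is
#' the rank sum of the positive-class scores with mean ranks on ties — so
#' tied scores count as half-concordant and all-equal scores give 0.5.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUC in [0, 1].
#' @export
rankAUC <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a model on a test split
#'
#' Thresholds predicted probabilities at 0.5 (probability >= 0.5 is called
#' positive), forms the confusion matrix, and derives the metric suite
#' plus the rank-based AUC.
#'
#' @param bundle a [ModelBundle-class].
#' @param test a labeled [FeatureMatrix-class].
#' @return A [MetricsReport-class].
#' @export
evaluateModel <- function(bundle, test) {
  labels <- featureLabels(test)
  if (is.null(labels)) stop("labels required to evaluate")
  p <- predictProb(bundle, test)
  pred <- as.integer(p >= 0.5)
  confusionMetrics(tp = sum(pred == 1 & labels == 1),
                   tn = sum(pred == 0 & labels == 0),
                   fp = sum(pred == 1 & labels == 0),
                   fn = sum(pred == 0 & labels == 1),
                   auc = rankAUC(p, labels))
}

#' SHAP feature and family attribution
#'
#' Computes exact tree-SHAP values (margin scale) for every sample, ranks
#' features by mean |SHAP|, and aggregates the per-feature importances
#' into the nine descriptor families (AAC, DC, PseAAC, APseAAC, CTD, SS,
#' SOCN, QSO, PSSM); families whose features were pruned away contribute
#' 0. The per-sample values satisfy the local-accuracy identity: base
#' value + row sum equals the model's margin output (to float32
#' representation error, since the booster evaluates in single precision).
#'
#' @param bundle a [ModelBundle-class].
#' @param data a [FeatureMatrix-class] (conventionally the test split).
#' @param topK how many features `topFeatures` reports at minimum in
#'   `show()`; all features are ranked regardless. Default 10.
#' @return A [ShapSummary-class].
#' @export
explainModel <- function(bundle, data, topK = 10L) {
  stopifnot(is(bundle, "ModelBundle"))
  fm <- if (is(data, "FeatureMatrix")) data[, bundle@featureNames]
        else stop("'data' must be a FeatureMatrix")
  X <- featureValues(fm)
  bst <- xgboost::xgb.load.raw(bundle@booster)
  contrib <- stats::predict(bst, xgboost::xgb.DMatrix(X, nthread = 1),
                            predcontrib = TRUE)
  ## last column is the bias / expected-margin term
  base <- contrib[1, ncol(contrib)]
  vals <- contrib[, -ncol(contrib), drop = FALSE]
  colnames(vals) <- bundle@featureNames
  rownames(vals) <- rownames(X)
  mean_abs <- colMeans(abs(vals))
  ord <- order(-mean_abs, match(names(mean_abs), featureSchemaTable()$name))
  fams <- c("AAC", "DC", "PseAAC", "APseAAC", "CTD", "SS", "SOCN", "QSO",
            "PSSM")
  fam_of <- featureDisplayFamily(names(mean_abs))
  fam_sums <- vapply(fams, function(f) sum(mean_abs[fam_of == f]),
                     numeric(1))
  new("ShapSummary", values = vals, baseValue = unname(base),
      meanAbs = mean_abs, topFeatures = names(mean_abs)[ord],
      familySums = fam_sums)
}
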