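test_that("stratified train/test split uses the per-class floor rule", {
  fm <- syntheticPanel(1)
  sp <- splitTrainTest(fm, testFrac = 0.2, seed = 3)
  expect_identical(nrow(featureValues(sp$test)), 112L)  # floor(0.2*283)*2
  expect_identical(sum(featureLabels(sp$test)), 56L)
  expect_identical(nrow(featureValues(sp$train)), 454L)
  expect_setequal(c(sampleIds(sp$train), sampleIds(sp$test)), sampleIds(fm))
  expect_length(intersect(sampleIds(sp$train), sampleIds(sp$test)), 0)
  sp2 <- splitTrainTest(fm, testFrac = 0.2, seed = 3)
  expect_identical(sampleIds(sp2$test), sampleIds(sp$test))
})

test_that("the metric suite reproduces closed-form identities", {
  rep <- confusionMetrics(55, 56, 0, 1)
  m <- metricValues(rep)
  expect_equal(round(unname(m["accuracy"]), 4), 0.9911)
  expect_equal(unname(m["precision"]), 1)
  expect_equal(round(unname(m["recall"]), 4), 0.9821)
  expect_equal(round(unname(m["f1"]), 4), 0.9910)
  expect_equal(round(unname(m["mcc"]), 4), 0.9823)
  perfect <- metricValues(confusionMetrics(10, 10, 0, 0))
  expect_equal(unname(perfect[c("accuracy", "precision", "recall", "f1",
                                "mcc")]), rep(1, 5))
  # random confusion matrices: harmonic-mean, bounding and sign identities
  set.seed(5)
  for (i in 1:1000) {
    cm <- sample(0:40, 4, replace = TRUE)
    m <- metricValues(confusionMetrics(cm[1], cm[2], cm[3], cm[4]))
    deg <- confusionMetrics(cm[1], cm[2], cm[3], cm[4])@degenerate
    if (!any(c("precision", "recall", "f1") %in% deg) &&
        (m["precision"] + m["recall"]) > 0)
      expect_equal(unname(m["f1"]),
                   2 * m[["precision"]] * m[["recall"]] /
                     (m[["precision"]] + m[["recall"]]))
    if (cm[1] + cm[4] > 0 && cm[2] + cm[3] > 0) {
      accs <- c(cm[1] / (cm[1] + cm[4]), cm[2] / (cm[2] + cm[3]))
      expect_gte(m[["accuracy"]], min(accs) - 1e-12)
      expect_lte(m[["accuracy"]], max(accs) + 1e-12)
    }
    if (!"mcc" %in% deg)
      expect_identical(sign(m[["mcc"]]),
                       sign(as.numeric(cm[1]) * cm[2] -
                            as.numeric(cm[3]) * cm[4]))
  }
  # degenerate denominators report 0 with a flag, not NaN
  deg <- confusionMetrics(0, 10, 0, 5)
  expect_identical(unname(metricValues(deg)["precision"]), 0)
  expect_true(all(c("precision", "mcc") %in% deg@degenerate))
})

test_that("label-convention swap maps the metrics symmetrically", {
  set.seed(8)
  for (i in 1:50) {
    cm <- sample(1:30, 4)                             # TP TN FP FN
    a <- metricValues(confusionMetrics(cm[1], cm[2], cm[3], cm[4]))
    b <- metricValues(confusionMetrics(cm[2], cm[1], cm[4], cm[3]))
    expect_equal(unname(a["mcc"]), unname(b["mcc"]))
    # swapped recall is the original specificity TN/(TN+FP)
    expect_equal(unname(b["recall"]), cm[2] / (cm[2] + cm[3]))
    expect_equal(unname(a["accuracy"]), unname(b["accuracy"]))
  }
})

test_that("rank AUC counts concordant pairs with tie correction", {
  expect_equal(rankAUC(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(rankAUC(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(rankAUC(rep(0.3, 10), rep(c(1, 0), 5)), 0.5)
  # cross-check against an independent implementation on random scores
  skip_if_not_installed("pROC")
  set.seed(9)
  for (i in 1:10) {
    sc <- round(runif(60), 2)                          # forces ties
    lb <- rbinom(60, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(rankAUC(sc, lb),
                 as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                                direction = "<"))))
  }
})

smallGrid <- function()
  expand.grid(max_depth = c(3L, 5L), eta = 0.3, nrounds = 50L,
              subsample = 1.0, KEEP.OUT.ATTRS = FALSE)

test_that("training is deterministic and validates its inputs", {
  fm <- plantedMatrix(n = 60, mNoise = 15, seed = 10)
  b1 <- trainModel(fm, grid = smallGrid(), nfolds = 3, seed = 7)
  b2 <- trainModel(fm, grid = smallGrid(), nfolds = 3, seed = 7)
  expect_identical(b1@booster, b2@booster)            # byte-identical
  expect_identical(b1@bestParams, b2@bestParams)
  expect_error(trainModel(fm, selected = character(0)), "empty selected")
  expect_error(trainModel(fm, selected = c("aac_1", "nope_9")),
               "unknown feature")
  single <- fm[featureLabels(fm) == 1L, ]
  expect_error(trainModel(single, grid = smallGrid()), "2 samples per class")
  # the committed 36-point grid is exercised end to end on a tiny fixture
  tiny <- plantedMatrix(n = 24, mNoise = 4, seed = 11)
  expect_identical(nrow(defaultGrid()), 36L)
  b3 <- trainModel(tiny, grid = defaultGrid()[c(1, 19, 36), ], nfolds = 2,
                   seed = 1)
  expect_s4_class(b3, "ModelBundle")
})

test_that("a planted signal is learned well above chance", {
  fm <- plantedMatrix(n = 120, mNoise = 20, seed = 12)
  sp <- splitTrainTest(fm, 0.25, seed = 12)
  b <- trainModel(sp$train, grid = smallGrid(), nfolds = 3, seed = 12)
  rep <- evaluateModel(b, sp$test)
  expect_gte(metricValues(rep)[["accuracy"]], 0.9)
  expect_gte(metricValues(rep)[["auc"]], 0.9)
  # prediction needs the bundle's features; a stripped matrix errors
  expect_error(evaluateModel(b, sp$test[, 2:10]), "schema mismatch")
})

test_that("SHAP attributions satisfy local accuracy and family bookkeeping", {
  fm <- plantedMatrix(n = 80, mNoise = 20, seed = 13)
  b <- trainModel(fm, grid = smallGrid(), nfolds = 3, seed = 13)
  sh <- explainModel(b, fm)
  # local accuracy: base + contributions reproduce the margin
  bst <- xgboost::xgb.load.raw(b@booster)
  marg <- predict(bst,
                  xgboost::xgb.DMatrix(featureValues(fm[, b@featureNames]),
                                       nthread = 1),
                  outputmargin = TRUE)
  # identity holds to float32 representation error on the margin scale
  expect_lt(max(abs(sh@baseValue + rowSums(sh@values) - marg)),
            1e-6 * max(1, max(abs(marg))))
  # the planted feature dominates
  expect_identical(sh@topFeatures[1], "aac_1")
  expect_gte(sh@meanAbs[["aac_1"]] / sum(sh@meanAbs), 0.8)
  # family sums conserve the grand total and map prefixes correctly
  expect_equal(sum(sh@familySums), sum(sh@meanAbs))
  expect_setequal(names(sh@familySums),
                  c("AAC", "DC", "PseAAC", "APseAAC", "CTD", "SS", "SOCN",
                    "QSO", "PSSM"))
  fake <- c(aac_1 = 0.2, dipep_3 = 0.1, dist_93 = 0.5)
  fams <- bacfindr:::featureDisplayFamily(names(fake))
  expect_identical(fams, c("AAC", "DC", "CTD"))
})

test_that("a model trained on one informative feature attributes to it", {
  set.seed(14)
  labels <- rep(c(1L, 0L), 40)
  v <- cbind(labels + rnorm(80, sd = 0.01), rnorm(80))
  rownames(v) <- sprintf("s%03d", 1:80)
  colnames(v) <- c("aac_1", "aac_2")
  fm <- FeatureMatrix(v, labels = labels)
  b <- trainModel(fm, selected = "aac_1", grid = smallGrid()[1, ],
                  nfolds = 2, seed = 1)
  sh <- explainModel(b, fm)
  expect_gte(sh@meanAbs[["aac_1"]] / sum(sh@meanAbs), 0.99)
})

test_that("model bundles round-trip through the JSON artifact", {
  fm <- plantedMatrix(n = 40, mNoise = 8, seed = 15)
  b <- trainModel(fm, grid = smallGrid()[1, ], nfolds = 2, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  writeModelBundle(b, path)
  b2 <- readModelBundle(path)
  expect_identical(b2@featureNames, b@featureNames)
  expect_equal(predictProb(b2, fm), predictProb(b, fm))
  # schema-version mismatch is an explicit error
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$schemaVersion <- "0.0"
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  expect_error(readModelBundle(path), "schema-version mismatch")
})
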