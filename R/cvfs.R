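## Cross-validated consensus feature selection (CVFS): repeatedly split the
## training data into c disjoint stratified parts, rank features by
## gradient-boosting gain within each part, intersect across parts, and
## keep features present in at least ceiling(p * e) of the e intersections.

## derive a reproducible 32-bit sub-seed for (seed, run)
runSeed <- function(seed, run) (abs(seed) %% 10000000L) * 200L + run

## stratified fold assignment: per class, shuffled round-robin; sizes per
## class differ by at most 1 across folds
stratifiedFolds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  set.seed(seed)
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Split a labeled feature matrix into c disjoint stratified parts
#'
#' Parts are disjoint, their union is the input, and per-class part sizes
#' differ by at most one (stratified by label).
#'
#' @param fm a labeled [FeatureMatrix-class].
#' @param c number of parts (>= 2).
#' @param seed integer seed; identical seeds give identical parts.
#' @return list of `c` [FeatureMatrix-class] parts.
#' @export
splitDisjoint <- function(fm, c = 2L, seed = 1L) {
  stopifnot(is(fm, "FeatureMatrix"), c >= 2)
  labels <- featureLabels(fm)
  if (is.null(labels)) stop("labels required for a stratified split")
  if (any(table(labels) < c))
    stop("too few samples per class for c = ", c, " parts")
  fold <- stratifiedFolds(labels, c, seed)
  lapply(seq_len(c), function(k) fm[fold == k, ])
}

#' Top-ranked features of one partition by boosted-tree gain
#'
#' Fits a gradient-boosted tree model on the part and returns every feature
#' with positive gain importance, ranked by descending gain with ties
#' broken by ascending schema index. This is the per-subset "top-ranked"
#' cut of the consensus selector: positive gain is parameter-free, so no
#' arbitrary top-k has to be chosen.
#'
#' @param part a labeled [FeatureMatrix-class] containing both classes.
#' @param xgbParams named list of xgboost parameters (merged over the
#'   defaults `max_depth = 5`, `eta = 0.3`, `subsample = 1`).
#' @param nrounds boosting rounds (default 100).
#' @param seed integer seed.
#' @return character vector of feature names (possibly empty).
#' @export
subsetTopFeatures <- function(part, xgbParams = list(), nrounds = 100L,
                              seed = 1L) {
  stopifnot(is(part, "FeatureMatrix"))
  labels <- featureLabels(part)
  if (is.null(labels) || length(unique(labels)) < 2)
    stop("partition must contain both classes")
  params <- utils::modifyList(
    list(objective = "binary:logistic", max_depth = 5, eta = 0.3,
         subsample = 1, nthread = 1, seed = as.integer(seed)),
    xgbParams)
  dtrain <- xgboost::xgb.DMatrix(featureValues(part), label = labels,
                                 nthread = 1)
  bst <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = nrounds, verbose = 0)
  imp <- xgboost::xgb.importance(model = bst)
  if (is.null(imp) || nrow(imp) == 0) return(character(0))
  feats <- imp$Feature[imp$Gain > 0]
  gains <- imp$Gain[imp$Gain > 0]
  idx <- match(feats, featureSchema(part)$name)
  feats[order(-gains, idx)]
}

#' Cross-validated consensus feature selection
#'
#' For each of `e` runs: split the data into `c` disjoint stratified parts
#' with a run-specific seed, take each part's positive-gain feature set
#' ([subsetTopFeatures()]), and intersect across the parts. A feature
#' enters the final selection if it appears in at least `ceiling(p * e)`
#' of the `e` intersection sets (i.e. in at least p x 100% of them).
#' Deterministic given `seed`.
#'
#' @param fm a labeled [FeatureMatrix-class] (training data).
#' @param c number of disjoint parts per run (default 2).
#' @param e number of repeated runs (default 5).
#' @param p consensus proportion in (0, 1] (default 0.4).
#' @param seed integer seed.
#' @inheritParams subsetTopFeatures
#' @return A [CVFSResult-class]; `selected` is in schema order.
#' @export
#' @seealso [selectHFE()] for the hypergraph-based alternative.
runCVFS <- function(fm, c = 2L, e = 5L, p = 0.4, seed = 1L,
                    xgbParams = list(), nrounds = 100L) {
  stopifnot(is(fm, "FeatureMatrix"), c >= 2, e >= 1, p > 0, p <= 1)
  schema <- featureSchema(fm)$name
  threshold <- as.integer(ceiling(p * e - 1e-9))
  inter <- vector("list", e)
  for (run in seq_len(e)) {
    rs <- runSeed(seed, run)
    parts <- splitDisjoint(fm, c = c, seed = rs)
    tops <- lapply(seq_along(parts), function(k)
      subsetTopFeatures(parts[[k]], xgbParams = xgbParams,
                        nrounds = nrounds, seed = rs + k))
    inter[[run]] <- Reduce(intersect, tops)
  }
  support <- table(unlist(inter))
  support <- stats::setNames(as.integer(support), names(support))
  selected <- names(support)[support >= threshold]
  selected <- selected[order(match(selected, schema))]
  new("CVFSResult", selected = selected, runIntersections = inter,
      supportCounts = support,
      config = list(c = as.integer(c), e = as.integer(e), p = p,
                    seed = as.integer(seed), threshold = threshold,
                    xgbParams = xgbParams, nrounds = as.integer(nrounds)))
}
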