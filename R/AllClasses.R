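#' @import methods
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' FeatureMatrix: a sample-by-feature descriptor table
#'
#' Central container of the package: an n x m numeric matrix of descriptor
#' values (samples in rows, features in columns), the ordered schema naming
#' each column and its family, optional 0/1 class labels (1 = bacteriocin),
#' and free-form metadata (descriptor parameters, fallback usage).
#'
#' Build one with [featurize()] or [readFeatureTable()]; subset features
#' with `[`, e.g. `fm[, selectedFeatures(sel)]`.
#'
#' @slot values numeric matrix, rownames are sample ids.
#' @slot schema data.frame with columns `name`, `family`, one row per column
#'   of `values`.
#' @slot labels integer vector of 0/1 labels (one per sample) or `NULL`.
#' @slot metadata list.
#'
#' @aliases FeatureMatrix-class
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(values = "matrix", schema = "data.frame",
                 labels = "integerOrNULL", metadata = "list"),
  prototype(values = matrix(numeric(0), 0, 0),
            schema = data.frame(name = character(0), family = character(0)),
            labels = NULL, metadata = list()))

setValidity("FeatureMatrix", function(object) {
  msg <- character(0)
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "'values' must be numeric")
  if (ncol(v) != nrow(object@schema))
    msg <- c(msg, "column count must equal schema length")
  if (!all(c("name", "family") %in% colnames(object@schema)))
    msg <- c(msg, "schema needs 'name' and 'family' columns")
  else if (anyDuplicated(object@schema$name))
    msg <- c(msg, "duplicated feature names in schema")
  if (anyNA(v)) msg <- c(msg, "missing values are not allowed")
  if (is.null(rownames(v)) && nrow(v) > 0)
    msg <- c(msg, "sample ids (rownames) required")
  if (anyDuplicated(rownames(v)))
    msg <- c(msg, "duplicated sample ids")
  if (!is.null(object@labels)) {
    if (length(object@labels) != nrow(v))
      msg <- c(msg, "labels length must equal sample count")
    else if (!all(object@labels %in% c(0L, 1L)))
      msg <- c(msg, "labels must be 0/1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureMatrix
#'
#' @param values numeric matrix (samples x features) with rownames.
#' @param schema data.frame with `name`/`family`, or `NULL` to resolve the
#'   colnames of `values` against the canonical schema.
#' @param labels optional integer/numeric 0/1 vector, one per sample.
#' @param metadata list of free-form metadata.
#' @return A [FeatureMatrix-class] object.
#' @export
FeatureMatrix <- function(values, schema = NULL, labels = NULL,
                          metadata = list()) {
  if (is.null(schema)) {
    canon <- featureSchemaTable()
    idx <- match(colnames(values), canon$name)
    if (anyNA(idx))
      stop("unknown feature name(s): ",
           paste(colnames(values)[is.na(idx)][1:min(3, sum(is.na(idx)))],
                 collapse = ", "))
    schema <- canon[idx, , drop = FALSE]
    rownames(schema) <- NULL
  }
  colnames(values) <- schema$name
  if (!is.null(labels)) labels <- as.integer(labels)
  new("FeatureMatrix", values = values, schema = schema, labels = labels,
      metadata = metadata)
}

#' PruneResult: outcome of Pearson correlation pruning
#'
#' @slot kept integer indices (into the input schema) of retained features.
#' @slot dropped data.frame with columns `dropped`, `partner`, `r`: for each
#'   discarded feature, the retained feature it correlated with at
#'   `|r| >= threshold` and that correlation.
#' @slot constant integer indices of zero-variance features (dropped,
#'   reported separately).
#' @slot threshold numeric pruning threshold.
#' @aliases PruneResult-class
#' @exportClass PruneResult
setClass("PruneResult",
  representation(kept = "integer", dropped = "data.frame",
                 constant = "integer", threshold = "numeric"))

setValidity("PruneResult", function(object) {
  all_idx <- sort(c(object@kept, object@dropped$dropped, object@constant))
  if (anyDuplicated(all_idx))
    return("kept, dropped and constant sets must be disjoint")
  TRUE
})

#' CVFSResult: cross-validated consensus feature selection
#'
#' @slot selected character vector of consensus feature names (schema order).
#' @slot runIntersections list of `e` character vectors: the across-partition
#'   intersection of each repeated run.
#' @slot supportCounts named integer: in how many of the `e` intersections
#'   each feature appeared (features with support >= 1).
#' @slot config list: `c`, `e`, `p`, `seed`, consensus `threshold`, xgboost
#'   settings.
#' @aliases CVFSResult-class
#' @exportClass CVFSResult
setClass("CVFSResult",
  representation(selected = "character", runIntersections = "list",
                 supportCounts = "integer", config = "list"))

#' HFEResult: hypergraph-based feature evaluation
#'
#' @slot scores named numeric: per-feature separation score S(f) in [0, 1].
#' @slot ranking character: all features by descending score (ties broken by
#'   ascending schema index).
#' @slot z integer: retained budget, round(beta * m) half away from zero.
#' @slot selected character: the top-z feature names.
#' @slot m integer: number of input features.
#' @slot config list: `bins`, `beta`, `seed`.
#' @aliases HFEResult-class
#' @exportClass HFEResult
setClass("HFEResult",
  representation(scores = "numeric", ranking = "character", z = "integer",
                 selected = "character", m = "integer", config = "list"))

setValidity("HFEResult", function(object) {
  msg <- character(0)
  if (length(object@selected) != object@z)
    msg <- c(msg, "length(selected) must equal z")
  if (!identical(object@selected, object@ranking[seq_len(object@z)]))
    msg <- c(msg, "selected must be the top-z of the ranking")
  if (length(msg)) msg else TRUE
})

#' Hypergraph over samples
#'
#' Vertices are samples; hyperedges are (feature, bin) groups of samples
#' sharing a discretized feature value, plus one hyperedge per class.
#'
#' @slot vertexIds character sample ids.
#' @slot labels integer 0/1 per vertex.
#' @slot edges list of integer vectors (vertex indices); no empty edge.
#' @slot edgeMeta data.frame with `type` ("bin"/"class"), `feature`, `bin`.
#' @slot edgeWeights,vertexWeights numeric (uniform 1 by default).
#' @aliases Hypergraph-class
#' @exportClass Hypergraph
setClass("Hypergraph",
  representation(vertexIds = "character", labels = "integer",
                 edges = "list", edgeMeta = "data.frame",
                 edgeWeights = "numeric", vertexWeights = "numeric"))

setValidity("Hypergraph", function(object) {
  msg <- character(0)
  if (length(object@edges) != nrow(object@edgeMeta))
    msg <- c(msg, "edgeMeta must describe every edge")
  if (any(lengths(object@edges) == 0))
    msg <- c(msg, "empty hyperedges are not allowed")
  if (length(object@labels) != length(object@vertexIds))
    msg <- c(msg, "one label per vertex required")
  if (length(msg)) msg else TRUE
})

#' MetricsReport: confusion counts and the derived metric suite
#'
#' @slot confusion named integer `TP`, `TN`, `FP`, `FN`.
#' @slot metrics named numeric `accuracy`, `precision`, `recall`, `f1`,
#'   `mcc`, and `auc` when scores were available (`NA` otherwise).
#' @slot degenerate character: names of metrics whose denominator was zero
#'   (reported as 0).
#' @aliases MetricsReport-class
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(confusion = "integer", metrics = "numeric",
                 degenerate = "character"))

setValidity("MetricsReport", function(object) {
  if (!all(c("TP", "TN", "FP", "FN") %in% names(object@confusion)))
    return("confusion must contain TP, TN, FP, FN")
  if (any(object@confusion < 0)) return("confusion counts must be >= 0")
  TRUE
})

#' ModelBundle: a trained gradient-boosted classifier with provenance
#'
#' @slot booster raw: portable xgboost serialization ([xgboost::xgb.save.raw]).
#' @slot featureNames character: the exact ordered feature subset the model
#'   requires at prediction time.
#' @slot bestParams list: winning hyperparameter configuration.
#' @slot searchInfo list: grid, fold count, per-configuration CV accuracy.
#' @slot seed integer.
#' @slot schemaVersion character.
#' @aliases ModelBundle-class
#' @exportClass ModelBundle
setClass("ModelBundle",
  representation(booster = "raw", featureNames = "character",
                 bestParams = "list", searchInfo = "list", seed = "integer",
                 schemaVersion = "character"))

#' ShapSummary: per-feature and per-family SHAP attribution
#'
#' @slot values numeric matrix of signed per-sample, per-feature SHAP values
#'   (margin scale).
#' @slot baseValue numeric: expected margin (the BIAS term).
#' @slot meanAbs named numeric: mean |SHAP| per feature, the importance used
#'   for ranking.
#' @slot topFeatures character: features by descending mean |SHAP|.
#' @slot familySums named numeric over the nine descriptor families (AAC,
#'   DC, PseAAC, APseAAC, CTD, SS, SOCN, QSO, PSSM); features pruned away
#'   contribute 0.
#' @aliases ShapSummary-class
#' @exportClass ShapSummary
setClass("ShapSummary",
  representation(values = "matrix", baseValue = "numeric",
                 meanAbs = "numeric", topFeatures = "character",
                 familySums = "numeric"))

setValidity("ShapSummary", function(object) {
  fams <- c("AAC", "DC", "PseAAC", "APseAAC", "CTD", "SS", "SOCN", "QSO",
            "PSSM")
  if (!identical(sort(names(object@familySums)), sort(fams)))
    return("familySums must cover exactly the nine descriptor families")
  TRUE
})
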