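#' @rdname FeatureMatrix-class
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureSchema", "FeatureMatrix", function(x) x@schema)

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureLabels", "FeatureMatrix", function(x) x@labels)

#' @rdname FeatureMatrix-class
#' @export
setMethod("sampleIds", "FeatureMatrix", function(x) rownames(x@values))

#' @rdname FeatureMatrix-class
#' @export
setMethod("dim", "FeatureMatrix", function(x) dim(x@values))

#' @rdname FeatureMatrix-class
#' @param i,j sample / feature subscripts (ids, names, or indices)
#' @param drop ignored
#' @param ... ignored
#' @export
setMethod("[", "FeatureMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  if (is.character(j)) {
    jj <- match(j, x@schema$name)
    if (anyNA(jj)) stop("unknown feature name(s): ",
                        paste(j[is.na(jj)], collapse = ", "))
    j <- jj
  }
  if (is.character(i)) {
    ii <- match(i, rownames(x@values))
    if (anyNA(ii)) stop("unknown sample id(s)")
    i <- ii
  }
  idx <- seq_len(nrow(x@values))[i]
  new("FeatureMatrix",
      values = x@values[i, j, drop = FALSE],
      schema = x@schema[j, , drop = FALSE],
      labels = if (is.null(x@labels)) NULL else x@labels[idx],
      metadata = x@metadata)
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", nrow(object@values), "samples x",
      ncol(object@values), "features\n")
  fam <- table(factor(object@schema$family,
                      levels = unique(object@schema$family)))
  cat("  families:",
      paste(names(fam), fam, sep = "=", collapse = " "), "\n")
  if (!is.null(object@labels))
    cat("  labels: ", sum(object@labels == 1L), " positive / ",
        sum(object@labels == 0L), " negative\n", sep = "")
})

#' @rdname PruneResult-class
#' @param object a `PruneResult`
setMethod("show", "PruneResult", function(object) {
  cat("PruneResult (|r| >=", object@threshold, "):",
      length(object@kept), "kept,", nrow(object@dropped),
      "dropped by correlation,", length(object@constant),
      "constant\n")
})

#' @rdname CVFSResult-class
#' @export
setMethod("selectedFeatures", "CVFSResult", function(x) x@selected)

setMethod("show", "CVFSResult", function(object) {
  cfg <- object@config
  cat("CVFSResult (c=", cfg$c, ", e=", cfg$e, ", p=", cfg$p,
      "): ", length(object@selected), " features selected (support >= ",
      cfg$threshold, " of ", cfg$e, " runs)\n", sep = "")
})

#' @rdname HFEResult-class
#' @export
setMethod("selectedFeatures", "HFEResult", function(x) x@selected)

#' @rdname HFEResult-class
#' @export
setMethod("featureScores", "HFEResult", function(x) x@scores)

setMethod("show", "HFEResult", function(object) {
  cfg <- object@config
  cat("HFEResult (bins=", cfg$bins, ", beta=", cfg$beta, "): retained z=",
      object@z, " of m=", object@m, " features\n", sep = "")
})

setMethod("show", "Hypergraph", function(object) {
  cat("Hypergraph:", length(object@vertexIds), "vertices,",
      sum(object@edgeMeta$type == "bin"), "bin hyperedges +",
      sum(object@edgeMeta$type == "class"), "class hyperedges\n")
})

setMethod("show", "MetricsReport", function(object) {
  cm <- object@confusion
  cat("MetricsReport  TP=", cm["TP"], " TN=", cm["TN"], " FP=", cm["FP"],
      " FN=", cm["FN"], "\n", sep = "")
  m <- object@metrics
  cat(paste(sprintf("  %s=%.4f", names(m), m), collapse = ""), "\n")
  if (length(object@degenerate))
    cat("  degenerate (reported as 0):",
        paste(object@degenerate, collapse = ", "), "\n")
})

setMethod("show", "ModelBundle", function(object) {
  cat("ModelBundle:", length(object@featureNames), "features, schema",
      object@schemaVersion, "\n")
  bp <- object@bestParams
  cat("  best:", paste(names(bp), unlist(bp), sep = "=", collapse = " "),
      "\n")
})

setMethod("show", "ShapSummary", function(object) {
  cat("ShapSummary over", ncol(object@values), "features,",
      nrow(object@values), "samples\n")
  k <- min(5L, length(object@topFeatures))
  cat("  top:", paste(object@topFeatures[seq_len(k)], collapse = ", "),
      "\n")
  fs <- sort(object@familySums, decreasing = TRUE)
  cat("  family sums:",
      paste(names(fs), signif(fs, 3), sep = "=", collapse = " "), "\n")
})

#' Confusion counts and metric values of a report
#' @param report a [MetricsReport-class]
#' @return `metricValues`: named numeric; `confusionCounts`: named integer.
#' @export
metricValues <- function(report) report@metrics

#' @rdname metricValues
#' @export
confusionCounts <- function(report) report@confusion
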