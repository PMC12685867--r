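## Hypergraph-based feature evaluation (HFE): discretize each feature into
## uniform bins, view every non-empty (feature, bin) group of samples as a
## hyperedge (plus one hyperedge per class), rate each bin edge by how a
## lazy random walk entering it splits across the classes, aggregate the
## per-bin separation ratings into a per-feature score, and keep the top
## z = round(beta * m) features.

#' Discretize features into uniform bins
#'
#' Per feature: `bins` uniform-width intervals over the training range
#' `[min, max]`, left-closed / right-open with the final bin closed; a
#' value lying exactly on an interior boundary joins the upper bin.
#' Constant features occupy a single bin. Values outside the range (e.g.
#' test-time data binned against a training range) clamp to the edge bins.
#'
#' @param fm a [FeatureMatrix-class].
#' @param bins number of bins per feature (>= 2).
#' @param range optional 2 x m matrix of (min, max) per feature; defaults
#'   to the observed range.
#' @return integer n x m matrix of bin assignments in 1..bins.
#' @export
discretizeFeatures <- function(fm, bins = 10L, range = NULL) {
  stopifnot(is(fm, "FeatureMatrix"), bins >= 2)
  X <- featureValues(fm)
  if (is.null(range))
    range <- rbind(apply(X, 2, min), apply(X, 2, max))
  lo <- range[1, ]; hi <- range[2, ]
  width <- (hi - lo) / bins
  B <- matrix(1L, nrow(X), ncol(X), dimnames = dimnames(X))
  ok <- which(width > 0)
  for (j in ok) {
    b <- floor((X[, j] - lo[j]) / width[j]) + 1
    B[, j] <- as.integer(pmin(pmax(b, 1), bins))
  }
  B
}

#' Build the sample hypergraph
#'
#' Vertices are samples. For every feature and every non-empty bin of its
#' discretization, a hyperedge connects the samples falling in that bin;
#' two additional hyperedges hold the positive and negative class members.
#' Every vertex therefore lies in exactly one bin edge per feature and
#' exactly one class edge. Edge and vertex weights are uniform.
#'
#' @inheritParams discretizeFeatures
#' @return A [Hypergraph-class].
#' @export
buildHypergraph <- function(fm, bins = 10L) {
  labels <- featureLabels(fm)
  if (is.null(labels)) stop("labels required to build the class hyperedges")
  B <- discretizeFeatures(fm, bins = bins)
  fnames <- featureSchema(fm)$name
  edges <- list(); feat <- character(0); bin <- integer(0)
  for (j in seq_len(ncol(B))) {
    for (b in sort(unique(B[, j]))) {
      edges[[length(edges) + 1L]] <- which(B[, j] == b)
      feat <- c(feat, fnames[j]); bin <- c(bin, b)
    }
  }
  n_bin <- length(edges)
  for (cls in c(1L, 0L)) {
    members <- which(labels == cls)
    if (length(members)) {
      edges[[length(edges) + 1L]] <- members
      feat <- c(feat, if (cls == 1L) ".class_pos" else ".class_neg")
      bin <- c(bin, NA_integer_)
    }
  }
  meta <- data.frame(
    type = rep(c("bin", "class"), c(n_bin, length(edges) - n_bin)),
    feature = feat, bin = bin, stringsAsFactors = FALSE)
  new("Hypergraph", vertexIds = sampleIds(fm), labels = labels,
      edges = edges, edgeMeta = meta,
      edgeWeights = rep(1, length(edges)),
      vertexWeights = rep(1, length(labels)))
}

#' Rate one hyperedge by lazy-walk class retention
#'
#' With uniform vertex weights, a single non-lazy step of the walk that
#' enters a hyperedge lands on each member vertex with equal probability,
#' so it lands in the minority class with probability n_min / n and in the
#' majority class with n_maj / n. The ratings are R1 = n_min / n (minority
#' retention), R2 = n_maj / n (majority retention) and R0 =
#' |n_pos - n_neg| / n (class separation); R1 + R2 = 1 and R0 = R2 - R1.
#' Minority / majority are designated from the overall training class
#' sizes; on a tie the positive class is the minority.
#'
#' @param nPos,nNeg class member counts inside the edge.
#' @param classTotals named vector with overall `pos` / `neg` training
#'   counts (designates the minority class).
#' @return named numeric: `R1`, `R2`, `R0`, `n`.
#' @export
rateHyperedge <- function(nPos, nNeg, classTotals) {
  n <- nPos + nNeg
  if (n == 0) stop("empty hyperedge cannot be rated")
  minority_pos <- classTotals[["pos"]] <= classTotals[["neg"]]
  nMin <- if (minority_pos) nPos else nNeg
  nMaj <- n - nMin
  c(R1 = nMin / n, R2 = nMaj / n, R0 = abs(nPos - nNeg) / n, n = n)
}

#' Ratings of all bin hyperedges
#'
#' @param hg a [Hypergraph-class].
#' @return data.frame with one row per bin edge: `feature`, `bin`, `nPos`,
#'   `nNeg`, `R1`, `R2`, `R0`, `n`.
#' @export
hyperedgeRatings <- function(hg) {
  stopifnot(is(hg, "Hypergraph"))
  totals <- c(pos = sum(hg@labels == 1L), neg = sum(hg@labels == 0L))
  keep <- which(hg@edgeMeta$type == "bin")
  out <- lapply(keep, function(i) {
    members <- hg@edges[[i]]
    nPos <- sum(hg@labels[members] == 1L)
    rateHyperedge(nPos, length(members) - nPos, totals)
  })
  r <- as.data.frame(do.call(rbind, out))
  cbind(hg@edgeMeta[keep, c("feature", "bin")],
        nPos = vapply(keep, function(i) sum(hg@labels[hg@edges[[i]]] == 1L),
                      numeric(1)),
        nNeg = vapply(keep, function(i) sum(hg@labels[hg@edges[[i]]] == 0L),
                      numeric(1)),
        r, row.names = NULL)
}

#' Aggregate bin ratings into per-feature scores
#'
#' S(f) = sum over f's bins of (n_bin / N) * R0(bin): the sample-weighted
#' mean class separation of the feature's bins. S lies in [0, 1]; a feature
#' whose bins are all class-pure scores 1, a constant feature on balanced
#' data scores 0. Invariant to sample order and to duplicating all samples.
#'
#' @param hg a [Hypergraph-class].
#' @param ratings output of [hyperedgeRatings()] (recomputed if missing).
#' @return named numeric vector of scores, one per feature, in the order
#'   the features appear in the hypergraph.
#' @export
scoreFeatures <- function(hg, ratings = hyperedgeRatings(hg)) {
  N <- length(hg@vertexIds)
  contrib <- (ratings$n / N) * ratings$R0
  s <- tapply(contrib, ratings$feature, sum)
  feats <- unique(hg@edgeMeta$feature[hg@edgeMeta$type == "bin"])
  stats::setNames(as.numeric(s[feats]), feats)
}

#' Hypergraph-based feature selection
#'
#' Full pipeline: discretize, build the hypergraph, rate every bin edge,
#' score and rank the features (descending score, ties broken by ascending
#' schema index), and retain the top z = round(beta * m) (half away from
#' zero), where m is the input feature count.
#'
#' @param fm a labeled [FeatureMatrix-class] (training data).
#' @param bins bins per feature, typically 5 or 10.
#' @param beta retained proportion in (0, 1].
#' @return An [HFEResult-class].
#' @export
#' @seealso [runCVFS()] for the cross-validated consensus alternative.
#' @examples
#' ## a feature identical to the label scores 1 and is always retained
selectHFE <- function(fm, bins = 10L, beta = 0.3) {
  stopifnot(is(fm, "FeatureMatrix"), beta > 0, beta <= 1)
  m <- ncol(featureValues(fm))
  if (m < 1) stop("empty feature matrix")
  hg <- buildHypergraph(fm, bins = bins)
  scores <- scoreFeatures(hg)
  schema <- featureSchema(fm)$name
  scores <- scores[schema]               # schema order
  ord <- order(-scores, seq_len(m))
  ranking <- schema[ord]
  z <- as.integer(roundHalfUp(beta * m))
  new("HFEResult", scores = scores, ranking = ranking, z = z,
      selected = ranking[seq_len(z)], m = as.integer(m),
      config = list(bins = as.integer(bins), beta = beta))
}

#' Retained-feature budget of the hypergraph selector
#'
#' z = round(beta * m), rounding half away from zero; e.g. m = 602 gives
#' z = 90, 181, 301 at beta = 0.15, 0.30, 0.50.
#'
#' @param beta retained proportion in (0, 1].
#' @param m total feature count.
#' @return integer budget.
#' @export
hfeBudget <- function(beta, m) {
  stopifnot(beta > 0, beta <= 1, m >= 1)
  as.integer(roundHalfUp(beta * m))
}
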