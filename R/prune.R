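#' Greedy Pearson correlation pruning
#'
#' Scans features in schema order and drops feature j if it correlates at
#' `|r| >= threshold` (inclusive) with any already-kept feature i < j, so
#' the earlier schema index always wins. Must be run on training rows only
#' so no information leaks from a test split. Zero-variance (constant)
#' features, for which Pearson r is undefined, are dropped and reported
#' separately. After pruning, no retained pair correlates at or above the
#' threshold.
#'
#' @param fm a [FeatureMatrix-class] (training samples only).
#' @param threshold correlation cutoff in (0, 1], default 0.9.
#' @return A [PruneResult-class]; apply it with [applyPrune()].
#' @export
pearsonPrune <- function(fm, threshold = 0.9) {
  stopifnot(is(fm, "FeatureMatrix"))
  X <- featureValues(fm)
  if (nrow(X) < 3) stop("need at least 3 samples to estimate correlations")
  if (ncol(X) == 0) stop("empty feature matrix")
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  sds <- apply(X, 2, stats::sd)
  constant <- which(sds == 0)
  live <- setdiff(seq_len(ncol(X)), constant)
  kept <- integer(0)
  drop_idx <- integer(0); drop_partner <- integer(0); drop_r <- numeric(0)
  if (length(live)) {
    C <- suppressWarnings(stats::cor(X[, live, drop = FALSE]))
    for (jj in seq_along(live)) {
      if (!length(kept)) { kept <- live[jj]; next }
      kk <- match(kept, live)
      r <- C[kk, jj]
      hit <- which(abs(r) >= threshold)
      if (length(hit)) {
        drop_idx <- c(drop_idx, live[jj])
        drop_partner <- c(drop_partner, kept[hit[1]])
        drop_r <- c(drop_r, r[hit[1]])
      } else {
        kept <- c(kept, live[jj])
      }
    }
  }
  new("PruneResult", kept = kept,
      dropped = data.frame(dropped = drop_idx, partner = drop_partner,
                           r = drop_r),
      constant = as.integer(constant), threshold = threshold)
}

#' Apply a prune result to a feature matrix
#'
#' @param fm a [FeatureMatrix-class] whose schema matches the one pruned
#'   (training or test split).
#' @param prune a [PruneResult-class] from [pearsonPrune()].
#' @return the [FeatureMatrix-class] restricted to the kept features.
#' @export
applyPrune <- function(fm, prune) {
  stopifnot(is(fm, "FeatureMatrix"), is(prune, "PruneResult"))
  fm[, prune@kept]
}
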