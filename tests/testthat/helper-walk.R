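# Monte-Carlo lazy random walk over a Hypergraph: at each step stay with
# probability alpha, otherwise pick an incident hyperedge proportionally
# to its weight and land on a member vertex proportionally to its vertex
# weight. Returns, for the requested edge, the empirical class frequencies
# of landings made through that edge — the independent oracle for the
# closed-form hyperedge ratings.
lazyWalkEdgeLandings <- function(hg, edgeIndex, steps = 1e5, alpha = 0.5,
                                 seed = 1) {
  set.seed(seed)
  nV <- length(hg@vertexIds)
  incident <- lapply(seq_len(nV), function(v)
    which(vapply(hg@edges, function(e) v %in% e, logical(1))))
  w <- hg@edgeWeights
  gv <- hg@vertexWeights
  cur <- sample.int(nV, 1)
  landPos <- 0L; landNeg <- 0L
  for (s in seq_len(steps)) {
    if (runif(1) < alpha) next
    inc <- incident[[cur]]
    e <- if (length(inc) == 1) inc else sample(inc, 1, prob = w[inc])
    members <- hg@edges[[e]]
    cur <- if (length(members) == 1) members
           else sample(members, 1, prob = gv[members])
    if (e == edgeIndex) {
      if (hg@labels[cur] == 1L) landPos <- landPos + 1L
      else landNeg <- landNeg + 1L
    }
  }
  c(pos = landPos, neg = landNeg)
}
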