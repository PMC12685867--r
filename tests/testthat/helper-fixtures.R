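# shared fixtures, all generated in code

# random FeatureMatrix over the first m canonical feature names
canonicalSubsetMatrix <- function(n, m, seed = 1, labels = NULL) {
  set.seed(seed)
  v <- matrix(rnorm(n * m), n, m)
  rownames(v) <- sprintf("s%03d", seq_len(n))
  colnames(v) <- featureSchemaTable()$name[seq_len(m)]
  FeatureMatrix(v, labels = labels)
}

# planted-signal matrix: feature 1 tracks the label, the rest are noise
plantedMatrix <- function(n = 60, mNoise = 50, seed = 1, flip = 0.02) {
  set.seed(seed)
  labels <- rep(c(1L, 0L), length.out = n)
  v <- matrix(rnorm(n * (mNoise + 1)), n, mNoise + 1)
  v[, 1] <- labels + rnorm(n, sd = 0.05)
  rownames(v) <- sprintf("s%03d", seq_len(n))
  colnames(v) <- featureSchemaTable()$name[seq_len(mNoise + 1)]
  FeatureMatrix(v, labels = labels)
}

# emit a PSI-BLAST-style ASCII PSSM for a score matrix whose columns are
# in 'colOrder'; includes header, row ids, paired percentage columns and a
# footer, like `psiblast -out_ascii_pssm` output
writePSSMFixture <- function(path, scores, residues, colOrder) {
  stopifnot(ncol(scores) == 20, length(residues) == nrow(scores))
  lines <- c("", "Last position-specific scoring matrix computed",
             paste(" ", paste(c(colOrder, colOrder), collapse = "  ")))
  for (i in seq_len(nrow(scores)))
    lines <- c(lines, paste(c(i, residues[i], scores[i, ],
                              rep(0, 20), "0.50", "0.10"), collapse = "  "))
  lines <- c(lines, "", "                      K         Lambda")
  writeLines(lines, path)
  path
}

# random sequence of length L over the standard alphabet
randomSeq <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabetOrder(), L, replace = TRUE), collapse = "")
}

# memoised featurized default synthetic panel (shared across test files)
.panelCache <- new.env(parent = emptyenv())
syntheticPanel <- function(seed) {
  key <- paste0("seed", seed)
  if (is.null(.panelCache[[key]])) {
    sim <- generateSequences(synthConfig(), seed = seed)
    .panelCache[[key]] <- featurize(sim$sequences, labels = sim$labels)
  }
  .panelCache[[key]]
}

# features that directly carry the generator's planted compositional
# signal: composition of C (depleted) and L/I/V/F (enriched) in the
# composition-type families, plus the CTD hydrophobicity-group fractions
plantedFamilyFeatures <- function() {
  resid_idx <- c(5, 10, 11, 14, 20)            # C, I, L, F, V
  c(paste0("aac_", resid_idx), paste0("pseudo_", resid_idx),
    paste0("qso_", resid_idx), paste0("comp_", 1:3))
}
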