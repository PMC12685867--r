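## Nine descriptor families totalling exactly 1,103 features per sequence:
## AAC(20) + DC(400) + PseAAC(30) + APseAAC(40) + CTD(21+21+105) + SS(6) +
## SOCN(20) + QSO(40) + PSSM-transition(400).

#' Descriptor parameters
#'
#' Lags and weights of the sequence-order descriptor families. The lags are
#' fixed by the schema dimensionalities (PseAAC = 20 + lambda, APseAAC =
#' 20 + 2*lambda, QSO = 20 + maxlag) and should not normally be changed;
#' the weights follow the conventional defaults of the pseudo-composition
#' and quasi-sequence-order literature.
#'
#' @param lambdaPaac PseAAC correlation lag (default 10).
#' @param lambdaApaac APseAAC correlation lag (default 10).
#' @param wPaac,wApaac pseudo-composition weights (default 0.05).
#' @param maxlagSo SOCN/QSO maximum lag (default 20).
#' @param wQso quasi-sequence-order weight (default 0.1).
#' @return list of parameters.
#' @export
descriptorParams <- function(lambdaPaac = 10L, lambdaApaac = 10L,
                             wPaac = 0.05, wApaac = 0.05,
                             maxlagSo = 20L, wQso = 0.1) {
  stopifnot(lambdaPaac >= 1, lambdaApaac >= 1, maxlagSo >= 1,
            wPaac >= 0, wApaac >= 0, wQso >= 0)
  list(lambdaPaac = as.integer(lambdaPaac),
       lambdaApaac = as.integer(lambdaApaac),
       wPaac = wPaac, wApaac = wApaac,
       maxlagSo = as.integer(maxlagSo), wQso = wQso)
}

## residue string -> integer codes in AA_ORDER; errors on invalid residues
seqCodes <- function(x) {
  if (is(x, "AAString") || is(x, "AAStringSet")) x <- as.character(x)
  stopifnot(is.character(x), length(x) == 1)
  codes <- match(strsplit(x, "")[[1]], AA_ORDER)
  if (length(codes) == 0) stop("empty sequence")
  if (anyNA(codes))
    stop("invalid residue '", strsplit(x, "")[[1]][which(is.na(codes))[1]],
         "' at position ", which(is.na(codes))[1])
  codes
}

#' Amino-acid composition (AAC)
#'
#' Fraction of each of the 20 residues, in [alphabetOrder()]; sums to 1.
#'
#' @param x a protein sequence (single string or `AAString`).
#' @return named numeric vector `aac_1` .. `aac_20`.
#' @export
#' @examples
#' extractAAC("CCCCG")["aac_5"]  # cysteine fraction 0.8
extractAAC <- function(x) {
  codes <- seqCodes(x)
  v <- tabulate(codes, nbins = 20) / length(codes)
  names(v) <- paste0("aac_", 1:20)
  v
}

#' Dipeptide composition (DC)
#'
#' Frequency of each adjacent residue pair (a, b), row-major in
#' [alphabetOrder()] (pair (a, b) has index (a-1)*20 + b), divided by L - 1;
#' sums to 1.
#'
#' @inheritParams extractAAC
#' @return named numeric vector `dipep_1` .. `dipep_400`.
#' @export
extractDC <- function(x) {
  codes <- seqCodes(x)
  L <- length(codes)
  if (L < 2) stop("sequence too short for dipeptide composition (L >= 2)")
  idx <- (codes[-L] - 1L) * 20L + codes[-1L]
  v <- tabulate(idx, nbins = 400) / (L - 1)
  names(v) <- paste0("dipep_", 1:400)
  v
}

## standardized scale matrix: 20 x 3 (hydrophobicity, hydrophilicity, mass)
paacScales <- function() {
  cbind(h1 = standardizeScale(AA_HYDROPHOBICITY),
        h2 = standardizeScale(AA_HYDROPHILICITY),
        h3 = standardizeScale(AA_SIDECHAIN_MASS))
}

## mean squared scale difference between residue codes a and b (Theta)
thetaCorrelation <- function(a, b, scales) {
  rowMeans((scales[a, , drop = FALSE] - scales[b, , drop = FALSE])^2)
}

#' Pseudo amino-acid composition (type 1)
#'
#' The 20 composition components augmented with `lambda` sequence-order
#' correlation factors tau_j, where tau_j averages, over positions j apart,
#' the mean squared difference of the three standardized physicochemical
#' scales (hydrophobicity, hydrophilicity, side-chain mass). Components:
#' first 20 are f_r / (1 + w * sum(tau)), the tail is w * tau_j /
#' (1 + w * sum(tau)); all 20 + lambda components sum to 1.
#'
#' @inheritParams extractAAC
#' @param params see [descriptorParams()].
#' @return named numeric vector `pseudo_1` .. `pseudo_30` (for lambda = 10).
#' @export
extractPAAC <- function(x, params = descriptorParams()) {
  codes <- seqCodes(x)
  L <- length(codes)
  lambda <- params$lambdaPaac
  if (L <= lambda)
    stop("sequence length ", L, " must exceed the PseAAC lag ", lambda)
  scales <- paacScales()
  tau <- vapply(seq_len(lambda), function(j)
    mean(thetaCorrelation(codes[1:(L - j)], codes[(1 + j):L], scales)),
    numeric(1))
  f <- tabulate(codes, nbins = 20) / L
  denom <- 1 + params$wPaac * sum(tau)
  v <- c(f / denom, params$wPaac * tau / denom)
  names(v) <- paste0("pseudo_", seq_along(v))
  v
}

#' Amphiphilic pseudo amino-acid composition (type 2)
#'
#' As [extractPAAC()] but with 2 * lambda correlation factors that
#' alternate hydrophobicity- and hydrophilicity-based terms: for each lag j,
#' tau(2j-1) averages the squared difference of the standardized
#' hydrophobicity and tau(2j) of the standardized hydrophilicity between
#' residues j apart. Squared-difference (not product) correlation terms keep
#' every component non-negative and make the tail vanish for homopolymers,
#' so the 40 components always form a unit-sum vector.
#'
#' @inheritParams extractPAAC
#' @return named numeric vector `amphipseudo_1` .. `amphipseudo_40`.
#' @export
extractAPAAC <- function(x, params = descriptorParams()) {
  codes <- seqCodes(x)
  L <- length(codes)
  lambda <- params$lambdaApaac
  if (L <= lambda)
    stop("sequence length ", L, " must exceed the APseAAC lag ", lambda)
  scales <- paacScales()
  tau <- numeric(2 * lambda)
  for (j in seq_len(lambda)) {
    a <- codes[1:(L - j)]; b <- codes[(1 + j):L]
    tau[2 * j - 1] <- mean((scales[a, "h1"] - scales[b, "h1"])^2)
    tau[2 * j]     <- mean((scales[a, "h2"] - scales[b, "h2"])^2)
  }
  f <- tabulate(codes, nbins = 20) / L
  denom <- 1 + params$wApaac * sum(tau)
  v <- c(f / denom, params$wApaac * tau / denom)
  names(v) <- paste0("amphipseudo_", seq_along(v))
  v
}

#' Composition / transition / distribution (CTD) descriptors
#'
#' Seven physicochemical properties (hydrophobicity, normalized van der
#' Waals volume, polarity, polarizability, charge, secondary structure,
#' solvent accessibility — in that order) each partition the residues into
#' three groups. Per property: 3 composition features (group fraction),
#' 3 transition features (adjacent inter-group pair rate over L - 1, for
#' group pairs (1,2), (1,3), (2,3)), and 15 distribution features (for each
#' group, the sequence position — as a percentage of L — of its first,
#' 25%, 50%, 75% and 100% occurrence, where the q-quantile occurrence is
#' the ceiling(q * k)-th of the group's k occurrences). A group absent from
#' the sequence contributes zeros. Ordering is property-major, then group,
#' then quantile; `dist_93` is therefore the 50% quantile of solvent-
#' accessibility group 1 (buried residues).
#'
#' @inheritParams extractAAC
#' @return named numeric vector of 147 values: `comp_1..21`, `tran_1..21`,
#'   `dist_1..105`.
#' @export
extractCTD <- function(x) {
  codes <- seqCodes(x)
  L <- length(codes)
  if (L < 2) stop("sequence too short for CTD (L >= 2)")
  comp <- numeric(0); tran <- numeric(0); dist <- numeric(0)
  for (prop in CTD_GROUPS) {
    grp <- integer(20)
    for (g in 1:3) grp[match(prop[[g]], AA_ORDER)] <- g
    gseq <- grp[codes]
    comp <- c(comp, tabulate(gseq, nbins = 3) / L)
    pairs <- cbind(gseq[-L], gseq[-1])
    tran <- c(tran, vapply(list(c(1, 2), c(1, 3), c(2, 3)), function(gh)
      sum((pairs[, 1] == gh[1] & pairs[, 2] == gh[2]) |
          (pairs[, 1] == gh[2] & pairs[, 2] == gh[1])) / (L - 1),
      numeric(1)))
    for (g in 1:3) {
      pos <- which(gseq == g)
      k <- length(pos)
      if (k == 0) { dist <- c(dist, numeric(5)); next }
      picks <- pmax(1L, ceiling(c(1 / k, 0.25, 0.5, 0.75, 1) * k))
      picks[1] <- 1L
      dist <- c(dist, 100 * pos[picks] / L)
    }
  }
  v <- c(comp, tran, dist)
  names(v) <- c(paste0("comp_", 1:21), paste0("tran_", 1:21),
                paste0("dist_", 1:105))
  v
}

#' Propensity-based secondary-structure fallback
#'
#' Assigns a state in `{H, E, C}` to every residue as the argmax of
#' Chou-Fasman-style helix/strand/coil propensities averaged over a
#' centered window of 5 (truncated at the termini); ties resolve in the
#' order H, E, C. Used by [extractSS()] when no external prediction is
#' supplied; an ingested `.ss2` profile always takes precedence.
#'
#' @inheritParams extractAAC
#' @param window smoothing window (odd, default 5).
#' @return a string over `{H, E, C}` of the same length as `x`.
#' @export
predictSSPropensity <- function(x, window = 5L) {
  codes <- seqCodes(x)
  L <- length(codes)
  half <- (window - 1L) %/% 2L
  prop <- CHOU_FASMAN[codes, , drop = FALSE]
  sm <- sapply(1:3, function(s) {
    cs <- cumsum(c(0, prop[, s]))
    lo <- pmax(1L, seq_len(L) - half); hi <- pmin(L, seq_len(L) + half)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  states <- c("H", "E", "C")[apply(sm, 1, which.max)]
  paste(states, collapse = "")
}

#' Secondary-structure summary descriptors
#'
#' Six features from a per-residue state string over `{H, E, C}`: the
#' fractions of helix, strand and coil states, and the longest run of each
#' state divided by L. If no state string is given the internal propensity
#' fallback ([predictSSPropensity()]) predicts one first.
#'
#' @inheritParams extractAAC
#' @param ss optional state string over `{H, E, C}`, same length as `x`.
#' @return named numeric vector `ss_1` .. `ss_6`.
#' @export
extractSS <- function(x, ss = NULL) {
  codes <- seqCodes(x)
  L <- length(codes)
  if (is.null(ss)) ss <- predictSSPropensity(x)
  st <- strsplit(ss, "")[[1]]
  if (length(st) != L)
    stop("secondary-structure length ", length(st),
         " does not match sequence length ", L)
  if (!all(st %in% c("H", "E", "C")))
    stop("secondary-structure states must be in {H, E, C}")
  r <- rle(st)
  v <- c(vapply(c("H", "E", "C"), function(s) mean(st == s), numeric(1)),
         vapply(c("H", "E", "C"), function(s) {
           runs <- r$lengths[r$values == s]
           if (length(runs)) max(runs) / L else 0
         }, numeric(1)))
  names(v) <- paste0("ss_", 1:6)
  v
}

#' Sequence-order coupling numbers (SOCN)
#'
#' For each lag d = 1 .. maxlag, the sum over positions of the squared
#' physicochemical distance ([aaDistanceMatrix()]) between residues d
#' apart: tau_d = sum_i dist(R_i, R_(i+d))^2.
#'
#' @inheritParams extractPAAC
#' @return named numeric vector `socn_1` .. `socn_20`.
#' @export
extractSOCN <- function(x, params = descriptorParams()) {
  codes <- seqCodes(x)
  L <- length(codes)
  maxlag <- params$maxlagSo
  if (L <= maxlag)
    stop("sequence length ", L, " must exceed the SOCN/QSO maximum lag ",
         maxlag, " (minimum length ", maxlag + 1, ")")
  D2 <- aaDistanceMatrix()^2
  v <- vapply(seq_len(maxlag), function(d)
    sum(D2[cbind(codes[1:(L - d)], codes[(1 + d):L])]), numeric(1))
  names(v) <- paste0("socn_", seq_len(maxlag))
  v
}

#' Quasi-sequence-order descriptors (QSO)
#'
#' Combines residue frequencies with the coupling numbers of
#' [extractSOCN()]: first 20 components f_r / (1 + w * sum(tau)), last
#' `maxlag` components w * tau_d / (1 + w * sum(tau)); all 40 components
#' are non-negative and sum to 1.
#'
#' @inheritParams extractPAAC
#' @return named numeric vector `qso_1` .. `qso_40`.
#' @export
extractQSO <- function(x, params = descriptorParams()) {
  tau <- unname(extractSOCN(x, params))
  f <- tabulate(seqCodes(x), nbins = 20) / length(seqCodes(x))
  denom <- 1 + params$wQso * sum(tau)
  v <- c(f / denom, params$wQso * tau / denom)
  names(v) <- paste0("qso_", seq_along(v))
  v
}

#' PSSM transition descriptors
#'
#' Squashes the per-position log-odds scores with the logistic function
#' sigma(s) = 1 / (1 + exp(-s)) and, for every ordered residue pair (a, b),
#' averages the product sigma(S[i, a]) * sigma(S[i+1, b]) over adjacent
#' positions: feature (a, b) = (1 / (L - 1)) * sum_i sigma(S[i, a]) *
#' sigma(S[i+1, b]), row-major in [alphabetOrder()]. When no profile is
#' supplied a pseudo-profile S[i, a] = BLOSUM62(residue_i, a) is used so
#' the full schema stays computable without an external profile search;
#' callers can see whether the fallback was used in the metadata of
#' [featurize()].
#'
#' @inheritParams extractAAC
#' @param profile optional L x 20 score matrix (e.g. from [readPSSM()]),
#'   columns in [alphabetOrder()].
#' @return named numeric vector `pssm_1` .. `pssm_400`.
#' @export
extractPSSMTransition <- function(x, profile = NULL) {
  codes <- seqCodes(x)
  L <- length(codes)
  if (L < 2) stop("sequence too short for PSSM transitions (L >= 2)")
  if (is.null(profile)) {
    profile <- blosumProfile(codes)
  } else {
    if (is.list(profile)) profile <- profile$scores
    if (nrow(profile) != L)
      stop("PSSM profile has ", nrow(profile), " rows for a sequence of ",
           "length ", L)
    if (!is.null(colnames(profile)))
      profile <- profile[, AA_ORDER, drop = FALSE]
  }
  sig <- 1 / (1 + exp(-profile))
  m <- crossprod(sig[-L, , drop = FALSE], sig[-1, , drop = FALSE]) / (L - 1)
  v <- as.vector(t(m))
  names(v) <- paste0("pssm_", 1:400)
  v
}

## BLOSUM62-derived pseudo-profile (cached substitution matrix)
blosumEnv <- new.env(parent = emptyenv())
blosumProfile <- function(codes) {
  if (is.null(blosumEnv$B)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosumEnv$B <- e$BLOSUM62[AA_ORDER, AA_ORDER]
  }
  blosumEnv$B[codes, , drop = FALSE]
}

#' Compute the full 1,103-feature panel for a set of sequences
#'
#' Concatenates the nine descriptor families in schema order for every
#' sequence: AAC, DC, PseAAC, APseAAC, CTD composition/transition/
#' distribution, SS, SOCN, QSO, PSSM transitions. Sequences must be longer
#' than the strictest lag (L > maxlag, i.e. at least 21 residues by
#' default); shorter sequences raise an error naming the offending id.
#'
#' @param seqs an `AAStringSet` (e.g. from [readFasta()]) or named
#'   character vector of sequences.
#' @param profiles optional named list of PSSM profiles (see [readPSSM()]);
#'   sequences without an entry fall back to the BLOSUM62 pseudo-profile.
#' @param ss optional named character vector of secondary-structure state
#'   strings; missing entries use the propensity fallback.
#' @param labels optional 0/1 labels, recycled onto the sequence ids by
#'   name when named.
#' @param params see [descriptorParams()].
#' @return A [FeatureMatrix-class] with 1,103 columns; `metadata` records
#'   the parameters and which sequences used the PSSM / SS fallbacks.
#' @export
#' @examples
#' set.seed(1)
#' s <- paste(sample(alphabetOrder(), 30, replace = TRUE), collapse = "")
#' fm <- featurize(c(seq1 = s))
#' dim(fm)  # 1 x 1103
featurize <- function(seqs, profiles = NULL, ss = NULL, labels = NULL,
                      params = descriptorParams()) {
  if (is(seqs, "AAStringSet")) seqs <- as.character(seqs)
  stopifnot(is.character(seqs), length(seqs) >= 1)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq_", seq_along(seqs))
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  schema <- featureSchemaTable()
  pssm_fallback <- character(0); ss_fallback <- character(0)
  rows <- lapply(names(seqs), function(id) {
    x <- seqs[[id]]
    prof <- profiles[[id]]
    ssx <- if (!is.null(ss) && id %in% names(ss)) ss[[id]] else NULL
    if (is.null(prof)) pssm_fallback <<- c(pssm_fallback, id)
    if (is.null(ssx)) ss_fallback <<- c(ss_fallback, id)
    v <- tryCatch(
      c(extractAAC(x), extractDC(x), extractPAAC(x, params),
        extractAPAAC(x, params), extractCTD(x), extractSS(x, ssx),
        extractSOCN(x, params), extractQSO(x, params),
        extractPSSMTransition(x, prof)),
      error = function(e) stop("sequence '", id, "': ", conditionMessage(e),
                               call. = FALSE))
    stopifnot(length(v) == 1103L)
    v
  })
  values <- do.call(rbind, rows)
  rownames(values) <- names(seqs)
  colnames(values) <- schema$name
  if (!is.null(labels) && !is.null(names(labels)))
    labels <- labels[names(seqs)]
  FeatureMatrix(values, schema = schema, labels = labels,
                metadata = list(params = params,
                                schemaVersion = SCHEMA_VERSION,
                                pssmFallback = pssm_fallback,
                                ssFallback = ss_fallback))
}
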