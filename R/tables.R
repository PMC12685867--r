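#' Amino-acid alphabet order
#'
#' The fixed 20-letter amino-acid order used by every descriptor family and
#' feature name in the package: A, R, N, D, C, Q, E, G, H, I, L, K, M, F, P,
#' S, T, W, Y, V. Position 5 is cysteine, so the feature `aac_5` is the
#' cysteine composition; this anchoring is asserted by the test suite.
#'
#' @return Character vector of the 20 standard amino-acid one-letter codes.
#' @export
#' @examples
#' alphabetOrder()[5]  # "C"
alphabetOrder <- function() AA_ORDER

AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## Chou's normalized hydrophobicity scale (PseAAC convention)
AA_HYDROPHOBICITY <- c(
  A =  0.62, R = -2.53, N = -0.78, D = -0.90, C =  0.29,
  Q = -0.85, E = -0.74, G =  0.48, H = -0.40, I =  1.38,
  L =  1.06, K = -1.50, M =  0.64, F =  1.19, P =  0.12,
  S = -0.18, T = -0.05, W =  0.81, Y =  0.26, V =  1.08)

## Hopp-Woods hydrophilicity
AA_HYDROPHILICITY <- c(
  A = -0.5, R =  3.0, N =  0.2, D =  3.0, C = -1.0,
  Q =  0.2, E =  3.0, G =  0.0, H = -0.5, I = -1.8,
  L = -1.8, K =  3.0, M = -1.3, F = -2.5, P =  0.0,
  S =  0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5)

## Side-chain mass (Da)
AA_SIDECHAIN_MASS <- c(
  A =  15, R = 101, N =  58, D =  59, C =  47,
  Q =  72, E =  73, G =   1, H =  82, I =  57,
  L =  57, K =  73, M =  75, F =  91, P =  42,
  S =  31, T =  45, W = 130, Y = 107, V =  43)

## Chou-Fasman conformational propensities (helix, strand, turn/coil),
## used only by the internal secondary-structure fallback predictor.
CHOU_FASMAN <- matrix(c(
  1.42, 0.83, 0.66,   # A
  0.98, 0.93, 0.95,   # R
  0.67, 0.89, 1.56,   # N
  1.01, 0.54, 1.46,   # D
  0.70, 1.19, 1.19,   # C
  1.11, 1.10, 0.98,   # Q
  1.51, 0.37, 0.74,   # E
  0.57, 0.75, 1.56,   # G
  1.00, 0.87, 0.95,   # H
  1.08, 1.60, 0.47,   # I
  1.21, 1.30, 0.59,   # L
  1.16, 0.74, 1.01,   # K
  1.45, 1.05, 0.60,   # M
  1.13, 1.38, 0.60,   # F
  0.57, 0.55, 1.52,   # P
  0.77, 0.75, 1.43,   # S
  0.83, 1.19, 0.96,   # T
  1.08, 1.37, 0.96,   # W
  0.69, 1.47, 1.14,   # Y
  1.06, 1.70, 0.50),  # V
  nrow = 20, ncol = 3, byrow = TRUE,
  dimnames = list(AA_ORDER, c("H", "E", "C")))

## CTD residue grouping: 7 physicochemical properties, each partitioning
## the 20 amino acids into 3 disjoint exhaustive groups (classic Dubchak
## convention). Property order fixes the feature numbering: solvent
## accessibility is property 7, whose group 1 (buried residues) drives the
## distribution anchor dist_93.
CTD_GROUPS <- list(
  hydrophobicity = list(
    g1 = c("R", "K", "E", "D", "Q", "N"),
    g2 = c("G", "A", "S", "T", "P", "H", "Y"),
    g3 = c("C", "L", "V", "I", "M", "F", "W")),
  vdw_volume = list(
    g1 = c("G", "A", "S", "C", "T", "P", "D"),
    g2 = c("N", "V", "E", "Q", "I", "L"),
    g3 = c("M", "H", "K", "F", "R", "Y", "W")),
  polarity = list(
    g1 = c("L", "I", "F", "W", "C", "M", "V", "Y"),
    g2 = c("P", "A", "T", "G", "S"),
    g3 = c("H", "Q", "R", "K", "N", "E", "D")),
  polarizability = list(
    g1 = c("G", "A", "S", "D", "T"),
    g2 = c("C", "P", "N", "V", "E", "Q", "I", "L"),
    g3 = c("K", "M", "H", "F", "R", "Y", "W")),
  charge = list(
    g1 = c("K", "R"),
    g2 = c("A", "N", "C", "Q", "G", "H", "I", "L", "M", "F",
           "P", "S", "T", "W", "Y", "V"),
    g3 = c("D", "E")),
  secondary_structure = list(
    g1 = c("E", "A", "L", "M", "Q", "K", "R", "H"),
    g2 = c("V", "I", "Y", "C", "W", "F", "T"),
    g3 = c("G", "N", "P", "S", "D")),
  solvent_accessibility = list(
    g1 = c("A", "L", "F", "C", "G", "I", "V", "W"),
    g2 = c("R", "K", "Q", "E", "N", "D"),
    g3 = c("M", "S", "P", "T", "H", "Y")))

## Standardize a 20-value scale to zero mean, unit population SD.
standardizeScale <- function(h) {
  h <- h[AA_ORDER]
  (h - mean(h)) / sqrt(mean((h - mean(h))^2))
}

#' Physicochemical amino-acid distance matrix
#'
#' The 20 x 20 symmetric distance matrix used by the sequence-order coupling
#' number (SOCN) and quasi-sequence-order (QSO) descriptors. It is
#' constructed by the package as the Euclidean distance over the three
#' standardized physicochemical scales (hydrophobicity, hydrophilicity,
#' side-chain mass) that also drive the pseudo amino-acid composition,
#' divided by sqrt(3) so each squared entry is the mean squared scale
#' difference. It is a synthetic stand-in constructed from published scales,
#' not a reprint of any published distance table.
#'
#' @return Numeric 20 x 20 matrix, dimnames in [alphabetOrder()], zero
#'   diagonal.
#' @export
#' @examples
#' d <- aaDistanceMatrix()
#' all(diag(d) == 0)
aaDistanceMatrix <- function() {
  scales <- cbind(standardizeScale(AA_HYDROPHOBICITY),
                  standardizeScale(AA_HYDROPHILICITY),
                  standardizeScale(AA_SIDECHAIN_MASS))
  d <- as.matrix(stats::dist(scales)) / sqrt(3)
  dimnames(d) <- list(AA_ORDER, AA_ORDER)
  d
}

## Feature-family display groups used for SHAP aggregation.
FAMILY_DISPLAY <- c(aac = "AAC", dipep = "DC", pseudo = "PseAAC",
                    amphipseudo = "APseAAC", comp = "CTD", tran = "CTD",
                    dist = "CTD", ss = "SS", socn = "SOCN", qso = "QSO",
                    pssm = "PSSM")

SCHEMA_VERSION <- "1.0"

#' The canonical 1,103-feature schema
#'
#' Returns the fixed, ordered vocabulary of all 1,103 descriptor names and
#' their families: `aac` (20), `dipep` (400), `pseudo` (30), `amphipseudo`
#' (40), `comp` (21), `tran` (21), `dist` (105), `ss` (6), `socn` (20),
#' `qso` (40), `pssm` (400). Feature numbering is positional within each
#' family: `aac_5` is the cysteine composition, `dist_93` the 50% occurrence
#' quantile of buried residues under the solvent-accessibility property.
#'
#' @return A `data.frame` with columns `name` and `family`, 1,103 rows, in
#'   the order [featurize()] emits columns.
#' @seealso [featurize()]
#' @export
#' @examples
#' s <- featureSchemaTable()
#' nrow(s)                 # 1103
#' table(s$family)
featureSchemaTable <- function() {
  sizes <- c(aac = 20, dipep = 400, pseudo = 30, amphipseudo = 40,
             comp = 21, tran = 21, dist = 105, ss = 6, socn = 20,
             qso = 40, pssm = 400)
  fam <- rep(names(sizes), sizes)
  data.frame(
    name = paste0(fam, "_", unlist(lapply(sizes, seq_len), use.names = FALSE)),
    family = fam,
    stringsAsFactors = FALSE)
}

## Map canonical feature names to their display family (AAC, DC, PseAAC,
## APseAAC, CTD, SS, SOCN, QSO, PSSM); unknown names error.
featureDisplayFamily <- function(names) {
  prefix <- sub("_[0-9]+$", "", names)
  bad <- !prefix %in% names(FAMILY_DISPLAY)
  if (any(bad))
    stop("unknown feature name(s): ", paste(names[bad], collapse = ", "))
  unname(FAMILY_DISPLAY[prefix])
}

## round half away from zero (base round() is banker's)
roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)
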