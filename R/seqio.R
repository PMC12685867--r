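## I/O for the formats the toolkit touches: FASTA protein sequences,
## PSI-BLAST ASCII PSSM profiles, PSIPRED .ss2 secondary-structure files,
## and the TSV feature-table artifact.

#' Read and validate protein sequences from FASTA
#'
#' Reads a multi-record FASTA file into an [Biostrings::AAStringSet] and
#' validates every record against the 20-letter amino-acid alphabet.
#' Record ids are the first whitespace-delimited token of each header and
#' must be unique. Non-standard residue codes (B, Z, X, U, O, `*`, gaps)
#' are rejected by default; with `invalid = "drop"` the offending records
#' are dropped with a warning instead.
#'
#' @param path path to a FASTA file.
#' @param invalid policy for records with non-standard residues:
#'   `"error"` (default) or `"drop"`.
#' @return An `AAStringSet`, one element per retained record, in file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACDEF", ">s2", "MKLVW"), fa)
#' readFasta(fa)
readFasta <- function(path, invalid = c("error", "drop")) {
  invalid <- match.arg(invalid)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) stop("no FASTA records in ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence id(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  chars <- as.character(seqs)
  if (any(nchar(chars) == 0)) stop("empty sequence record(s)")
  bad <- regexpr(sprintf("[^%s]", paste(AA_ORDER, collapse = "")), chars)
  if (any(bad > 0)) {
    which_bad <- which(bad > 0)
    first <- which_bad[1]
    detail <- sprintf("record '%s' has invalid residue '%s' at position %d",
                      names(seqs)[first],
                      substr(chars[first], bad[first], bad[first]),
                      bad[first])
    if (invalid == "error")
      stop("invalid residue(s): ", detail)
    warning("dropping ", length(which_bad), " record(s) with non-standard ",
            "residues: ", detail)
    seqs <- seqs[-which_bad]
    if (length(seqs) == 0) stop("all records dropped as invalid")
  }
  seqs
}

#' Read a PSI-BLAST ASCII PSSM profile
#'
#' Parses the common `-out_ascii_pssm` layout: header lines, a column-header
#' row naming 40 amino-acid columns, one row per residue position, then
#' footer statistics. Only the first 20 (log-odds) score columns are
#' consumed; they are re-ordered into [alphabetOrder()] according to the
#' file's own column header.
#'
#' @param path path to the PSSM file.
#' @return list with `scores` (L x 20 numeric matrix, columns in
#'   [alphabetOrder()]) and `residues` (character, the per-position residue
#'   column).
#' @export
readPSSM <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  ## the column header: a line whose tokens are >= 40 single amino acids
  hdr_idx <- NA_integer_
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) >= 40 && all(nchar(tok) == 1) &&
        all(tok %in% AA_ORDER)) { hdr_idx <- i; break }
  }
  if (is.na(hdr_idx)) stop("malformed PSSM header: no amino-acid column row")
  col_order <- strsplit(trimws(lines[hdr_idx]), "\\s+")[[1]][1:20]
  scores <- list(); residues <- character(0)
  for (i in seq(hdr_idx + 1, length(lines))) {
    ln <- trimws(lines[i])
    if (ln == "") break
    tok <- strsplit(ln, "\\s+")[[1]]
    if (!grepl("^[0-9]+$", tok[1])) break   # footer statistics
    if (length(tok) < 22)
      stop("malformed PSSM row at line ", i, ": expected 20 score columns")
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(vals))
      stop("malformed PSSM row at line ", i, ": non-numeric score")
    residues <- c(residues, tok[2])
    scores[[length(scores) + 1L]] <- vals
  }
  if (length(scores) == 0) stop("PSSM file has no score rows")
  m <- do.call(rbind, scores)
  colnames(m) <- col_order
  m <- m[, AA_ORDER, drop = FALSE]
  list(scores = m, residues = residues)
}

#' Read a PSIPRED .ss2 secondary-structure file
#'
#' Each body line carries position, residue, state (one of H/E/C) and three
#' confidence values; comment (`#`) and blank lines are skipped. Positions
#' must be consecutive from 1.
#'
#' @param path path to a `.ss2` file.
#' @return A single string over `{H, E, C}`, one state per position.
#' @export
readSS2 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) stop("empty secondary-structure profile: ", path)
  tok <- strsplit(trimws(lines), "\\s+")
  pos <- as.integer(vapply(tok, `[`, "", 1L))
  states <- vapply(tok, `[`, "", 3L)
  bad <- !states %in% c("H", "E", "C")
  if (any(bad))
    stop("unknown secondary-structure state '", states[which(bad)[1]],
         "' at position ", pos[which(bad)[1]])
  if (!identical(pos, seq_along(pos)))
    stop("position gap in .ss2 file at line ",
         which(pos != seq_along(pos))[1])
  paste(states, collapse = "")
}

#' Write / read the TSV feature-table artifact
#'
#' The on-disk artifact is tab-separated: header row of schema names, first
#' column `sample_id`, optional final column `label` (1 = bacteriocin,
#' 0 = non-bacteriocin), floats at 10 significant digits so that a
#' write/read round trip reproduces values bit-for-bit at textual
#' precision.
#'
#' @param fm a [FeatureMatrix-class].
#' @param path output (input) path.
#' @return `writeFeatureTable`: `path`, invisibly. `readFeatureTable`: a
#'   [FeatureMatrix-class].
#' @export
writeFeatureTable <- function(fm, path) {
  stopifnot(is(fm, "FeatureMatrix"))
  v <- featureValues(fm)
  cols <- c("sample_id", featureSchema(fm)$name)
  body <- cbind(rownames(v),
                matrix(formatC(v, digits = 10, format = "g"),
                       nrow = nrow(v)))
  if (!is.null(featureLabels(fm))) {
    cols <- c(cols, "label")
    body <- cbind(body, as.character(featureLabels(fm)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @param requireLabels error if the table lacks a `label` column.
#' @export
readFeatureTable <- function(path, requireLabels = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(tab)[1] != "sample_id")
    stop("feature table must start with a 'sample_id' column")
  has_label <- colnames(tab)[ncol(tab)] == "label"
  if (requireLabels && !has_label)
    stop("feature table lacks the required 'label' column")
  feat_cols <- setdiff(seq_along(tab), c(1L, if (has_label) ncol(tab)))
  fnames <- colnames(tab)[feat_cols]
  if (anyDuplicated(fnames))
    stop("duplicated feature name(s) in table header: ",
         paste(unique(fnames[duplicated(fnames)]), collapse = ", "))
  v <- as.matrix(tab[, feat_cols, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- as.character(tab$sample_id)
  colnames(v) <- fnames
  FeatureMatrix(v, labels = if (has_label) tab$label else NULL)
}
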