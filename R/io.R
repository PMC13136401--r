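# readers/writers for the external text formats
#
# All tabular outputs are labelled CSV with fixed column order; floats are
# serialized at 10 significant digits. Readers reject malformed input
# rather than repairing it.

FLOAT_DIGITS <- 10L

fmt_num <- function(x) signif(x, FLOAT_DIGITS)

#' Read a word-embedding table in fastText `.vec` text dialect
#'
#' The file starts with a header line `"N D"` followed by one line per word:
#' the word token then D floats, whitespace-separated. Words containing
#' spaces are not supported. Vectors may optionally be restricted to (and
#' re-keyed by) a concept set.
#'
#' @param path path to a `.vec` text file.
#' @param restrict_to optional character vector of words/concept ids to keep;
#'   words absent from the file are reported via the `missing` attribute.
#' @param language_code language label attached to the table.
#' @return an `embedding_table`: list with `language_code`, `dim`, and
#'   `vectors` (words x dim numeric matrix with word rownames). Attribute
#'   `missing` lists requested words not found.
#' @export
read_embeddings <- function(path, restrict_to = NULL, language_code = NA_character_) {
  if (!file.exists(path)) stop("embedding file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("empty .vec file: ", path)
  hdr <- strsplit(trimws(lines[[1L]]), "[ \t]+")[[1L]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr))))
    stop("malformed .vec header (expected \"N D\"): ", lines[[1L]])
  n <- as.integer(hdr[1L]); d <- as.integer(hdr[2L])
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n)
    stop("header declares ", n, " rows but file has ", length(body))
  words <- character(n)
  vecs <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(body[[i]]), "[ \t]+")[[1L]]
    if (length(tok) != d + 1L)
      stop("row ", i, " (word '", tok[1L], "'): expected ", d,
           " values, found ", length(tok) - 1L)
    v <- suppressWarnings(as.numeric(tok[-1L]))
    if (anyNA(v)) stop("row ", i, ": non-numeric vector component")
    words[i] <- tok[1L]
    vecs[i, ] <- v
  }
  if (anyDuplicated(words)) stop("duplicate words in .vec file")
  rownames(vecs) <- words
  missing <- character(0)
  if (!is.null(restrict_to)) {
    missing <- setdiff(restrict_to, words)
    vecs <- vecs[intersect(restrict_to, words), , drop = FALSE]
  }
  structure(
    list(language_code = language_code, dim = d, vectors = vecs),
    missing = missing, class = "embedding_table"
  )
}

#' Write an embedding table in `.vec` text dialect
#'
#' @param emb an `embedding_table` (or a numeric matrix with rownames).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path) {
  m <- if (inherits(emb, "embedding_table")) emb$vectors else emb
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(m), ncol(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(rownames(m)[i],
                     paste(format(fmt_num(m[i, ]), scientific = FALSE, trim = TRUE,
                                  digits = FLOAT_DIGITS), collapse = " ")), con)
  }
  invisible(path)
}

#' Construct an embedding table from a matrix
#'
#' @param vectors numeric matrix, words/concepts as rownames.
#' @param language_code language label.
#' @return an `embedding_table`.
#' @export
embedding_table <- function(vectors, language_code = NA_character_) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  if (anyDuplicated(rownames(vectors))) stop("duplicate concept ids")
  structure(list(language_code = language_code, dim = ncol(vectors),
                 vectors = vectors), class = "embedding_table")
}

#' Filter languages by concept coverage
#'
#' Retains languages whose fraction of missing concept vectors does not
#' exceed `max_missing_frac` (the reference analysis excluded languages
#' missing over 25% of concepts).
#'
#' @param tables named list of `embedding_table`s (names = language codes).
#' @param concepts master concept character vector.
#' @param max_missing_frac maximum tolerated missing fraction, in \[0, 1\].
#' @return character vector of retained language codes, in input order,
#'   with the per-language missing fractions as attribute `missing_frac`.
#' @export
language_coverage_filter <- function(tables, concepts, max_missing_frac = 0.25) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1)
  codes <- names(tables)
  if (is.null(codes)) codes <- vapply(tables, `[[`, "", "language_code")
  frac <- vapply(tables, function(t)
    mean(!(concepts %in% rownames(t$vectors))), 0)
  names(frac) <- codes
  keep <- codes[frac <= max_missing_frac]
  if (length(keep) == 0L) stop("no language passes the coverage filter")
  structure(keep, missing_frac = frac)
}

#' Read a labelled representational dissimilarity matrix from CSV
#'
#' Expects a square CSV with identical row and column labels; entries must
#' be symmetric within `tol`.
#'
#' @param path CSV path (first column = row labels).
#' @param tol symmetry tolerance.
#' @return a labelled symmetric numeric matrix with zero diagonal.
#' @export
read_rdm <- function(path, tol = 1e-8) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("RDM not square: ", nrow(m), "x", ncol(m))
  if (!identical(rownames(m), colnames(m)))
    stop("RDM row/column labels differ")
  if (max(abs(m - t(m))) > tol)
    stop("RDM asymmetric beyond tolerance ", tol)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

#' Write an RDM to labelled CSV
#'
#' Symmetry is checked and the diagonal zeroed on write.
#'
#' @param rdm labelled square symmetric matrix.
#' @param path output CSV path.
#' @param tol symmetry tolerance.
#' @return `path`, invisibly.
#' @export
write_rdm <- function(rdm, path, tol = 1e-8) {
  if (max(abs(rdm - t(rdm))) > tol) stop("refusing to write asymmetric RDM")
  m <- (rdm + t(rdm)) / 2
  diag(m) <- 0
  df <- as.data.frame(fmt_num(m))
  colnames(df) <- colnames(rdm)
  utils::write.csv(df, path, row.names = TRUE)
  invisible(path)
}

#' Read a concept translation wordlist (TSV: concept_id, language, wordform)
#'
#' @param path TSV path with header.
#' @return data.frame with columns concept_id, language_code, wordform.
#' @export
read_wordlist <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("concept_id", "language_code", "wordform")
  if (!all(need %in% names(df)))
    stop("wordlist must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df[, c("concept_id", "language_code")]))
    stop("duplicate (concept_id, language_code) rows in wordlist")
  df[, need]
}

#' Read an anchor specification (TSV: dimension, concept_id)
#'
#' @param path TSV path with header columns `dimension`, `concept_id`.
#' @return named list mapping dimension name -> character vector of anchors.
#' @export
read_anchor_spec <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("dimension", "concept_id") %in% names(df)))
    stop("anchor spec must have columns: dimension, concept_id")
  sp <- split(df$concept_id, df$dimension)
  if (any(lengths(sp) == 0L)) stop("empty anchor dimension")
  sp[unique(df$dimension)]
}

#' Write an anchor specification to TSV
#' @param anchors named list dimension -> concept ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_anchor_spec <- function(anchors, path) {
  df <- data.frame(dimension = rep(names(anchors), lengths(anchors)),
                   concept_id = unlist(anchors, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a colexification edge list (TSV: concept_a, concept_b, n_languages)
#' @param path TSV path with header.
#' @return data.frame with the three columns.
#' @export
read_colex_edges <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("concept_a", "concept_b", "n_languages")
  if (!all(need %in% names(df)))
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  df[, need]
}

#' Write a colexification edge list to TSV
#' @param edges data.frame(concept_a, concept_b, n_languages).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_colex_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
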