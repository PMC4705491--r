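#' Read protein sequences from a FASTA file
#'
#' Wrapped lines are joined, sequences are uppercased, and trailing `*` stop
#' symbols are removed. The record identifier is the first whitespace-delimited
#' token of the header line.
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return A tibble with columns `protein_id` and `sequence`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo", "MKV", "LAA*"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- stringr::str_extract(names(set), "^\\S+")
  seqs <- toupper(as.character(set))
  seqs <- stringr::str_remove_all(seqs, "\\*")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate protein id in FASTA: %s", ids[duplicated(ids)][1]))
  }
  tibble(protein_id = unname(ids), sequence = unname(seqs))
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs A data frame with columns `protein_id` and `sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(setNames(seqs$sequence, seqs$protein_id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read tabular homology-search hits
#'
#' Accepts the 12-column BLAST `outfmt 6` layout (qseqid, sseqid, pident, ...,
#' evalue, bitscore) or a minimal variant with the first three (optionally
#' four: an e-value) columns. Only query id, subject accession, percent
#' similarity and (when present) e-value are consumed.
#'
#' @param path Path to a tab-separated hits file without a header.
#' @return A tibble with columns `query_id`, `subject_accession`,
#'   `similarity_pct`, `evalue` (`NA` when the input has no e-value column).
#' @export
read_hits <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  nc <- ncol(raw)
  if (!nc %in% c(3L, 4L, 12L)) {
    abort(sprintf("hits file must have 3, 4 or 12 tab-separated columns, found %d", nc))
  }
  ev <- if (nc == 12L) as.numeric(raw[[11]]) else if (nc == 4L) as.numeric(raw[[4]]) else NA_real_
  hits <- tibble(
    query_id = raw[[1]],
    subject_accession = raw[[2]],
    similarity_pct = as.numeric(raw[[3]]),
    evalue = ev
  )
  validate_hits(hits)
  hits
}

validate_hits <- function(hits) {
  need <- c("query_id", "subject_accession", "similarity_pct")
  missing <- setdiff(need, names(hits))
  if (length(missing)) {
    abort(paste0("hits are missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(!nzchar(hits$query_id)) || any(!nzchar(hits$subject_accession))) {
    abort("hit query ids and subject accessions must be non-empty")
  }
  bad <- which(is.na(hits$similarity_pct) | hits$similarity_pct < 0 |
                 hits$similarity_pct > 100)
  if (length(bad)) {
    abort(sprintf("similarity_pct out of [0, 100] for hit %s -> %s",
                  hits$query_id[bad[1]], hits$subject_accession[bad[1]]))
  }
  invisible(hits)
}

#' Write homology hits in 12-column tabular form
#'
#' Unconsumed BLAST `outfmt 6` columns are written as zeros so the file remains
#' readable by standard tooling.
#'
#' @param hits A data frame as returned by [read_hits()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  validate_hits(hits)
  ev <- hits$evalue
  if (is.null(ev)) ev <- rep(NA_real_, nrow(hits))
  out <- tibble(
    q = hits$query_id, s = hits$subject_accession,
    pident = hits$similarity_pct,
    length = 0L, mismatch = 0L, gapopen = 0L,
    qstart = 0L, qend = 0L, sstart = 0L, send = 0L,
    evalue = ifelse(is.na(ev), 0, ev), bitscore = 0
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

go_id_pattern <- "^GO:\\d{7}$"

validate_annotations <- function(annotations) {
  if (!all(c("accession", "go_id") %in% names(annotations))) {
    abort("annotations need columns `accession` and `go_id`")
  }
  bad <- which(!stringr::str_detect(annotations$go_id, go_id_pattern))
  if (length(bad)) {
    abort(sprintf("malformed GO id '%s' for accession '%s'",
                  annotations$go_id[bad[1]], annotations$accession[bad[1]]))
  }
  invisible(annotations)
}

#' Read a GO annotation table
#'
#' Two formats are supported: a headerless two-column TSV (`accession`,
#' `go_id`) and GAF 2.x, of which only column 2 (DB Object ID) and column 5
#' (GO ID) are consumed; `!`-prefixed comment lines are skipped. `format =
#' "auto"` treats files whose first data line has 5 or more columns as GAF.
#'
#' @param path Path to the annotation file.
#' @param format One of `"auto"`, `"tsv"`, `"gaf"`.
#' @return A deduplicated tibble with columns `accession` and `go_id`.
#' @export
read_annotations <- function(path, format = c("auto", "tsv", "gaf")) {
  format <- match.arg(format)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines)) abort("annotation file contains no records")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "auto") {
    format <- if (length(fields[[1]]) >= 5L) "gaf" else "tsv"
  }
  if (format == "gaf") {
    short <- which(lengths(fields) < 5L)
    if (length(short)) abort(sprintf("GAF line %d has fewer than 5 columns", short[1]))
    ann <- tibble(accession = vapply(fields, `[[`, "", 2L),
                  go_id = vapply(fields, `[[`, "", 5L))
  } else {
    short <- which(lengths(fields) < 2L)
    if (length(short)) abort(sprintf("annotation line %d has fewer than 2 columns", short[1]))
    ann <- tibble(accession = vapply(fields, `[[`, "", 1L),
                  go_id = vapply(fields, `[[`, "", 2L))
  }
  ann <- dplyr::distinct(ann)
  validate_annotations(ann)
  ann
}

#' Write a GO annotation table as two-column TSV
#'
#' @param annotations A data frame with columns `accession` and `go_id`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  validate_annotations(annotations)
  readr::write_tsv(annotations[, c("accession", "go_id")], path, col_names = FALSE)
  invisible(path)
}

#' Read per-protein location labels
#'
#' The file is a headerless two-column TSV: protein id, comma-separated
#' location names.
#'
#' @param path Path to the label file.
#' @return A tibble with columns `protein_id` and `labels` (a list column of
#'   character vectors).
#' @export
read_labels <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("protein_id", "locations"),
                         col_types = "cc", show_col_types = FALSE)
  tibble(protein_id = raw$protein_id,
         labels = as_label_sets(raw$locations))
}

#' Write per-protein location labels
#'
#' @param labels A data frame with columns `protein_id` and `labels` (list
#'   column of character vectors).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  out <- tibble(protein_id = labels$protein_id,
                locations = vapply(as_label_sets(labels$labels),
                                   paste, "", collapse = ","))
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Write a feature matrix as MatrixMarket plus sidecar id files
#'
#' Writes `<prefix>.mtx` (sparse MatrixMarket), `<prefix>.rows.txt` (one
#' protein id per line) and `<prefix>.cols.txt` (one column id per line).
#'
#' @param mat A matrix or `Matrix` sparse matrix with row and column names.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_feature_matrix <- function(mat, prefix) {
  mat <- as(as(mat, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    abort("feature matrix must carry row and column names")
  }
  Matrix::writeMM(mat, paste0(prefix, ".mtx"))
  readr::write_lines(rownames(mat), paste0(prefix, ".rows.txt"))
  readr::write_lines(colnames(mat), paste0(prefix, ".cols.txt"))
  invisible(prefix)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param prefix Path prefix used when writing.
#' @return A sparse `dgCMatrix` with protein ids as row names.
#' @export
read_feature_matrix <- function(prefix) {
  mat <- as(Matrix::readMM(paste0(prefix, ".mtx")), "CsparseMatrix")
  rn <- readr::read_lines(paste0(prefix, ".rows.txt"))
  cn <- readr::read_lines(paste0(prefix, ".cols.txt"))
  if (length(rn) != nrow(mat) || length(cn) != ncol(mat)) {
    abort("sidecar id files do not match the matrix dimensions")
  }
  dimnames(mat) <- list(rn, cn)
  mat
}

#' Write prediction records as TSV
#'
#' One row per protein: id, `;`-joined predicted locations, the feature mode
#' used, then one signed score column per label in label-space order.
#'
#' @param predictions A tibble as returned by [predict.eccloc_ecc()] or
#'   [jackknife()] (`$predictions`), with columns `protein_id`, `predicted`
#'   (list column), `mode`, and `score_*` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  out <- predictions
  out$predicted <- vapply(as_label_sets(out$predicted), paste, "", collapse = ";")
  if (!"mode" %in% names(out)) out$mode <- NA_character_
  score_cols <- grep("^score_", names(out), value = TRUE)
  readr::write_tsv(out[, c("protein_id", "predicted", "mode", score_cols)], path)
  invisible(path)
}

#' Read prediction records written by [write_predictions()]
#'
#' @param path Path to the prediction TSV.
#' @return A tibble with `protein_id`, `predicted` (list column), `mode`, and
#'   `score_*` columns.
#' @export
read_predictions <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  raw$predicted <- as_label_sets(raw$predicted)
  raw
}
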