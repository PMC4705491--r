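# GO frequency features: each query protein is represented by the frequency
# with which each GO term is carried by its typical homologous set (the
# homology-search hits at or above a pairwise-similarity threshold). The j-th
# coordinate is f_j = (number of typical homologs annotated with term j) / N_h.

#' Select the typical homologous set of one query protein
#'
#' Retains the distinct subject accessions of hits whose percent similarity is
#' at or above `threshold_pct`, in first-occurrence order. Exact self-hits
#' (subject accession equal to the query id) are excluded. Duplicate subject
#' accessions (multiple HSPs) are collapsed to one homolog.
#'
#' @param hits A data frame of hits for a single query, with columns
#'   `query_id`, `subject_accession`, `similarity_pct`.
#' @param threshold_pct Minimum pairwise similarity, in percent. Default 60.
#' @return A tibble with columns `query_id` and `accession`, one row per
#'   retained homolog; the query id is also attached as attribute `query_id`.
#'   The number of rows is the typical-set size N_h.
#' @export
#' @examples
#' hits <- tibble::tibble(query_id = "Q1",
#'                        subject_accession = c("A", "B", "C"),
#'                        similarity_pct = c(80, 61, 59))
#' select_typical_homologs(hits) # keeps A and B
select_typical_homologs <- function(hits, threshold_pct = 60) {
  check_scalar_number(threshold_pct, "threshold_pct", 0, 100)
  validate_hits(hits)
  qids <- unique(hits$query_id)
  if (length(qids) > 1L) {
    off <- hits$query_id[hits$query_id != qids[1]][1]
    abort(sprintf("hits mix query ids ('%s' and '%s'); filter to one query first",
                  qids[1], off))
  }
  qid <- if (length(qids)) qids[1] else NA_character_
  keep <- hits$similarity_pct >= threshold_pct &
    hits$subject_accession != hits$query_id
  acc <- unique(hits$subject_accession[keep])
  out <- tibble(query_id = rep(qid, length(acc)), accession = acc)
  attr(out, "query_id") <- qid
  out
}

#' Build the GO term index defining the feature space
#'
#' The feature-space columns are the distinct GO terms appearing anywhere in
#' the annotation table, ordered lexicographically for reproducibility.
#'
#' @param annotations A data frame with columns `accession` and `go_id`.
#' @return A tibble with columns `go_id` and `column` (1-based); the number of
#'   rows is the feature-space dimension D.
#' @export
build_go_index <- function(annotations) {
  if (is.null(annotations) || nrow(annotations) == 0L) {
    abort("annotation table is empty; cannot build a GO term index")
  }
  validate_annotations(annotations)
  terms <- sort(unique(annotations$go_id))
  tibble(go_id = terms, column = seq_along(terms))
}

#' Compute the GO frequency vector of one protein
#'
#' Given the typical homologous set of a query, the frequency of GO term j is
#' the fraction of homologs annotated with j. Homologs with no annotation
#' record contribute zeros but still count in the denominator N_h.
#'
#' @param homologs A tibble from [select_typical_homologs()] (columns
#'   `query_id`, `accession`).
#' @param annotations Annotation table (`accession`, `go_id`).
#' @param index GO term index from [build_go_index()].
#' @return A tibble of the non-zero coordinates: columns `protein_id`,
#'   `go_id`, `column`, `frequency`, with every frequency in (0, 1] and an
#'   integer multiple of 1/N_h.
#' @export
compute_go_vector <- function(homologs, annotations, index) {
  n_h <- nrow(homologs)
  if (n_h == 0L) {
    abort("typical homologous set is empty: no GO representation (use the dipeptide backup)",
          class = "eccloc_no_go_representation")
  }
  if (is.null(index) || nrow(index) == 0L) abort("GO term index is empty")
  ann <- dplyr::distinct(annotations[annotations$accession %in% homologs$accession,
                                     c("accession", "go_id")])
  missing <- setdiff(unique(ann$go_id), index$go_id)
  if (length(missing)) {
    abort(sprintf("GO term %s is annotated but absent from the index (index/annotation mismatch)",
                  missing[1]))
  }
  counts <- dplyr::count(ann, .data$go_id, name = "n_carriers")
  qid <- attr(homologs, "query_id") %||% homologs$query_id[1]
  tibble(
    protein_id = qid,
    go_id = counts$go_id,
    column = index$column[match(counts$go_id, index$go_id)],
    frequency = counts$n_carriers / n_h
  ) |> dplyr::arrange(.data$column)
}

#' Assess which proteins have a usable GO representation
#'
#' A protein is GO-representable when its typical homologous set is non-empty
#' and at least one homolog accession matches the annotation table; others
#' must be routed to the dipeptide backup encoder.
#'
#' @param hits Hit table for any number of queries.
#' @param annotations Annotation table.
#' @param query_ids Protein ids to report on; defaults to the queries present
#'   in `hits`. Ids with no hits at all are reported with `n_h = 0`.
#' @param threshold_pct Similarity threshold, percent. Default 60.
#' @return A tibble with columns `protein_id`, `n_h`, `n_annotated`,
#'   `representable`.
#' @export
go_representable <- function(hits, annotations, query_ids = NULL,
                             threshold_pct = 60) {
  query_ids <- query_ids %||% unique(hits$query_id)
  annotated_acc <- unique(annotations$accession)
  rows <- lapply(query_ids, function(q) {
    hom <- select_typical_homologs(hits[hits$query_id == q, , drop = FALSE],
                                   threshold_pct = threshold_pct)
    n_ann <- sum(hom$accession %in% annotated_acc)
    tibble(protein_id = q, n_h = nrow(hom), n_annotated = n_ann,
           representable = nrow(hom) > 0L && n_ann > 0L)
  })
  dplyr::bind_rows(rows)
}

#' Build the sparse GO feature matrix for a set of proteins
#'
#' Rows are proteins (in `query_ids` order), columns the indexed GO terms.
#' Proteins without a usable GO representation get an all-zero row; use
#' [go_representable()] to route them to the backup encoder.
#'
#' @inheritParams go_representable
#' @param index GO term index; defaults to [build_go_index()] on
#'   `annotations`.
#' @return A sparse `dgCMatrix` with protein ids as row names and GO ids as
#'   column names.
#' @export
go_feature_matrix <- function(hits, annotations, query_ids = NULL,
                              index = NULL, threshold_pct = 60) {
  index <- index %||% build_go_index(annotations)
  query_ids <- query_ids %||% unique(hits$query_id)
  triplets <- lapply(query_ids, function(q) {
    hom <- select_typical_homologs(hits[hits$query_id == q, , drop = FALSE],
                                   threshold_pct = threshold_pct)
    if (nrow(hom) == 0L) return(NULL)
    v <- compute_go_vector(hom, annotations, index)
    if (nrow(v) == 0L) return(NULL)
    tibble(row = match(q, query_ids), column = v$column, frequency = v$frequency)
  })
  trip <- dplyr::bind_rows(triplets)
  Matrix::sparseMatrix(
    i = trip$row, j = trip$column, x = trip$frequency,
    dims = c(length(query_ids), nrow(index)),
    dimnames = list(query_ids, index$go_id)
  )
}
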