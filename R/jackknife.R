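# Jackknife (leave-one-out) evaluation of the full pipeline. Every protein
# is predicted by a model trained on the remaining proteins: GO-representable
# proteins by an ECC over GO frequency vectors (fitted on the representable
# training proteins), the rest by an ECC over dipeptide composition vectors
# (fitted on all training proteins). Feature vectors depend only on external
# knowledge (hits, annotations, sequences), so they are computed once; the
# leave-one-out structure applies to classifier training.

#' Jackknife evaluation of the localization pipeline
#'
#' Runs leave-one-out cross-validation: for each protein, an ensemble of
#' classifier chains is trained on the other proteins and the held-out
#' protein's location set is predicted, using GO frequency features when the
#' protein has a usable GO representation and the dipeptide composition
#' backup otherwise. Returns the overall locative/absolute accuracies and
#' per-location success rates.
#'
#' The run is deterministic given the inputs, the configuration and `seed`:
#' chain orders are fixed once per run for each feature mode (derived from
#' `seed`), not re-drawn per fold.
#'
#' @param labels Tibble of true locations: columns `protein_id`, `labels`
#'   (list column, or `,`-separated strings).
#' @param hits Homology hit table ([read_hits()] layout).
#' @param annotations GO annotation table ([read_annotations()] layout).
#' @param sequences Tibble with `protein_id`, `sequence` for every protein.
#' @param label_space Optional fixed label order.
#' @param threshold_pct Typical-homolog similarity threshold, percent.
#'   Default 60.
#' @param m Ensemble size (number of chains). Default 25.
#' @param base Binary base learner. Default [linear_svm_learner()].
#' @param seed Integer seed for the chain orders.
#' @return An object of class `eccloc_jackknife`: list with `metrics` (an
#'   `eccloc_metrics`), `predictions` (tibble with `protein_id`, `truth`,
#'   `predicted`, `mode`, and `score_*` columns), `label_space`, `config`.
#' @export
jackknife <- function(labels, hits, annotations, sequences,
                      label_space = NULL, threshold_pct = 60, m = 25,
                      base = linear_svm_learner(), seed = 1) {
  Y <- as_label_sets(labels$labels)
  ids <- labels$protein_id
  n <- length(ids)
  if (n < 3L) abort("jackknife needs at least 3 proteins")
  label_space <- label_space_from(Y, label_space)

  seq_idx <- match(ids, sequences$protein_id)
  if (anyNA(seq_idx)) {
    abort(sprintf("no sequence for protein '%s'", ids[which(is.na(seq_idx))[1]]))
  }
  index <- build_go_index(annotations)
  X_go <- go_feature_matrix(hits, annotations, query_ids = ids, index = index,
                            threshold_pct = threshold_pct)
  route <- go_representable(hits, annotations, query_ids = ids,
                            threshold_pct = threshold_pct)
  representable <- route$representable[match(ids, route$protein_id)]
  X_dip <- dipeptide_feature_matrix(sequences[seq_idx, ])

  go_seed <- derive_seed(seed, 1L)
  dip_seed <- derive_seed(seed, 2L)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    if (representable[i]) {
      tr <- train[representable[train]]
      model <- ecc_train(X_go[tr, , drop = FALSE], Y[tr], m = m,
                         label_space = label_space, base = base,
                         seed = go_seed)
      out <- ecc_predict(model, X_go[i, , drop = FALSE])
      mode <- "go"
    } else {
      model <- ecc_train(X_dip[train, , drop = FALSE], Y[train], m = m,
                         label_space = label_space, base = base,
                         seed = dip_seed)
      out <- ecc_predict(model, X_dip[i, , drop = FALSE])
      mode <- "dipeptide"
    }
    rows[[i]] <- dplyr::bind_cols(
      tibble(protein_id = ids[i], truth = list(Y[[i]]),
             predicted = out$labels, mode = mode),
      setNames(as_tibble(out$scores, .name_repair = "minimal"),
               paste0("score_", label_space))
    )
  }
  predictions <- dplyr::bind_rows(rows)
  structure(
    list(
      metrics = metrics_report(Y, predictions$predicted, label_space),
      predictions = predictions,
      label_space = label_space,
      config = list(threshold_pct = threshold_pct, m = m, base = base$name,
                    base_config = base$config, seed = as.integer(seed))
    ),
    class = "eccloc_jackknife"
  )
}

#' @export
print.eccloc_jackknife <- function(x, ...) {
  cat(sprintf("Jackknife evaluation (m = %d chains, base %s, seed %d)\n",
              x$config$m, x$config$base, x$config$seed))
  cat(sprintf("  feature routing: %d GO, %d dipeptide\n",
              sum(x$predictions$mode == "go"),
              sum(x$predictions$mode == "dipeptide")))
  print(x$metrics)
  invisible(x)
}

#' Per-location success rates of a jackknife run
#'
#' @param x An `eccloc_jackknife` object.
#' @param ... Unused.
#' @return A tibble with one row per location.
#' @export
tidy.eccloc_jackknife <- function(x, ...) tidy(x$metrics)

#' One-row summary of a jackknife run
#'
#' @param x An `eccloc_jackknife` object.
#' @param ... Unused.
#' @return A one-row tibble with the overall accuracies, counts, and
#'   configuration.
#' @export
glance.eccloc_jackknife <- function(x, ...) {
  dplyr::bind_cols(glance(x$metrics),
                   tibble(m = x$config$m, threshold_pct = x$config$threshold_pct,
                          seed = x$config$seed))
}

#' Write a jackknife report to disk
#'
#' Writes the metrics report (`<prefix>.txt`, `<prefix>.tsv`, see
#' [write_metrics()]) and the per-protein predictions
#' (`<prefix>.predictions.tsv`).
#'
#' @param x An `eccloc_jackknife` object.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_jackknife <- function(x, prefix) {
  write_metrics(x$metrics, prefix)
  write_predictions(x$predictions, paste0(prefix, ".predictions.tsv"))
  invisible(prefix)
}
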