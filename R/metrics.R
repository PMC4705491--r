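# Multi-label performance measures for localization prediction. A protein
# with k annotated locations contributes k "locative" proteins; N_loc is the
# sum of true label-set sizes and N_dif the number of distinct proteins.
# Overall locative accuracy averages |Y ∩ Z| over N_loc; overall absolute
# accuracy is the stricter exact-match rate over N_dif.

#' Count locative proteins
#'
#' Each (protein, location) annotation pair counts once, so a protein with
#' two locations contributes two locative proteins: the count is the sum of
#' the true label-set sizes.
#'
#' @param Ys True label sets: a list of non-empty character vectors (or a
#'   character vector of `,`/`;`-separated names).
#' @return An integer, N_loc.
#' @export
#' @examples
#' count_locative(list(c("cytoplasm"), c("cytoplasm", "cell_wall")))
count_locative <- function(Ys) {
  Ys <- as_label_sets(Ys)
  sum(lengths(Ys))
}

check_ys_zs <- function(Ys, Zs) {
  if (length(Ys) != length(Zs)) {
    abort(sprintf("there are %d true but %d predicted label sets",
                  length(Ys), length(Zs)))
  }
}

#' Overall locative accuracy
#'
#' The summed sizes of the intersections between true and predicted label
#' sets, divided by the number of locative proteins N_loc.
#'
#' @param Ys,Zs True and predicted label sets (lists of character vectors, or
#'   character vectors of separated names). True sets must be non-empty.
#' @return A number in `[0, 1]`.
#' @export
overall_locative_accuracy <- function(Ys, Zs) {
  Ys <- as_label_sets(Ys)
  Zs <- as_label_sets(Zs, allow_empty = TRUE)
  check_ys_zs(Ys, Zs)
  hits <- mapply(function(y, z) length(intersect(y, z)), Ys, Zs)
  sum(hits) / count_locative(Ys)
}

#' Overall absolute accuracy
#'
#' The fraction of proteins whose predicted label set is exactly identical to
#' the true set. A prediction that is a strict superset of the truth scores
#' zero for that protein, making this measure stricter than the overall
#' locative accuracy.
#'
#' @inheritParams overall_locative_accuracy
#' @return A number in `[0, 1]`.
#' @export
overall_absolute_accuracy <- function(Ys, Zs) {
  Ys <- as_label_sets(Ys)
  Zs <- as_label_sets(Zs, allow_empty = TRUE)
  check_ys_zs(Ys, Zs)
  mean(mapply(function(y, z) setequal(y, z), Ys, Zs))
}

#' Per-location success rates
#'
#' For each location, the fraction of its carrier proteins (those whose true
#' set contains the location) whose predicted set also contains it — the
#' locative recall of the location. Weighting each location's rate by its
#' carrier count and dividing by N_loc reproduces the overall locative
#' accuracy.
#'
#' @inheritParams overall_locative_accuracy
#' @param label_space Locations to report; defaults to the sorted distinct
#'   labels in `Ys`. Locations carried by no protein get `NA`.
#' @return A tibble with columns `location`, `n_carriers`, `n_recovered`,
#'   `success_rate`.
#' @export
per_location_success <- function(Ys, Zs, label_space = NULL) {
  Ys <- as_label_sets(Ys)
  Zs <- as_label_sets(Zs, allow_empty = TRUE)
  check_ys_zs(Ys, Zs)
  label_space <- label_space %||% sort(unique(unlist(Ys)))
  purrr::map_dfr(label_space, function(l) {
    carriers <- vapply(Ys, function(y) l %in% y, logical(1))
    n_c <- sum(carriers)
    n_r <- sum(vapply(Zs[carriers], function(z) l %in% z, logical(1)))
    tibble(location = l, n_carriers = n_c, n_recovered = n_r,
           success_rate = if (n_c > 0L) n_r / n_c else NA_real_)
  })
}

#' Full metrics report for a set of multi-label predictions
#'
#' @inheritParams per_location_success
#' @return An object of class `eccloc_metrics`: a list with
#'   `overall_locative_accuracy`, `overall_absolute_accuracy`,
#'   `per_location` (tibble), `n_loc`, `n_dif`.
#' @export
metrics_report <- function(Ys, Zs, label_space = NULL) {
  Ys <- as_label_sets(Ys)
  Zs <- as_label_sets(Zs, allow_empty = TRUE)
  structure(
    list(
      overall_locative_accuracy = overall_locative_accuracy(Ys, Zs),
      overall_absolute_accuracy = overall_absolute_accuracy(Ys, Zs),
      per_location = per_location_success(Ys, Zs, label_space),
      n_loc = count_locative(Ys),
      n_dif = length(Ys)
    ),
    class = "eccloc_metrics"
  )
}

#' @export
print.eccloc_metrics <- function(x, ...) {
  cat(sprintf("Multi-label evaluation over %d proteins (%d locative)\n",
              x$n_dif, x$n_loc))
  cat(sprintf("  overall locative accuracy: %.4f\n", x$overall_locative_accuracy))
  cat(sprintf("  overall absolute accuracy: %.4f\n", x$overall_absolute_accuracy))
  for (i in seq_len(nrow(x$per_location))) {
    r <- x$per_location[i, ]
    cat(sprintf("  %-20s %3d/%3d  %s\n", r$location, r$n_recovered,
                r$n_carriers,
                ifelse(is.na(r$success_rate), "n/a",
                       sprintf("%.4f", r$success_rate))))
  }
  invisible(x)
}

#' Per-location rates of a metrics report as a tibble
#'
#' @param x An `eccloc_metrics` object.
#' @param ... Unused.
#' @return The `per_location` tibble.
#' @export
tidy.eccloc_metrics <- function(x, ...) x$per_location

#' One-row summary of a metrics report
#'
#' @param x An `eccloc_metrics` object.
#' @param ... Unused.
#' @return A one-row tibble with the two overall accuracies and the
#'   locative/distinct protein counts.
#' @export
glance.eccloc_metrics <- function(x, ...) {
  tibble(overall_locative_accuracy = x$overall_locative_accuracy,
         overall_absolute_accuracy = x$overall_absolute_accuracy,
         n_loc = x$n_loc, n_dif = x$n_dif)
}

#' Write a metrics report as text and key-value files
#'
#' Writes `<prefix>.txt` (human-readable) and `<prefix>.tsv` (machine-
#' readable key-value rows: the overall measures, counts, and one row per
#' location's success rate).
#'
#' @param x An `eccloc_metrics` object.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_metrics <- function(x, prefix) {
  txt <- paste0(prefix, ".txt")
  sink(txt); on.exit(sink(), add = TRUE)
  print(x)
  sink()
  on.exit()
  kv <- dplyr::bind_rows(
    tibble(key = c("overall_locative_accuracy", "overall_absolute_accuracy",
                   "n_loc", "n_dif"),
           value = c(x$overall_locative_accuracy, x$overall_absolute_accuracy,
                     x$n_loc, x$n_dif)),
    tibble(key = paste0("success_rate.", x$per_location$location),
           value = x$per_location$success_rate)
  )
  readr::write_tsv(kv, paste0(prefix, ".tsv"))
  invisible(prefix)
}
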