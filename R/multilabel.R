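# Multi-label engine: binary relevance (BR), classifier chains (CC) and the
# ensemble of classifier chains (ECC). All three decompose the label set into
# binary membership problems over a linear base learner; CC additionally
# feeds each classifier the 0/1 values of the labels earlier in its chain,
# and ECC averages the score vectors of m randomly ordered chains.

label_space_from <- function(Y, label_space = NULL) {
  if (is.null(label_space)) label_space <- sort(unique(unlist(Y)))
  label_space <- as.character(label_space)
  if (length(label_space) < 2L) abort("label space must contain at least 2 labels")
  if (anyDuplicated(label_space) || any(!nzchar(label_space))) {
    abort("label names must be unique and non-empty")
  }
  extra <- setdiff(unique(unlist(Y)), label_space)
  if (length(extra)) {
    abort(sprintf("label '%s' is not in the label space", extra[1]))
  }
  label_space
}

label_indicator <- function(Y, label_space) {
  m <- vapply(label_space, function(l) {
    vapply(Y, function(y) as.integer(l %in% y), integer(1))
  }, integer(length(Y)))
  matrix(m, nrow = length(Y), dimnames = list(NULL, label_space))
}

check_xy <- function(X, Y) {
  if (nrow(X) != length(Y)) {
    abort(sprintf("feature matrix has %d rows but there are %d label sets",
                  nrow(X), length(Y)))
  }
}

#' Decide the predicted label set from a signed score vector
#'
#' Labels with strictly positive scores are predicted. If no score is
#' positive, the single label with the maximum score is predicted (ties break
#' toward the lowest label index), so the predicted set is never empty.
#'
#' @param scores A numeric vector of signed decision scores (one per label,
#'   named or accompanied by `label_space`), or a matrix with one row per
#'   example and one column per label.
#' @param label_space Character vector of label names aligned with `scores`;
#'   defaults to its names.
#' @return A character vector of predicted labels, or a list of such vectors
#'   when `scores` is a matrix.
#' @export
#' @examples
#' decide_labels(c(cytoplasm = 0.5, cell_wall = -0.2, extracell = 0.1))
#' decide_labels(c(cytoplasm = -3, cell_wall = -1, extracell = -2))
decide_labels <- function(scores, label_space = NULL) {
  if (is.matrix(scores)) {
    label_space <- label_space %||% colnames(scores)
    return(lapply(seq_len(nrow(scores)),
                  function(i) decide_labels(scores[i, ], label_space)))
  }
  label_space <- label_space %||% names(scores)
  if (is.null(label_space)) abort("scores must be named or `label_space` given")
  if (any(!is.finite(scores))) abort("scores must be finite")
  pos <- scores > 0
  if (any(pos)) label_space[pos] else label_space[which.max(scores)]
}

#' Train a binary relevance (one-vs-rest) multi-label model
#'
#' Fits one binary scorer per label: examples carrying the label are
#' positives, all remaining examples negatives. Labels with no positives (or
#' no negatives) in the training data get a constant scorer, with a warning.
#'
#' @param X Feature matrix (dense or sparse), one row per training example.
#' @param Y Label sets: a list of character vectors (or a character vector of
#'   `,`/`;`-separated names), one per row of `X`.
#' @param label_space Optional character vector fixing the label order;
#'   defaults to the sorted distinct labels in `Y`.
#' @param base Binary base learner, e.g. [linear_svm_learner()].
#' @return An object of class `eccloc_br`.
#' @export
br_train <- function(X, Y, label_space = NULL, base = linear_svm_learner()) {
  Y <- as_label_sets(Y)
  check_xy(X, Y)
  label_space <- label_space_from(Y, label_space)
  ind <- label_indicator(Y, label_space)
  scorers <- lapply(label_space, function(l) base$fit(X, ind[, l]))
  structure(
    list(label_space = label_space, scorers = scorers, n_features = ncol(X),
         feature_names = colnames(X), base = base$name, config = base$config),
    class = "eccloc_br"
  )
}

#' Score new examples with a binary relevance model
#'
#' @param model An `eccloc_br` model.
#' @param X Feature matrix with the training feature dimension.
#' @return A numeric matrix of signed scores, one row per example, one column
#'   per label in label-space order.
#' @export
br_predict <- function(model, X) {
  X <- as_feature_rows(X, model$n_features)
  scores <- vapply(model$scorers, function(s) score_rows(s, X), numeric(nrow(X)))
  matrix(scores, nrow = nrow(X),
         dimnames = list(rownames(X), model$label_space))
}

as_feature_rows <- function(X, n_features) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != n_features) {
    abort(sprintf("feature dimension mismatch: model expects %d, got %d",
                  n_features, ncol(X)))
  }
  X
}

#' Train a single classifier chain
#'
#' The j-th classifier in chain order is trained on the base features
#' augmented with the true 0/1 values of the j-1 labels earlier in the chain
#' (teacher forcing); at prediction time the augmentation uses the chain's own
#' hard decisions instead.
#'
#' @inheritParams br_train
#' @param chain_order Integer permutation of `seq_along(label_space)` giving
#'   the order in which labels are chained.
#' @return An object of class `eccloc_cc`.
#' @export
cc_train <- function(X, Y, chain_order = NULL, label_space = NULL,
                     base = linear_svm_learner()) {
  Y <- as_label_sets(Y)
  check_xy(X, Y)
  label_space <- label_space_from(Y, label_space)
  n <- length(label_space)
  chain_order <- chain_order %||% seq_len(n)
  if (!identical(sort(as.integer(chain_order)), seq_len(n))) {
    abort("`chain_order` must be a permutation of the label indices")
  }
  chain_order <- as.integer(chain_order)
  ind <- label_indicator(Y, label_space)
  scorers <- vector("list", n)
  for (j in seq_len(n)) {
    prev <- chain_order[seq_len(j - 1L)]
    Xa <- if (j == 1L) X else cbind2(X, ind[, prev, drop = FALSE])
    scorers[[j]] <- base$fit(Xa, ind[, chain_order[j]])
  }
  structure(
    list(label_space = label_space, chain_order = chain_order,
         scorers = scorers, n_features = ncol(X),
         feature_names = colnames(X), base = base$name, config = base$config),
    class = "eccloc_cc"
  )
}

#' Score new examples with a classifier chain
#'
#' Labels are scored sequentially in chain order, each scorer consuming the
#' base features plus the hard 0/1 decisions (score > 0) of all previous
#' chain positions; the returned scores are re-ordered into label-space
#' order.
#'
#' @param model An `eccloc_cc` model.
#' @param X Feature matrix (or a single feature vector) with the training
#'   feature dimension.
#' @return A numeric matrix of signed scores in label-space order.
#' @export
cc_predict <- function(model, X) {
  X <- as_feature_rows(X, model$n_features)
  n <- length(model$label_space)
  scores <- matrix(NA_real_, nrow(X), n,
                   dimnames = list(rownames(X), model$label_space))
  bits <- matrix(0, nrow(X), 0L)
  for (j in seq_len(n)) {
    Xa <- if (j == 1L) X else cbind2(X, bits)
    s <- score_rows(model$scorers[[j]], Xa)
    scores[, model$chain_order[j]] <- s
    bits <- cbind(bits, as.numeric(s > 0))
  }
  scores
}

#' Train an ensemble of classifier chains (ECC)
#'
#' Trains `m` classifier chains, each with a chain order drawn uniformly at
#' random (with replacement across members) from the seeded random number
#' generator; every member sees the full training set. Ensemble sizes of 25
#' and 40 are the defaults used for the gram-positive and gram-negative
#' localization predictors respectively.
#'
#' @inheritParams br_train
#' @param m Number of chain members (default 25).
#' @param seed Integer seed controlling the chain orders.
#' @return An object of class `eccloc_ecc`.
#' @export
ecc_train <- function(X, Y, m = 25, label_space = NULL,
                      base = linear_svm_learner(), seed = 1) {
  check_scalar_number(m, "m", lower = 1)
  Y <- as_label_sets(Y)
  check_xy(X, Y)
  label_space <- label_space_from(Y, label_space)
  n <- length(label_space)
  orders <- withr::with_seed(seed,
                             lapply(seq_len(m), function(i) sample.int(n)))
  members <- lapply(orders, function(ord) {
    cc_train(X, Y, chain_order = ord, label_space = label_space, base = base)
  })
  structure(
    list(members = members, label_space = label_space, m = as.integer(m),
         seed = as.integer(seed), n_features = ncol(X),
         feature_names = colnames(X), base = base$name, config = base$config),
    class = "eccloc_ecc"
  )
}

#' Score and classify new examples with an ECC model
#'
#' The ensemble score vector is the arithmetic mean of the members' chain
#' score vectors (in label-space order); predicted label sets follow
#' [decide_labels()] on the mean scores.
#'
#' @param model An `eccloc_ecc` model.
#' @param X Feature matrix (or single feature vector).
#' @return A list with `scores` (numeric matrix, one row per example) and
#'   `labels` (list of predicted label sets).
#' @export
ecc_predict <- function(model, X) {
  X <- as_feature_rows(X, model$n_features)
  acc <- Reduce(`+`, lapply(model$members, function(mem) cc_predict(mem, X)))
  scores <- acc / length(model$members)
  list(scores = scores, labels = decide_labels(scores, model$label_space))
}

#' Predict method for ECC models
#'
#' @param object An `eccloc_ecc` model.
#' @param newdata Feature matrix; row names, when present, become
#'   `protein_id`.
#' @param ... Unused.
#' @return A tibble with `protein_id`, `predicted` (list column of label
#'   sets), and one `score_<label>` column per label.
#' @export
predict.eccloc_ecc <- function(object, newdata, ...) {
  out <- ecc_predict(object, newdata)
  ids <- rownames(out$scores) %||% as.character(seq_len(nrow(out$scores)))
  res <- tibble(protein_id = ids, predicted = out$labels)
  sc <- as_tibble(out$scores, .name_repair = "minimal")
  names(sc) <- paste0("score_", object$label_space)
  dplyr::bind_cols(res, sc)
}

#' @export
print.eccloc_ecc <- function(x, ...) {
  cat(sprintf("<ECC model: %d chains over %d labels, %d features, base %s, seed %d>\n",
              x$m, length(x$label_space), x$n_features, x$base, x$seed))
  invisible(x)
}

#' @export
print.eccloc_cc <- function(x, ...) {
  cat(sprintf("<classifier chain over %d labels (order %s), %d features>\n",
              length(x$label_space),
              paste(x$chain_order, collapse = " "), x$n_features))
  invisible(x)
}

#' @export
print.eccloc_br <- function(x, ...) {
  cat(sprintf("<binary relevance model over %d labels, %d features>\n",
              length(x$label_space), x$n_features))
  invisible(x)
}

#' Tidy the chain structure of an ECC model
#'
#' @param x An `eccloc_ecc` model.
#' @param ... Unused.
#' @return A tibble with one row per (member, chain position): columns
#'   `member`, `position`, `label`, `augmentation_width`.
#' @export
tidy.eccloc_ecc <- function(x, ...) {
  purrr::map_dfr(seq_along(x$members), function(i) {
    ord <- x$members[[i]]$chain_order
    tibble(member = i, position = seq_along(ord),
           label = x$label_space[ord],
           augmentation_width = seq_along(ord) - 1L)
  })
}

#' One-row summary of an ECC model
#'
#' @param x An `eccloc_ecc` model.
#' @param ... Unused.
#' @return A one-row tibble: `m`, `n_labels`, `n_features`, `base`, `seed`.
#' @export
glance.eccloc_ecc <- function(x, ...) {
  tibble(m = x$m, n_labels = length(x$label_space),
         n_features = x$n_features, base = x$base, seed = x$seed)
}
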