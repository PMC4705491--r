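# Pluggable binary base learner. A base learner is a list with a `fit`
# element: fit(X, y01) must return a linear scorer, i.e. list(w, b) scoring
# x as sum(w * x) + b, with positive scores meaning predicted membership.
# Keeping scorers as plain (w, b) pairs makes chains fast to evaluate,
# deterministic, and serializable as text.

#' Linear SVM base learner
#'
#' An L2-regularized linear support vector machine (libsvm via
#' \pkg{e1071}, linear kernel) used as the binary base learner inside binary
#' relevance and classifier chains. No feature scaling is applied: GO
#' frequency and composition features already lie in `[0, 1]`. The fitted
#' hyperplane is extracted as an explicit weight vector and intercept, with
#' the sign convention that positive decision values mean membership.
#'
#' Degenerate subproblems with a single target class (which arise during
#' leave-one-out runs on rare locations) yield a constant scorer: score
#' `-1` when there are no positive examples, `+1` when there are no
#' negatives.
#'
#' @param cost Regularization constant C of the SVM. Default 1.
#' @return A base-learner object usable as the `base` argument of
#'   [br_train()], [cc_train()] and [ecc_train()].
#' @export
linear_svm_learner <- function(cost = 1) {
  check_scalar_number(cost, "cost", lower = 1e-12)
  structure(
    list(
      name = "linear_svm",
      config = list(cost = cost),
      fit = function(X, y01) fit_linear_svm(X, y01, cost = cost)
    ),
    class = "eccloc_base_learner"
  )
}

#' @export
print.eccloc_base_learner <- function(x, ...) {
  cfg <- paste(names(x$config), unlist(x$config), sep = " = ", collapse = ", ")
  cat(sprintf("<base learner: %s (%s)>\n", x$name, cfg))
  invisible(x)
}

constant_scorer <- function(d, sign) {
  list(w = numeric(d), b = sign * 1, constant = TRUE)
}

fit_linear_svm <- function(X, y01, cost) {
  X <- as.matrix(X)
  y01 <- as.integer(y01)
  d <- ncol(X)
  if (all(y01 == 0L)) {
    warn("binary subproblem has no positive examples; using constant score -1")
    return(constant_scorer(d, -1))
  }
  if (all(y01 == 1L)) {
    warn("binary subproblem has no negative examples; using constant score +1")
    return(constant_scorer(d, +1))
  }
  yf <- factor(ifelse(y01 == 1L, "pos", "neg"), levels = c("pos", "neg"))
  fit <- e1071::svm(X, yf, kernel = "linear", cost = cost, scale = FALSE)
  w <- as.numeric(Matrix::crossprod(fit$SV, fit$coefs))
  b <- -fit$rho
  # libsvm orients decision values toward the first class it encounters in
  # the data; read the orientation off the decision-value column name.
  dv <- attr(predict(fit, X[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  first <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
  if (identical(first, "neg")) {
    w <- -w
    b <- -b
  }
  list(w = w, b = b, constant = FALSE)
}

# Score rows of X with a linear scorer.
score_rows <- function(scorer, X) {
  as.numeric(X %*% scorer$w) + scorer$b
}
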