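test_that("label decision takes positive scores, with argmax fallback and low-index ties", {
  ls3 <- c("L1", "L2", "L3")
  expect_equal(decide_labels(c(0.5, -0.2, 0.1), ls3), c("L1", "L3"))
  expect_equal(decide_labels(c(-3, -1, -2), ls3), "L2")
  expect_equal(decide_labels(c(-1, -1), c("A", "B")), "A")
  # a zero score is a non-member, so all-zero falls back to the first label
  expect_equal(decide_labels(c(0, 0), c("A", "B")), "A")
  expect_error(decide_labels(c(1, NaN), c("A", "B")), "finite")

  # matrix input returns one set per row; the set is never empty
  set.seed(5)
  scores <- matrix(rnorm(300), ncol = 3, dimnames = list(NULL, ls3))
  sets <- decide_labels(scores)
  expect_length(sets, 100L)
  expect_true(all(lengths(sets) >= 1L))
  for (i in c(1, 17, 99)) {
    expect_equal(sets[[i]], decide_labels(scores[i, ]))
  }
})

test_that("binary relevance trains one scorer per label and separates a toy problem", {
  # 4 points, 2 labels, linearly separable on each axis
  X <- rbind(c(1, 0), c(1, 1), c(0, 1), c(0, 0)) * 2 - 0.5
  colnames(X) <- c("f1", "f2")
  Y <- list("A", c("A", "B"), "B", "A")
  Y[[4]] <- "C" # third label so the space has 3 labels
  m <- br_train(X, Y, label_space = c("A", "B", "C"))
  expect_length(m$scorers, 3L)
  sc <- br_predict(m, X)
  # reference separator: label A iff f1 > 0.5, label B iff f2 > 0.5 (margin-free)
  expect_equal(unname(sc[, "A"] > 0), X[, 1] > 0.5)
  expect_equal(unname(sc[, "B"] > 0), X[, 2] > 0.5)
})

test_that("labels with no positives or no negatives get a constant scorer", {
  X <- matrix(rnorm(20), ncol = 2)
  Y <- rep(list("A"), 10)
  # label A has no negatives (warned first), label B no positives
  expect_warning(
    expect_warning(
      m <- br_train(X, Y, label_space = c("A", "B")),
      "no negative"
    ),
    "no positive"
  )
  sc <- br_predict(m, X)
  expect_true(all(sc[, "B"] == -1)) # no positives -> constant -1
  expect_true(all(sc[, "A"] == +1)) # no negatives -> constant +1
})

test_that("chain classifiers see a design widened by one label per position", {
  X <- matrix(rnorm(30), ncol = 3)
  Y <- random_label_sets(10, c("A", "B", "C"))
  log_env <- new.env(); log_env$widths <- integer()
  cc_train(X, Y, chain_order = c(2, 3, 1), label_space = c("A", "B", "C"),
           base = width_recording_learner(log_env))
  expect_equal(log_env$widths, c(3L, 4L, 5L))
})

test_that("a chain learns a deterministically dependent label from the passed bit", {
  # Label B always co-occurs with A; features inform A only. With teacher
  # forcing the B scorer can copy the augmented bit and held-out exact-match
  # accuracy is 1.
  set.seed(99)
  n <- 200
  x <- c(rep(1, n / 2), rep(-1, n / 2)) + rnorm(n, sd = 0.1)
  X <- cbind(x, rnorm(n, sd = 0.1))
  Y <- lapply(x, function(v) if (v > 0) c("A", "B") else "C")
  tr <- sample(n, 150); te <- setdiff(seq_len(n), tr)
  m <- cc_train(X[tr, ], Y[tr], chain_order = c(1, 2, 3),
                label_space = c("A", "B", "C"))
  Z <- decide_labels(cc_predict(m, X[te, ]))
  expect_equal(mean(mapply(setequal, Y[te], Z)), 1.0)

  # brute-force check of the sequential prediction on a few points
  for (i in te[1:5]) {
    xrow <- X[i, , drop = FALSE]
    s1 <- sum(m$scorers[[1]]$w * xrow) + m$scorers[[1]]$b
    b1 <- as.numeric(s1 > 0)
    s2 <- sum(m$scorers[[2]]$w * c(xrow, b1)) + m$scorers[[2]]$b
    b2 <- as.numeric(s2 > 0)
    s3 <- sum(m$scorers[[3]]$w * c(xrow, b1, b2)) + m$scorers[[3]]$b
    expect_equal(unname(cc_predict(m, xrow)[1, ]), c(s1, s2, s3))
  }
})

test_that("chain prediction equals pencil-and-paper evaluation of fixed scorers", {
  # order (L1, L2): scorer for L2 consumes the hard decision of L1
  cc <- fixed_cc(c("L1", "L2"), c(1, 2),
                 list(list(w = c(1, 0), b = -0.5, constant = FALSE),
                      list(w = c(0, 1, 2), b = -1, constant = FALSE)),
                 n_features = 2L)
  # x = (1, 0): s1 = 0.5 > 0 -> bit 1; s2 = 0 + 0 + 2*1 - 1 = 1
  expect_equal(unname(cc_predict(cc, c(1, 0))[1, ]), c(0.5, 1))
  # x = (0, 0.2): s1 = -0.5 -> bit 0; s2 = 0.2 - 1 = -0.8
  expect_equal(unname(cc_predict(cc, c(0, 0.2))[1, ]), c(-0.5, -0.8))

  # reversed order (L2, L1): L2 scored first from base features only
  cc_rev <- fixed_cc(c("L1", "L2"), c(2, 1),
                     list(list(w = c(0, 1), b = -1, constant = FALSE),
                          list(w = c(1, 0, 3), b = -0.5, constant = FALSE)),
                     n_features = 2L)
  # x = (1, 2): s(L2) = 2 - 1 = 1 -> bit 1; s(L1) = 1 + 3*1 - 0.5 = 3.5
  expect_equal(unname(cc_predict(cc_rev, c(1, 2))[1, ]), c(3.5, 1))

  expect_error(cc_predict(cc, c(1, 2, 3)), "mismatch")
})

test_that("ensemble scores are the arithmetic mean of member chains", {
  mk <- function(b1, b2) {
    fixed_cc(c("L1", "L2"), c(1, 2),
             list(list(w = c(0, 0), b = b1, constant = TRUE),
                  list(w = c(0, 0, 0), b = b2, constant = TRUE)),
             n_features = 2L)
  }
  # three members with constant scores: mean is the hand-computed average
  ecc <- fixed_ecc(list(mk(1, -1), mk(0.5, 0.5), mk(-0.5, 2)), c("L1", "L2"), 2L)
  out <- ecc_predict(ecc, c(0, 0))
  expect_equal(unname(out$scores[1, ]), c(mean(c(1, 0.5, -0.5)), mean(c(-1, 0.5, 2))))

  # two members scoring (+1, -1) and (-1, +1): mean (0, 0), all-negative
  # fallback picks the first label
  ecc2 <- fixed_ecc(list(mk(1, -1), mk(-1, 1)), c("L1", "L2"), 2L)
  out2 <- ecc_predict(ecc2, c(0, 0))
  expect_equal(unname(out2$scores[1, ]), c(0, 0))
  expect_equal(out2$labels[[1]], "L1")

  # m identical members: mean equals any single member's vector
  ecc3 <- fixed_ecc(list(mk(2, -3), mk(2, -3), mk(2, -3)), c("L1", "L2"), 2L)
  expect_equal(ecc_predict(ecc3, c(0, 0))$scores,
               cc_predict(mk(2, -3), c(0, 0)))
})

test_that("an ensemble of one chain reproduces that chain exactly", {
  set.seed(13)
  X <- matrix(rnorm(60), ncol = 3)
  Y <- random_label_sets(20, c("A", "B", "C"))
  ecc <- suppressWarnings(
    ecc_train(X, Y, m = 1, label_space = c("A", "B", "C"), seed = 4))
  cc <- suppressWarnings(
    cc_train(X, Y, chain_order = ecc$members[[1]]$chain_order,
             label_space = c("A", "B", "C")))
  Xn <- matrix(rnorm(15), ncol = 3)
  expect_identical(ecc_predict(ecc, Xn)$scores, cc_predict(cc, Xn))
  expect_identical(ecc_predict(ecc, Xn)$labels, decide_labels(cc_predict(cc, Xn)))
})

test_that("BR equals a chain whose augmented coefficients are forced to zero", {
  set.seed(17)
  X <- matrix(rnorm(80), ncol = 4)
  Y <- random_label_sets(20, c("A", "B", "C"))
  base <- centroid_learner(d_base = 4L)
  br <- br_train(X, Y, label_space = c("A", "B", "C"), base = base)
  cc <- cc_train(X, Y, chain_order = c(3, 1, 2),
                 label_space = c("A", "B", "C"), base = base)
  Xn <- matrix(rnorm(20), ncol = 4)
  expect_equal(br_predict(br, Xn), cc_predict(cc, Xn))
})

test_that("ensembles are deterministic given a seed, and orders vary across members", {
  set.seed(3)
  X <- matrix(rnorm(120), ncol = 4)
  Y <- random_label_sets(30, c("A", "B", "C", "D"))
  e1 <- suppressWarnings(ecc_train(X, Y, m = 6, seed = 11))
  e2 <- suppressWarnings(ecc_train(X, Y, m = 6, seed = 11))
  o1 <- lapply(e1$members, `[[`, "chain_order")
  expect_identical(o1, lapply(e2$members, `[[`, "chain_order"))
  Xn <- matrix(rnorm(40), ncol = 4)
  expect_identical(ecc_predict(e1, Xn), ecc_predict(e2, Xn))
  # different seed draws different chain orders
  e3 <- suppressWarnings(ecc_train(X, Y, m = 6, seed = 12))
  expect_false(identical(o1, lapply(e3$members, `[[`, "chain_order")))
})

test_that("different chain orders can yield different predictions", {
  set.seed(21)
  n <- 60
  x <- rnorm(n)
  X <- cbind(x, rnorm(n))
  Y <- lapply(x, function(v) if (v > 0) c("A", "B") else "C")
  c12 <- cc_train(X, Y, chain_order = c(1, 2, 3), label_space = c("A", "B", "C"))
  c21 <- cc_train(X, Y, chain_order = c(2, 1, 3), label_space = c("A", "B", "C"))
  Xn <- cbind(rnorm(50), rnorm(50))
  expect_false(identical(cc_predict(c12, Xn), cc_predict(c21, Xn)))
})

test_that("the JSON model archive round-trips predictions exactly", {
  set.seed(29)
  X <- matrix(runif(200), ncol = 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  Y <- random_label_sets(40, c("A", "B", "C"))
  model <- suppressWarnings(ecc_train(X, Y, m = 4, seed = 8))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  loaded <- load_model(path)
  expect_identical(loaded$label_space, model$label_space)
  expect_identical(loaded$members[[2]]$chain_order, model$members[[2]]$chain_order)
  Xn <- matrix(runif(50), ncol = 5)
  expect_identical(ecc_predict(loaded, Xn), ecc_predict(model, Xn))
  expect_error(load_model(withr::local_tempfile(lines = "{}", fileext = ".json")),
               "not an ECC")
})

test_that("tidy and glance summarise ensemble structure", {
  set.seed(2)
  X <- matrix(rnorm(60), ncol = 2)
  Y <- random_label_sets(30, c("A", "B"))
  model <- suppressWarnings(ecc_train(X, Y, m = 3, seed = 1))
  td <- tidy(model)
  expect_equal(nrow(td), 6L) # 3 members x 2 positions
  expect_equal(td$augmentation_width[td$position == 2], rep(1L, 3))
  gl <- glance(model)
  expect_equal(gl$m, 3L)
  expect_equal(gl$n_labels, 2L)
  expect_equal(gl$base, "linear_svm")
})
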