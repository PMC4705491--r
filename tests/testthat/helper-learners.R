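# Stub base learners and small oracles shared across test files.

# Centroid-difference learner restricted to the first `d_base` columns:
# coefficients on any augmented columns are forced to zero, so a classifier
# chain built on it must coincide with binary relevance.
centroid_learner <- function(d_base) {
  structure(
    list(
      name = "centroid_stub", config = list(d_base = d_base),
      fit = function(X, y01) {
        X <- as.matrix(X)
        Xb <- X[, seq_len(d_base), drop = FALSE]
        if (all(y01 == 1)) return(list(w = numeric(ncol(X)), b = 1, constant = TRUE))
        if (all(y01 == 0)) return(list(w = numeric(ncol(X)), b = -1, constant = TRUE))
        mu1 <- colMeans(Xb[y01 == 1, , drop = FALSE])
        mu0 <- colMeans(Xb[y01 == 0, , drop = FALSE])
        w <- c(mu1 - mu0, numeric(ncol(X) - d_base))
        list(w = w, b = -sum((mu1 + mu0) / 2 * (mu1 - mu0)), constant = FALSE)
      }
    ),
    class = "eccloc_base_learner"
  )
}

# Learner that records the width of every design matrix it is fitted on.
width_recording_learner <- function(log_env) {
  structure(
    list(
      name = "width_recorder", config = list(),
      fit = function(X, y01) {
        log_env$widths <- c(log_env$widths, ncol(X))
        list(w = numeric(ncol(X)), b = -1, constant = TRUE)
      }
    ),
    class = "eccloc_base_learner"
  )
}

# Hand-built classifier chain with fixed linear scorers (no training).
fixed_cc <- function(label_space, chain_order, scorers, n_features) {
  structure(
    list(label_space = label_space, chain_order = as.integer(chain_order),
         scorers = scorers, n_features = n_features, feature_names = NULL,
         base = "fixed", config = list()),
    class = "eccloc_cc"
  )
}

fixed_ecc <- function(members, label_space, n_features, seed = 0L) {
  structure(
    list(members = members, label_space = label_space,
         m = length(members), seed = as.integer(seed),
         n_features = n_features, feature_names = NULL,
         base = "fixed", config = list()),
    class = "eccloc_ecc"
  )
}

# Brute-force GO vector: double loop over (term, homolog).
brute_go_vector <- function(accessions, ann_list, terms) {
  vapply(terms, function(j) {
    hits <- 0L
    for (k in accessions) {
      ann <- ann_list[[k]]
      if (!is.null(ann) && j %in% ann) hits <- hits + 1L
    }
    hits / length(accessions)
  }, numeric(1))
}

# Brute-force 420-dim composition by explicit sliding window.
brute_dipeptide <- function(seq) {
  aa <- eccloc:::amino_acids
  chars <- strsplit(toupper(seq), "")[[1]]
  chars <- chars[chars %in% aa]
  v <- numeric(420)
  names(v) <- c(aa, as.vector(t(outer(aa, aa, paste0))))
  for (ch in chars) v[ch] <- v[ch] + 1 / length(chars)
  for (i in seq_len(length(chars) - 1)) {
    p <- paste0(chars[i], chars[i + 1])
    v[p] <- v[p] + 1 / (length(chars) - 1)
  }
  v
}

random_protein <- function(len) {
  paste(sample(eccloc:::amino_acids, len, replace = TRUE), collapse = "")
}

# Random label-set draws over a label space (always non-empty).
random_label_sets <- function(n, label_space, max_size = 2) {
  lapply(seq_len(n), function(i) {
    sample(label_space, sample.int(max_size, 1))
  })
}
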