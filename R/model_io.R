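# Single-file JSON model archive. Scorers are plain (w, b) linear functions,
# so the archive fully determines predictions; doubles are written at full
# precision and the round trip reproduces scores exactly.

# Doubles are archived as C99 hexadecimal floating-point literals so the
# round trip is bit-exact (decimal JSON numbers lose the last few bits).
num_to_hex <- function(x) sprintf("%a", x)
hex_to_num <- function(x) as.numeric(x)

scorer_to_list <- function(s) {
  list(w = num_to_hex(as.numeric(s$w)), b = num_to_hex(s$b),
       constant = isTRUE(s$constant))
}

#' Save an ECC model to a single JSON archive
#'
#' The archive stores the base-learner configuration, label space, seed,
#' every member's chain order, and every scorer's weight vector and
#' intercept, at full floating-point precision.
#'
#' @param model An `eccloc_ecc` model.
#' @param path Output file path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "eccloc_ecc")) abort("`model` must be an eccloc_ecc model")
  payload <- list(
    format = "eccloc_ecc",
    version = 1L,
    label_space = model$label_space,
    m = model$m,
    seed = model$seed,
    n_features = model$n_features,
    feature_names = model$feature_names,
    base = model$base,
    config = model$config,
    members = lapply(model$members, function(mem) {
      list(chain_order = mem$chain_order,
           scorers = lapply(mem$scorers, scorer_to_list))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load an ECC model saved with [save_model()]
#'
#' @param path Path to the JSON archive.
#' @return An `eccloc_ecc` model whose predictions reproduce the saved
#'   model's exactly.
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  if (!identical(p$format, "eccloc_ecc")) {
    abort(sprintf("'%s' is not an ECC model archive", path))
  }
  members <- lapply(p$members, function(mem) {
    structure(
      list(label_space = p$label_space,
           chain_order = as.integer(mem$chain_order),
           scorers = lapply(mem$scorers, function(s) {
             list(w = hex_to_num(unlist(s$w)), b = hex_to_num(s$b),
                  constant = isTRUE(s$constant))
           }),
           n_features = as.integer(p$n_features),
           feature_names = p$feature_names,
           base = p$base, config = p$config),
      class = "eccloc_cc"
    )
  })
  structure(
    list(members = members, label_space = p$label_space, m = as.integer(p$m),
         seed = as.integer(p$seed), n_features = as.integer(p$n_features),
         feature_names = p$feature_names, base = p$base, config = p$config),
    class = "eccloc_ecc"
  )
}
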