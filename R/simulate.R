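# Seeded synthetic-data generator. It emulates the structure the GO-feature
# pipeline assumes: each location owns a disjoint set of signature GO terms,
# and a protein's homologs carry the signature terms of the protein's
# locations (with a configurable per-label reliability), plus uniform noise
# terms. A configurable fraction of proteins carries a fixed co-occurring
# location pair, so label dependence exists for classifier chains to exploit.

default_location_names <- c("cell_membrane", "cell_wall", "cytoplasm",
                            "extracell", "periplasm", "cell_inner_membrane",
                            "cell_outer_membrane", "fimbrium")

go_term_id <- function(k) sprintf("GO:%07d", k)

#' Simulate a synthetic localization world
#'
#' Generates a complete, self-consistent input set for the pipeline: location
#' labels, homology hits (including sub-threshold decoy hits), a GO
#' annotation table, and random protein sequences (so the dipeptide backup
#' path is always exercisable). Regeneration from the same seed and
#' parameters is bit-identical.
#'
#' Each location gets `terms_per_label` dedicated signature GO terms, disjoint
#' across locations. Every homolog of a protein carries each signature term
#' of each of the protein's locations independently with probability
#' `signature_strength` (scalar, or one value per label), plus `noise_terms`
#' terms drawn uniformly from a shared noise vocabulary. With strength 1 and
#' no noise the GO vector of every protein is exactly 1 on its locations'
#' signature columns and 0 elsewhere.
#'
#' `round(multi_label_fraction * n_proteins)` proteins receive the fixed
#' co-occurring location pair `pair`; the rest carry one location. With
#' `pair_exclusive = TRUE` the pair's locations never occur alone, making the
#' second pair member deterministically dependent on the first.
#'
#' @param n_proteins Number of proteins (>= 3). Default 60.
#' @param n_labels Number of locations (>= 2). Default 4.
#' @param multi_label_fraction Fraction of proteins carrying the location
#'   pair. Default `4/60`, mirroring the gram-positive benchmark composition
#'   (4 dual-location proteins among 60).
#' @param signature_strength Probability that a homolog carries each
#'   signature term of its protein's locations; scalar or per-label vector in
#'   `[0, 1]`. Default 1.
#' @param noise_terms Number of noise GO terms per homolog. Default 0.
#' @param homolog_range Integer range (length 2) for the per-protein number
#'   of above-threshold homologs. Default `c(3, 6)`.
#' @param terms_per_label Signature GO terms per location. Default 3.
#' @param noise_vocabulary Size of the shared noise-term vocabulary.
#'   Default 30.
#' @param decoy_hits Sub-threshold (similarity < 60) hits per protein; they
#'   must be removed by the typical-homolog filter. Default 1.
#' @param pair Integer indices (length 2) of the co-occurring location pair.
#'   Default `c(1, 2)`.
#' @param pair_exclusive If `TRUE`, the pair's locations appear only
#'   together. Default `FALSE`.
#' @param seed Integer seed; all tables are reproducible from it.
#' @return An object of class `eccloc_world`: a list with `label_space`,
#'   `signatures`, `labels`, `hits`, `annotations`, `sequences`, `params`,
#'   `seed`.
#' @export
simulate_world <- function(n_proteins = 60, n_labels = 4,
                           multi_label_fraction = 4 / 60,
                           signature_strength = 1, noise_terms = 0,
                           homolog_range = c(3, 6), terms_per_label = 3,
                           noise_vocabulary = 30, decoy_hits = 1,
                           pair = c(1, 2), pair_exclusive = FALSE, seed = 1) {
  check_scalar_number(n_proteins, "n_proteins", lower = 3)
  check_scalar_number(n_labels, "n_labels", lower = 2)
  check_scalar_number(multi_label_fraction, "multi_label_fraction", 0, 1)
  check_scalar_number(noise_terms, "noise_terms", lower = 0)
  if (noise_terms > noise_vocabulary) {
    abort("`noise_terms` per homolog exceeds the noise vocabulary size")
  }
  strength <- rep_len(signature_strength, n_labels)
  if (any(strength < 0 | strength > 1)) {
    abort("`signature_strength` values must lie in [0, 1]")
  }
  if (length(pair) != 2L || anyDuplicated(pair) ||
      any(pair < 1) || any(pair > n_labels)) {
    abort("`pair` must be two distinct label indices")
  }
  label_space <- if (n_labels <= length(default_location_names)) {
    default_location_names[seq_len(n_labels)]
  } else {
    c(default_location_names,
      sprintf("location_%02d", seq_len(n_labels - length(default_location_names)) +
                length(default_location_names)))
  }

  signatures <- tibble(
    location = rep(label_space, each = terms_per_label),
    go_id = go_term_id(seq_len(n_labels * terms_per_label))
  )
  noise_vocab <- go_term_id(1000000L + seq_len(noise_vocabulary))
  sig_by_label <- split(signatures$go_id, signatures$location)

  withr::with_seed(seed, {
    ids <- sprintf("PROT%04d", seq_len(n_proteins))
    n_multi <- round(multi_label_fraction * n_proteins)
    single_pool <- if (pair_exclusive) setdiff(seq_len(n_labels), pair)
                   else seq_len(n_labels)
    if (!length(single_pool)) abort("no locations left for single-label proteins")
    multi_idx <- if (n_multi > 0) sort(sample.int(n_proteins, n_multi)) else integer()
    singles <- sample(rep_len(single_pool, n_proteins - n_multi))
    Y <- vector("list", n_proteins)
    Y[multi_idx] <- list(label_space[pair])
    Y[setdiff(seq_len(n_proteins), multi_idx)] <-
      lapply(singles, function(l) label_space[l])

    hit_rows <- list()
    ann_rows <- list()
    for (i in seq_len(n_proteins)) {
      n_h <- sample(homolog_range[1]:homolog_range[2], 1L)
      acc <- sprintf("HOM_%s_%02d", ids[i], seq_len(n_h))
      sims <- round(stats::runif(n_h, 65, 100), 1)
      dec_acc <- if (decoy_hits > 0) {
        sprintf("DEC_%s_%02d", ids[i], seq_len(decoy_hits))
      } else character()
      dec_sims <- if (decoy_hits > 0) round(stats::runif(decoy_hits, 20, 59), 1)
                  else numeric()
      hit_rows[[i]] <- tibble(
        query_id = ids[i],
        subject_accession = c(acc, dec_acc),
        similarity_pct = c(sims, dec_sims),
        evalue = 10^-round(stats::runif(n_h + decoy_hits, 5, 50), 2)
      )
      lab_idx <- match(Y[[i]], label_space)
      for (k in seq_len(n_h)) {
        terms <- character()
        for (l in lab_idx) {
          sig <- sig_by_label[[label_space[l]]]
          keep <- stats::runif(length(sig)) <= strength[l]
          terms <- c(terms, sig[keep])
        }
        if (noise_terms > 0) {
          terms <- c(terms, sample(noise_vocab, noise_terms))
        }
        if (length(terms)) {
          ann_rows[[length(ann_rows) + 1L]] <-
            tibble(accession = acc[k], go_id = terms)
        }
      }
      if (noise_terms > 0 && decoy_hits > 0) {
        for (dk in dec_acc) {
          ann_rows[[length(ann_rows) + 1L]] <-
            tibble(accession = dk, go_id = sample(noise_vocab, noise_terms))
        }
      }
    }
    sequences <- tibble(
      protein_id = ids,
      sequence = vapply(seq_len(n_proteins), function(i) {
        paste(sample(amino_acids, sample(120:300, 1L), replace = TRUE),
              collapse = "")
      }, character(1))
    )
  })

  structure(
    list(
      label_space = label_space,
      signatures = signatures,
      labels = tibble(protein_id = ids, labels = Y),
      hits = dplyr::bind_rows(hit_rows),
      annotations = dplyr::distinct(dplyr::bind_rows(ann_rows)),
      sequences = sequences,
      params = list(n_proteins = n_proteins, n_labels = n_labels,
                    multi_label_fraction = multi_label_fraction,
                    signature_strength = strength, noise_terms = noise_terms,
                    homolog_range = homolog_range,
                    terms_per_label = terms_per_label,
                    noise_vocabulary = noise_vocabulary,
                    decoy_hits = decoy_hits, pair = pair,
                    pair_exclusive = pair_exclusive),
      seed = as.integer(seed)
    ),
    class = "eccloc_world"
  )
}

#' @export
print.eccloc_world <- function(x, ...) {
  n_multi <- sum(lengths(x$labels$labels) > 1L)
  cat(sprintf("<synthetic world: %d proteins (%d multi-location) over %d locations, seed %d>\n",
              nrow(x$labels), n_multi, length(x$label_space), x$seed))
  cat(sprintf("  %d hits, %d annotation pairs, %d signature terms\n",
              nrow(x$hits), nrow(x$annotations), nrow(x$signatures)))
  invisible(x)
}

#' Write a synthetic world to disk
#'
#' Materializes the world as the pipeline's standard file formats:
#' `labels.tsv`, `hits.tsv` (12-column tabular), `annotations.tsv`,
#' `sequences.fasta`, `signatures.tsv`, and a `manifest.json` recording the
#' seed and generator parameters.
#'
#' @param world An `eccloc_world` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_labels(world$labels, file.path(dir, "labels.tsv"))
  write_hits(world$hits, file.path(dir, "hits.tsv"))
  write_annotations(world$annotations, file.path(dir, "annotations.tsv"))
  write_fasta(world$sequences, file.path(dir, "sequences.fasta"))
  readr::write_tsv(world$signatures, file.path(dir, "signatures.tsv"))
  jsonlite::write_json(list(seed = world$seed, params = world$params,
                            label_space = world$label_space),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
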