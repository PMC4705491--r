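# Backup sequence encoder: 20 amino acid composition frequencies followed by
# 400 adjacent-dipeptide frequencies (420 dimensions in total), used for
# proteins that cannot be represented by GO frequency vectors.

# The 20 standard residues in alphabetical one-letter order; this fixed order
# defines both the AAC block and the row-major dipeptide block.
amino_acids <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

dipeptide_names <- as.vector(t(outer(amino_acids, amino_acids, paste0)))

#' Clean a protein sequence for composition counting
#'
#' Uppercases the sequence and deletes every character that is not one of the
#' 20 standard one-letter amino acid codes (so B, J, O, U, X, Z, gaps and stop
#' symbols are removed). Adjacency for dipeptide counting is evaluated on the
#' cleaned string.
#'
#' @param sequence A single protein sequence string.
#' @return The cleaned sequence string.
#' @export
clean_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    abort("`sequence` must be a single string")
  }
  stringr::str_remove_all(toupper(sequence),
                          sprintf("[^%s]", paste(amino_acids, collapse = "")))
}

#' Amino acid composition of one sequence
#'
#' Frequencies of the 20 standard residues, in fixed alphabetical one-letter
#' order, computed on the cleaned sequence.
#'
#' @inheritParams clean_sequence
#' @return A named numeric vector of length 20 summing to 1.
#' @export
#' @examples
#' compute_aac("ACDC")[c("A", "C", "D")]
compute_aac <- function(sequence) {
  s <- clean_sequence(sequence)
  if (nchar(s) == 0L) {
    abort("sequence is empty after removing nonstandard residues")
  }
  idx <- match(strsplit(s, "")[[1]], amino_acids)
  setNames(tabulate(idx, nbins = 20L) / length(idx), amino_acids)
}

#' 420-dimensional amino acid plus dipeptide composition
#'
#' Positions 1-20 are the amino acid composition; positions 21-420 are the
#' frequencies of the 400 ordered adjacent residue pairs, enumerated row-major
#' in the same alphabetical residue order (AA, AC, ..., YY), each divided by
#' the number of adjacent pairs (cleaned length minus 1).
#'
#' @inheritParams clean_sequence
#' @return A named numeric vector of length 420; the first 20 entries sum to
#'   1 and the remaining 400 sum to 1.
#' @export
#' @examples
#' v <- compute_dipeptide_vector("ACD")
#' v[v > 0]
compute_dipeptide_vector <- function(sequence) {
  s <- clean_sequence(sequence)
  if (nchar(s) < 2L) {
    abort(paste("cleaned sequence has fewer than 2 residues;",
                "neither composition block is defined"))
  }
  idx <- match(strsplit(s, "")[[1]], amino_acids)
  aac <- setNames(tabulate(idx, nbins = 20L) / length(idx), amino_acids)
  a <- idx[-length(idx)]
  b <- idx[-1]
  pair_counts <- tabulate(20L * (a - 1L) + b, nbins = 400L)
  dip <- setNames(pair_counts / (length(idx) - 1L), dipeptide_names)
  c(aac, dip)
}

#' Dipeptide feature matrix for a set of proteins
#'
#' @param seqs A data frame with columns `protein_id` and `sequence`.
#' @return A dense numeric matrix with one 420-dimensional row per protein,
#'   protein ids as row names, and the residue/dipeptide legend as column
#'   names.
#' @export
dipeptide_feature_matrix <- function(seqs) {
  mat <- t(vapply(seqs$sequence, compute_dipeptide_vector,
                  numeric(420L), USE.NAMES = FALSE))
  dimnames(mat) <- list(seqs$protein_id, c(amino_acids, dipeptide_names))
  mat
}
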