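# Consensus sequences and occurrence feature groups (AAO, SSEO).

#' Evolutionary consensus sequence of a PSSM profile
#'
#' Replaces each residue by the amino acid with the maximal substitution
#' score in its profile row.  Ties are broken by the lowest column index
#' in the fixed [aa_alphabet()] order, so the result is deterministic.
#' The consensus depends only on per-row argmax positions, so any strictly
#' monotone rescaling of a row leaves it unchanged.
#'
#' @param profile A normalized [evolutionary_profile()].
#' @return Character scalar: the consensus sequence (length L).
#' @export
evolutionary_consensus <- function(profile) {
  stopifnot(inherits(profile, "evo_profile"))
  paste(aa_alphabet()[max.col(profile$matrix, ties.method = "first")],
        collapse = "")
}

#' Occurrence counts of symbols along a consensus sequence
#'
#' Raw counts of each alphabet symbol, in alphabet order.  Counts are not
#' divided by the sequence length: occurrence deliberately retains length
#' information that composition would discard.  Symbols outside the
#' alphabet (e.g. B, Z, X, U in a sequence) contribute no count.
#'
#' @param letters A single string.
#' @param alphabet Ordered character vector of counted symbols; defaults
#'   to the 20 amino acids.
#' @return Named integer vector of length `length(alphabet)`.
#' @export
#' @examples
#' occurrence_counts("HHECC", ss_alphabet())
occurrence_counts <- function(letters, alphabet = aa_alphabet()) {
  chars <- strsplit(as.character(letters), "")[[1]]
  tab <- table(factor(chars, levels = alphabet))
  stats::setNames(as.integer(tab), alphabet)
}
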