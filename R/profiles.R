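#' Amino-acid column order used by all evolutionary profiles
#'
#' The fixed 20-symbol column order of PSI-BLAST ASCII PSSM output
#' (`A R N D C Q E G H I L K M F P S T W Y V`).  Every profile in a dataset
#' uses this order, so features extracted from different proteins are
#' column-aligned by construction.
#'
#' @return Character vector of the 20 standard amino-acid one-letter codes.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Secondary-structure state order
#'
#' Column order (H, E, C) used for all structural profile matrices:
#' helix, strand, coil.
#'
#' @return Character vector `c("H", "E", "C")`.
#' @export
ss_alphabet <- function() c("H", "E", "C")

#' The four SCOP structural classes
#'
#' Canonical labels for the four top-level structural classes, in the
#' order used throughout the package (confusion-matrix rows, generator
#' output, plots).
#'
#' @return Character vector
#'   `c("all-alpha", "all-beta", "alpha/beta", "alpha+beta")`.
#' @export
structural_classes <- function() {
  c("all-alpha", "all-beta", "alpha/beta", "alpha+beta")
}

#' Construct an evolutionary (PSSM-derived) profile
#'
#' Bundles a protein sequence with its L x 20 substitution-score matrix.
#' The matrix is the log-odds block of a PSI-BLAST PSSM, either raw
#' (as parsed) or min-max normalized to \[0, 1\]; all feature extraction
#' expects the normalized form (see [normalize_profile()]).
#'
#' @param protein_id Identifier string.
#' @param sequence Amino-acid sequence (single string).  Non-standard
#'   residues (B, Z, X, U) are accepted.
#' @param matrix Numeric L x 20 matrix, columns in [aa_alphabet()] order.
#' @param normalized Logical; whether `matrix` has already been min-max
#'   normalized.
#' @return An object of class `evo_profile`.
#' @export
evolutionary_profile <- function(protein_id, sequence, matrix,
                                 normalized = FALSE) {
  sequence <- as.character(sequence)
  stopifnot(length(sequence) == 1L, nchar(sequence) >= 1L)
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix) || ncol(matrix) != 20L) {
    rlang::abort("`matrix` must be a numeric L x 20 matrix.")
  }
  if (nrow(matrix) != nchar(sequence)) {
    rlang::abort(sprintf(
      "matrix has %d rows but sequence '%s' has length %d",
      nrow(matrix), protein_id, nchar(sequence)))
  }
  if (any(!is.finite(matrix))) {
    rlang::abort("profile matrix contains non-finite entries")
  }
  colnames(matrix) <- aa_alphabet()
  structure(
    list(protein_id = as.character(protein_id),
         sequence = sequence,
         matrix = matrix,
         normalized = isTRUE(normalized)),
    class = "evo_profile")
}

#' Construct a secondary-structure profile
#'
#' Holds the L x 3 state-probability matrix (columns H, E, C) from a
#' secondary-structure predictor together with the predicted per-residue
#' state string (the structural consensus).  If `consensus` is omitted it
#' is derived as the per-row argmax, ties broken in H > E > C order.
#'
#' @param protein_id Identifier string.
#' @param matrix Numeric L x 3 matrix of state probabilities in \[0, 1\],
#'   columns in (H, E, C) order.
#' @param consensus Optional string over `{H, E, C}` of length L.  When a
#'   predictor supplies its own state calls they take precedence over the
#'   row argmax.
#' @return An object of class `struct_profile`.
#' @export
structural_profile <- function(protein_id, matrix, consensus = NULL) {
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix) || ncol(matrix) != 3L) {
    rlang::abort("`matrix` must be a numeric L x 3 matrix (H, E, C).")
  }
  if (any(!is.finite(matrix))) {
    rlang::abort("structural profile matrix contains non-finite entries")
  }
  if (any(matrix < -1e-6) || any(matrix > 1 + 1e-6)) {
    rlang::abort("state probabilities must lie in [0, 1] (tolerance 1e-6)")
  }
  matrix <- pmin(pmax(matrix, 0), 1)
  colnames(matrix) <- ss_alphabet()
  if (is.null(consensus)) {
    consensus <- paste(ss_alphabet()[max.col(matrix, ties.method = "first")],
                       collapse = "")
  }
  consensus <- as.character(consensus)
  if (nchar(consensus) != nrow(matrix)) {
    rlang::abort("consensus length must equal the matrix row count")
  }
  if (grepl("[^HEC]", consensus)) {
    rlang::abort("consensus may contain only H, E and C")
  }
  structure(
    list(protein_id = as.character(protein_id),
         matrix = matrix,
         consensus = consensus),
    class = "struct_profile")
}

#' @export
print.evo_profile <- function(x, ...) {
  cat(sprintf("<evo_profile> %s  L=%d  %s\n", x$protein_id,
              nrow(x$matrix),
              if (x$normalized) "normalized" else "raw log-odds"))
  invisible(x)
}

#' @export
print.struct_profile <- function(x, ...) {
  cat(sprintf("<struct_profile> %s  L=%d  consensus %s...\n",
              x$protein_id, nrow(x$matrix),
              substr(x$consensus, 1, min(20, nchar(x$consensus)))))
  invisible(x)
}

#' Assemble a labeled dataset of profile pairs
#'
#' @param profiles Named list; each element is `list(evo =, struct =)` with
#'   an [evolutionary_profile()] and a [structural_profile()] (either may be
#'   `NULL` if only one profile kind is available).  Names are protein ids.
#' @param labels Tibble/data frame with columns `protein_id` and `class`
#'   (one of [structural_classes()]).
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(profiles, labels) {
  labels <- tibble::as_tibble(labels)
  stopifnot(all(c("protein_id", "class") %in% names(labels)))
  bad <- setdiff(unique(labels$class), structural_classes())
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "unknown class label(s): %s; accepted: %s",
      paste(bad, collapse = ", "),
      paste(structural_classes(), collapse = ", ")))
  }
  missing <- setdiff(labels$protein_id, names(profiles))
  if (length(missing) > 0) {
    rlang::abort(sprintf("labeled ids with no profiles: %s",
                         paste(missing, collapse = ", ")))
  }
  structure(list(profiles = profiles, labels = labels),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d proteins, %d labeled\n",
              length(x$profiles), nrow(x$labels)))
  print(table(x$labels$class))
  invisible(x)
}
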