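# Readers and writers for the external profile formats: PSI-BLAST ASCII
# PSSM, per-residue secondary-structure tables, FASTA, label tables and
# the delimited feature table.

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the per-query matrix file written by PSI-BLAST (`-out_ascii_pssm`).
#' Each residue row carries a position index, the residue letter, 20 integer
#' log-odds scores (the `PSSM_cons` block) and 20 integer percentages (the
#' `PSSM_prob` block).  The log-odds block becomes the profile matrix —
#' it is the block used for all feature extraction — and the percentage
#' block is discarded.  Header and trailing statistics lines are skipped.
#'
#' The returned matrix is raw; pass the profile through
#' [normalize_profile()] before feature extraction.
#'
#' @param path Path to the PSSM file (or a character vector of lines via
#'   `text`).
#' @param text Optional character vector of lines, used instead of `path`.
#' @param protein_id Identifier for the profile; defaults to the file name
#'   without extension.
#' @return A raw (unnormalized) [evolutionary_profile()].
#' @export
read_pssm <- function(path, text = NULL, protein_id = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  if (is.null(protein_id)) {
    protein_id <- if (is.null(text)) {
      sub("\\.[^.]*$", "", basename(path))
    } else "pssm"
  }
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    rlang::abort("empty PSSM file")
  }

  residues <- character(0)
  scores <- list()
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(tok) < 2) next
    # residue rows start with a position index then a residue letter
    if (!grepl("^[0-9]+$", tok[[1]]) || !grepl("^[A-Za-z]$", tok[[2]])) next
    # 42 tokens = index, residue, 20 log-odds, 20 percentages; real
    # PSI-BLAST output appends two per-position statistics (44 tokens)
    if (!length(tok) %in% c(42L, 44L)) {
      rlang::abort(sprintf(
        "malformed PSSM row at line %d: expected 20 log-odds and 20 percentage columns, found %d value columns",
        i, length(tok) - 2))
    }
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (any(is.na(vals))) {
      rlang::abort(sprintf("non-numeric score at line %d", i))
    }
    residues <- c(residues, toupper(tok[[2]]))
    scores[[length(scores) + 1L]] <- vals
  }
  if (length(scores) == 0) {
    rlang::abort("no residue rows found: not a PSI-BLAST ASCII PSSM?")
  }
  m <- do.call(rbind, scores)
  evolutionary_profile(protein_id, paste(residues, collapse = ""), m,
                       normalized = FALSE)
}

#' Min-max normalize a matrix to \[0, 1\]
#'
#' Maps every entry by `(x - min) / (max - min)` using the global minimum
#' and maximum of the whole matrix (per protein, not per column).  A
#' constant matrix maps to all zeros.
#'
#' @param m Numeric matrix with finite entries.
#' @return Matrix of the same shape with entries in \[0, 1\].
#' @export
#' @examples
#' normalize_min_max(matrix(c(-3, 2, 7, 0), 2))
normalize_min_max <- function(m) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) {
    rlang::abort("matrix contains non-finite entries")
  }
  lo <- min(m)
  hi <- max(m)
  if (hi == lo) {
    return(array(0, dim = dim(m), dimnames = dimnames(m)))
  }
  (m - lo) / (hi - lo)
}

#' Min-max normalize an evolutionary profile
#'
#' @param profile A raw [evolutionary_profile()].
#' @return The profile with its matrix normalized to \[0, 1\] and
#'   `normalized = TRUE`.
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "evo_profile"))
  if (profile$normalized) return(profile)
  evolutionary_profile(profile$protein_id, profile$sequence,
                       normalize_min_max(profile$matrix), normalized = TRUE)
}

#' Write a profile in PSI-BLAST ASCII PSSM format
#'
#' Inverse of [read_pssm()] for fixtures and round-trip tests.  The
#' log-odds block is the profile matrix (rounded to integers if needed);
#' the percentage block is written as zeros unless supplied.
#'
#' @param profile An [evolutionary_profile()] (raw scores).
#' @param path Output file path.
#' @param percentages Optional L x 20 integer matrix for the second block.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path, percentages = NULL) {
  stopifnot(inherits(profile, "evo_profile"))
  m <- profile$matrix
  if (is.null(percentages)) {
    percentages <- array(0L, dim = dim(m))
  }
  aa <- aa_alphabet()
  res <- strsplit(profile$sequence, "")[[1]]
  header <- c(
    "",
    "Last position-specific scoring matrix computed, weighted, observed percentages",
    paste0("            ", paste(sprintf("%3s", c(aa, aa)), collapse = "")))
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste0(sprintf("%5d %s ", i, res[[i]]),
           paste(sprintf("%3d", as.integer(round(m[i, ]))), collapse = ""),
           " ",
           paste(sprintf("%4d", as.integer(round(percentages[i, ]))),
                 collapse = ""),
           sprintf("  %5.2f %9.2f", 0, 0))
  }, character(1))
  footer <- c("", "                      K         Lambda",
              "Standard Ungapped    0.1337     0.3177")
  writeLines(c(header, rows, footer), path)
  invisible(path)
}

#' Read a per-residue secondary-structure profile table
#'
#' Parses the whitespace-delimited per-residue output of a secondary
#' structure predictor (SPINE-X style): one row per residue with a
#' position index, the residue letter, the predicted state in
#' `{H, E, C}`, and the three state probabilities in (H, E, C) order.
#' Lines starting with `#` are treated as comments.
#'
#' The file's own state column is kept as the structural consensus even
#' where it disagrees with the row argmax — it is the predictor's call.
#'
#' @param path Path to the table (or lines via `text`).
#' @param text Optional character vector of lines.
#' @param protein_id Identifier; defaults to the file name.
#' @return A [structural_profile()].
#' @export
read_structural_profile <- function(path, text = NULL, protein_id = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  if (is.null(protein_id)) {
    protein_id <- if (is.null(text)) {
      sub("\\.[^.]*$", "", basename(path))
    } else "struct"
  }
  states <- character(0)
  probs <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) < 6) {
      rlang::abort(sprintf(
        "malformed structural profile row at line %d: expected index, residue, state, 3 probabilities",
        i))
    }
    st <- tok[[3]]
    if (!st %in% ss_alphabet()) {
      rlang::abort(sprintf("unknown secondary-structure state '%s' at line %d",
                           st, i))
    }
    p <- suppressWarnings(as.numeric(tok[4:6]))
    if (any(is.na(p))) {
      rlang::abort(sprintf("non-numeric probability at line %d", i))
    }
    if (any(p < -1e-6 | p > 1 + 1e-6)) {
      rlang::abort(sprintf(
        "probability outside [0, 1] at line %d (tolerance 1e-6)", i))
    }
    states <- c(states, st)
    probs[[length(probs) + 1L]] <- p
  }
  if (length(probs) == 0) {
    rlang::abort("no residue rows found in structural profile")
  }
  structural_profile(protein_id, do.call(rbind, probs),
                     consensus = paste(states, collapse = ""))
}

#' Write a structural profile in the per-residue table format
#'
#' Probabilities are written with six decimals; [read_structural_profile()]
#' recovers them exactly when the matrix is already quantized to that
#' precision (the synthetic generator quantizes for this reason).
#'
#' @param profile A [structural_profile()].
#' @param path Output file path.
#' @param sequence Optional residue string for the second column (defaults
#'   to "X" everywhere).
#' @return `path`, invisibly.
#' @export
write_structural_profile <- function(profile, path, sequence = NULL) {
  stopifnot(inherits(profile, "struct_profile"))
  m <- profile$matrix
  L <- nrow(m)
  res <- if (is.null(sequence)) rep("X", L) else strsplit(sequence, "")[[1]]
  st <- strsplit(profile$consensus, "")[[1]]
  rows <- sprintf("%5d  %s  %s  %8.6f  %8.6f  %8.6f",
                  seq_len(L), res, st, m[, 1], m[, 2], m[, 3])
  writeLines(c("#  pos  res  state  P(H)  P(E)  P(C)", rows), path)
  invisible(path)
}

# accepted spellings for each structural class
.class_synonyms <- local({
  syn <- list(
    "all-alpha"  = c("all-alpha", "all-a", "a", "alpha", "all_alpha",
                     "all-α", "α"),
    "all-beta"   = c("all-beta", "all-b", "b", "beta", "all_beta",
                     "all-β", "β"),
    "alpha/beta" = c("alpha/beta", "a/b", "ab", "alpha_beta",
                     "α/β"),
    "alpha+beta" = c("alpha+beta", "a+b", "alpha_plus_beta",
                     "α+β"))
  stats::setNames(rep(names(syn), lengths(syn)), unlist(syn))
})

#' Normalize structural class names
#'
#' Maps accepted synonyms (`"a"`, `"all-alpha"`, `"α/β"`, ...) onto the
#' canonical labels of [structural_classes()].
#'
#' @param x Character vector of class names.
#' @return Character vector of canonical class labels.
#' @export
normalize_class_labels <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(.class_synonyms[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    rlang::abort(sprintf(
      "unknown structural class name(s): %s\naccepted names: %s",
      paste(bad, collapse = ", "),
      paste(names(.class_synonyms), collapse = ", ")))
  }
  out
}

#' Read a protein-id to structural-class label table
#'
#' Two-column delimited file (comma or tab), `protein_id` then class name;
#' a header line is detected and skipped.  Class names are normalized via
#' [normalize_class_labels()].
#'
#' @param path Path to the table (or lines via `text`).
#' @param text Optional character vector of lines.
#' @return Tibble with columns `protein_id` and `class`.
#' @export
read_labels <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) rlang::abort("empty labels file")
  parts <- strsplit(lines, "[,\t]")
  parts <- lapply(parts, trimws)
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    rlang::abort(sprintf("malformed labels row at line %d", bad[[1]]))
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  cls <- vapply(parts, `[[`, character(1), 2L)
  if (tolower(ids[[1]]) %in% c("protein_id", "id", "protein") ||
      tolower(cls[[1]]) %in% c("class", "label")) {
    ids <- ids[-1]
    cls <- cls[-1]
  }
  tibble::tibble(protein_id = ids, class = normalize_class_labels(cls))
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file (or lines via `text`).
#' @param text Optional character vector of lines.
#' @return Tibble with columns `protein_id` (first word of the header) and
#'   `sequence`.
#' @export
read_fasta_sequences <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  hdr <- grepl("^>", lines)
  if (!any(hdr)) rlang::abort("no FASTA headers found")
  idx <- cumsum(hdr)
  ids <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  seqs <- vapply(seq_along(ids), function(k) {
    paste(gsub("\\s", "", lines[idx == k & !hdr]), collapse = "")
  }, character(1))
  tibble::tibble(protein_id = ids, sequence = toupper(seqs))
}

#' Write a feature table to a delimited file
#'
#' One row per protein: `protein_id`, `class` (if present), then the
#' features in canonical group order with their stable column names.
#'
#' @param features Tibble from [extract_dataset()].
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Input path.
#' @return Tibble with `protein_id`, optional `class`, and numeric feature
#'   columns.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}
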