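# Synthetic profile generator with class-dependent statistics.  Emulates
# the two external inputs (PSI-BLAST PSSMs and per-residue secondary
# structure probability tables) so the whole pipeline is testable without
# running the external predictors.
#
# The class signal is planted primarily in the secondary-structure state
# arrangement and secondarily in state-correlated residue propensities:
#   all-alpha  : helix everywhere
#   all-beta   : strand everywhere
#   alpha/beta : alternating helix/strand runs (interleaved architecture)
#   alpha+beta : one helix block followed by one strand block (segregated)
# alpha/beta and alpha+beta share the same state *composition* and differ
# only in arrangement, which is exactly what the segmented distribution
# and segmented auto covariance groups are built to detect.

.run_length <- 8L  # helix/strand run length in the interleaved class

# residue propensity rows per secondary-structure state, aa_alphabet order
.residue_propensities <- local({
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  make <- function(boosts) {
    w <- stats::setNames(rep(1, 20), aa)
    w[names(boosts)] <- w[names(boosts)] + boosts
    w / sum(w)
  }
  rbind(
    H = make(c(A = 7, L = 5, E = 4, M = 3, Q = 2, K = 2)),  # helix formers
    E = make(c(V = 7, I = 5, F = 4, Y = 3, W = 2, T = 2)),  # strand formers
    C = make(c(G = 7, P = 5, S = 4, N = 3, D = 2)))         # coil formers
})

.rdirichlet_row <- function(k) {
  g <- stats::rgamma(k, shape = 1)
  if (sum(g) == 0) rep(1 / k, k) else g / sum(g)
}

.planted_states <- function(class, length) {
  switch(class,
    "all-alpha" = rep("H", length),
    "all-beta" = rep("E", length),
    "alpha/beta" = {
      runs <- rep(c("H", "E"),
                  length.out = ceiling(length / .run_length))
      rep(runs, each = .run_length)[seq_len(length)]
    },
    "alpha+beta" = c(rep("H", ceiling(length / 2)),
                     rep("E", length - ceiling(length / 2))),
    rlang::abort(sprintf("unknown class '%s'", class)))
}

#' Generate one synthetic protein profile pair
#'
#' Draws a structural and an evolutionary profile whose statistics depend
#' on the structural class.  Each structural row is an interpolation
#' `(1 - t) * onehot(state) + t * Dirichlet(1, 1, 1)` with
#' `t = noise / (1 + noise)`: at `noise = 0` the rows are exact state
#' indicators, and increasing noise moves them toward exchangeable
#' Dirichlet rows with no class signal.  Evolutionary rows interpolate
#' the same way between a state-specific residue-propensity row (helix
#' formers boosted under H, strand formers under E) and a flat
#' Dirichlet row, are quantized to plausible integer log-odds, and are
#' returned both raw and min-max normalized.  Uses the current RNG state;
#' seed upstream (see [generate_dataset()]).
#'
#' @param class One of [structural_classes()].
#' @param length Protein length L (>= 1).
#' @param noise Non-negative noise level; 0 is fully deterministic class
#'   signal.
#' @param protein_id Identifier for the generated profiles.
#' @return List with elements `evo` (normalized [evolutionary_profile()]),
#'   `struct` ([structural_profile()]), `evo_raw` (integer log-odds
#'   profile, for writing fixtures) and `percentages` (integer L x 20
#'   matrix for the PSSM percentage block).
#' @export
generate_protein <- function(class, length, noise = 0.3,
                             protein_id = "synthetic") {
  stopifnot(length >= 1, noise >= 0)
  class <- normalize_class_labels(class)
  t <- noise / (1 + noise)
  states <- .planted_states(class, length)

  smat <- t(vapply(states, function(s) {
    onehot <- as.numeric(ss_alphabet() == s)
    (1 - t) * onehot + t * .rdirichlet_row(3)
  }, numeric(3), USE.NAMES = FALSE))
  smat <- round(smat, 6)  # file precision, so write/read round-trips exactly
  struct <- structural_profile(protein_id, smat)

  pmat <- t(vapply(states, function(s) {
    (1 - t) * .residue_propensities[s, ] + t * .rdirichlet_row(20)
  }, numeric(20), USE.NAMES = FALSE))
  dimnames(pmat) <- NULL
  raw <- round(40 * pmat) - 4  # plausible integer log-odds range
  seq <- paste(aa_alphabet()[max.col(pmat, ties.method = "first")],
               collapse = "")
  evo_raw <- evolutionary_profile(protein_id, seq, raw, normalized = FALSE)
  list(evo = normalize_profile(evo_raw),
       struct = struct,
       evo_raw = evo_raw,
       percentages = round(100 * pmat))
}

#' Generate a balanced labeled synthetic dataset
#'
#' Draws `n_per_class` proteins for each of the four structural classes
#' with lengths uniform on `length_range`, reproducibly from `seed`.
#' Optionally writes each protein's PSSM and structural profile in the
#' external file formats plus a `labels.csv`, valid for the package's own
#' parsers — the fixture path used by round-trip tests.
#'
#' @param n_per_class Proteins per class (default 25).
#' @param length_range Integer `c(min, max)` protein length, default
#'   50 ... 150.
#' @param noise Noise level, see [generate_protein()]; default 0.3.
#' @param seed Integer seed; equal seeds give identical datasets.
#' @param write_dir Optional directory for on-disk fixture files.
#' @return A [labeled_dataset()].
#' @export
generate_dataset <- function(n_per_class = 25, length_range = c(50, 150),
                             noise = 0.3, seed = 1, write_dir = NULL) {
  stopifnot(n_per_class >= 1, length_range[[1]] >= 1,
            length_range[[2]] >= length_range[[1]])
  classes <- structural_classes()
  profiles <- list()
  labels <- list()
  withr::with_seed(seed, {
    stems <- c("all-alpha" = "alla", "all-beta" = "allb",
               "alpha/beta" = "ab", "alpha+beta" = "apb")
    for (cl in classes) {
      stem <- stems[[cl]]
      for (i in seq_len(n_per_class)) {
        id <- sprintf("%s_%03d", stem, i)
        L <- sample(seq(length_range[[1]], length_range[[2]]), 1)
        p <- generate_protein(cl, L, noise, protein_id = id)
        profiles[[id]] <- p
        labels[[id]] <- tibble::tibble(protein_id = id, class = cl)
      }
    }
  })
  ds <- labeled_dataset(profiles, dplyr::bind_rows(labels))
  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(ds$profiles)) {
      p <- ds$profiles[[id]]
      write_pssm(p$evo_raw, file.path(write_dir, paste0(id, ".pssm")),
                 percentages = p$percentages)
      write_structural_profile(p$struct,
                               file.path(write_dir, paste0(id, ".ss")),
                               sequence = p$evo_raw$sequence)
    }
    utils::write.table(ds$labels, file.path(write_dir, "labels.csv"),
                       sep = ",", quote = FALSE, row.names = FALSE)
  }
  ds
}

#' Load a dataset from profile files on disk
#'
#' Reads `<id>.pssm` and `<id>.ss` files plus a `labels.csv` from a
#' directory — the inverse of `generate_dataset(write_dir = ...)`, and the
#' entry point for real PSI-BLAST / secondary-structure predictor output
#' laid out the same way.
#'
#' @param dir Directory containing the files.
#' @return A [labeled_dataset()] with normalized evolutionary profiles.
#' @export
read_dataset <- function(dir) {
  labels <- read_labels(file.path(dir, "labels.csv"))
  profiles <- lapply(labels$protein_id, function(id) {
    evo <- read_pssm(file.path(dir, paste0(id, ".pssm")), protein_id = id)
    struct <- read_structural_profile(file.path(dir, paste0(id, ".ss")),
                                      protein_id = id)
    list(evo = normalize_profile(evo), struct = struct, evo_raw = evo)
  })
  names(profiles) <- labels$protein_id
  labeled_dataset(profiles, labels)
}
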