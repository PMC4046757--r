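# Assembly of the canonical feature vectors (PSSM-S, SPINE-S, combined)
# and whole-dataset feature tables.

.pssm_groups <- c("AAO", "PSSM_AAC", "PSSM_SD", "PSSM_SAC")
.spine_groups <- c("SSEO", "SPINE_SSEC", "SPINE_SD", "SPINE_SAC")

#' Feature-extraction configuration
#'
#' Collects the tunable parameters of the extraction pipeline.  Defaults
#' are the adopted operating point: distance factors K = 4 for both
#' profile kinds and distribution factor F = 25 (four cumulative-mass
#' segments per column).
#'
#' @param kp Distance factor (maximum auto covariance lag) for the PSSM,
#'   integer 1..10.
#' @param ks Distance factor for the structural matrix, integer 1..10.
#' @param fp Distribution factor (percent) for the PSSM; must divide 50.
#' @param fs Distribution factor for the structural matrix.
#' @param normalize_distribution Divide distribution boundary indices by
#'   the protein length (default `TRUE`).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(kp = 4, ks = 4, fp = 25, fs = 25,
                           normalize_distribution = TRUE) {
  for (K in c(kp, ks)) {
    if (K != round(K) || K < 1 || K > 10) {
      rlang::abort("distance factors must be integers in 1..10")
    }
  }
  for (F in c(fp, fs)) {
    if (F <= 0 || 50 %% F != 0) {
      rlang::abort("distribution factors must divide 50 (5, 10 or 25)")
    }
  }
  structure(list(kp = as.integer(kp), ks = as.integer(ks),
                 fp = fp, fs = fs,
                 normalize_distribution = isTRUE(normalize_distribution)),
            class = "feature_config")
}

.match_scheme <- function(scheme) {
  scheme <- tolower(gsub("_", "-", scheme))
  switch(scheme,
         "pssm-s" = "pssm-s",
         "spine-s" = "spine-s",
         "combined" = ,
         "pssm-spine-s" = "pssm-spine-s",
         rlang::abort(
           "scheme must be one of 'pssm-s', 'spine-s', 'pssm-spine-s' (alias 'combined')"))
}

.scheme_groups <- function(scheme) {
  switch(scheme,
         "pssm-s" = .pssm_groups,
         "spine-s" = .spine_groups,
         "pssm-spine-s" = c(.pssm_groups, .spine_groups))
}

#' Expected feature-vector width for a scheme and configuration
#'
#' Widths depend only on the configuration, never on protein length:
#' PSSM-S has `20 + 20 + 20 * 100/fp + 20 * 5 * kp` features (520 at the
#' defaults), SPINE-S `3 + 3 + 3 * 100/fs + 3 * 5 * ks` (78), and the
#' combined scheme their sum (598).
#'
#' @param scheme `"pssm-s"`, `"spine-s"` or `"pssm-spine-s"`/`"combined"`.
#' @param config A [feature_config()].
#' @param groups Optional subset of group names (for ablations).
#' @return Integer width.
#' @export
feature_width <- function(scheme = "pssm-spine-s", config = feature_config(),
                          groups = NULL) {
  scheme <- .match_scheme(scheme)
  groups <- groups %||% .scheme_groups(scheme)
  w <- c(AAO = 20, PSSM_AAC = 20,
         PSSM_SD = 20 * 100 / config$fp, PSSM_SAC = 20 * 5 * config$kp,
         SSEO = 3, SPINE_SSEC = 3,
         SPINE_SD = 3 * 100 / config$fs, SPINE_SAC = 3 * 5 * config$ks)
  as.integer(sum(w[groups]))
}

#' Extract the feature vector of one protein
#'
#' Computes the requested feature groups from a normalized evolutionary
#' profile and (unless the scheme is PSSM-only) a structural profile, and
#' concatenates them in the canonical order AAO, PSSM-AAC, PSSM-SD,
#' PSSM-SAC, SSEO, SPINE-SSEC, SPINE-SD, SPINE-SAC.  The result is
#' deterministic: identical inputs give identical vectors.
#'
#' @param evo An [evolutionary_profile()]; normalized automatically if raw.
#' @param struct A [structural_profile()], required unless the scheme (or
#'   `groups`) needs no structural features.
#' @param scheme Feature scheme (see [feature_width()]).
#' @param config A [feature_config()].
#' @param groups Optional character subset of the scheme's groups, kept in
#'   canonical order — the group-mask used by ablation experiments.
#' @return Named numeric vector of class `feature_vector` with attributes
#'   `scheme` and `group_spans` (group -> c(offset, length)).
#' @export
extract_features <- function(evo, struct = NULL, scheme = "pssm-spine-s",
                             config = feature_config(), groups = NULL) {
  scheme <- .match_scheme(scheme)
  all_groups <- .scheme_groups(scheme)
  if (is.null(groups)) {
    groups <- all_groups
  } else {
    bad <- setdiff(groups, c(.pssm_groups, .spine_groups))
    if (length(bad) > 0) {
      rlang::abort(sprintf("unknown feature group(s): %s",
                           paste(bad, collapse = ", ")))
    }
    groups <- intersect(c(.pssm_groups, .spine_groups), groups)  # canonical order
  }

  need_evo <- any(groups %in% .pssm_groups)
  need_struct <- any(groups %in% .spine_groups)
  if (need_evo && is.null(evo)) {
    rlang::abort("scheme requires an evolutionary profile")
  }
  if (need_struct && is.null(struct)) {
    rlang::abort("scheme requires a structural profile")
  }
  if (need_evo) {
    stopifnot(inherits(evo, "evo_profile"))
    evo <- normalize_profile(evo)
  }
  if (need_evo && need_struct &&
      nrow(evo$matrix) != nrow(struct$matrix)) {
    rlang::abort(sprintf(
      "protein '%s': evolutionary profile has L=%d but structural profile has L=%d",
      evo$protein_id, nrow(evo$matrix), nrow(struct$matrix)))
  }

  pieces <- list()
  for (g in groups) {
    v <- switch(g,
      AAO = {
        cnt <- occurrence_counts(evolutionary_consensus(evo), aa_alphabet())
        stats::setNames(as.numeric(cnt), paste0("AAO_", names(cnt)))
      },
      PSSM_AAC = {
        s <- semi_composition(evo$matrix)
        stats::setNames(as.numeric(s), paste0("PSSM_AAC_", names(s)))
      },
      PSSM_SD = {
        v <- segmented_distribution(evo$matrix, F = config$fp,
                                    normalize = config$normalize_distribution)
        stats::setNames(as.numeric(v), paste0("PSSM_SD_", names(v)))
      },
      PSSM_SAC = {
        v <- segmented_auto_covariance(evo$matrix, K = config$kp)
        stats::setNames(as.numeric(v), paste0("PSSM_SAC_", names(v)))
      },
      SSEO = {
        cnt <- occurrence_counts(struct$consensus, ss_alphabet())
        stats::setNames(as.numeric(cnt), paste0("SSEO_", names(cnt)))
      },
      SPINE_SSEC = {
        s <- semi_composition(struct$matrix)
        stats::setNames(as.numeric(s), paste0("SPINE_SSEC_", names(s)))
      },
      SPINE_SD = {
        v <- segmented_distribution(struct$matrix, F = config$fs,
                                    normalize = config$normalize_distribution)
        stats::setNames(as.numeric(v), paste0("SPINE_SD_", names(v)))
      },
      SPINE_SAC = {
        v <- segmented_auto_covariance(struct$matrix, K = config$ks)
        stats::setNames(as.numeric(v), paste0("SPINE_SAC_", names(v)))
      })
    pieces[[g]] <- v
  }
  lens <- lengths(pieces)
  offsets <- cumsum(c(0, lens[-length(lens)]))
  spans <- purrr::map2(offsets, lens, ~c(offset = unname(.x), length = unname(.y)))
  names(spans) <- names(pieces)
  structure(unlist(unname(pieces)),
            scheme = scheme, group_spans = spans,
            class = c("feature_vector", "numeric"))
}

#' Extract a feature table for a whole dataset
#'
#' Applies [extract_features()] to every protein of a [labeled_dataset()]
#' and returns a tibble with one row per protein: `protein_id`, `class`
#' (where labeled; `NA` otherwise) and the feature columns in canonical
#' order.  The width is constant across proteins of any length.  Errors in
#' a single protein are rethrown with its id attached.
#'
#' @param dataset A [labeled_dataset()], or a named list of
#'   `list(evo =, struct =)` profile pairs.
#' @param scheme,config,groups Passed to [extract_features()].
#' @return A tibble, `n_proteins` x `(2 + width)`.
#' @export
extract_dataset <- function(dataset, scheme = "pssm-spine-s",
                            config = feature_config(), groups = NULL) {
  if (inherits(dataset, "labeled_dataset")) {
    profiles <- dataset$profiles
    labels <- dataset$labels
  } else {
    profiles <- dataset
    labels <- tibble::tibble(protein_id = character(0), class = character(0))
  }
  scheme <- .match_scheme(scheme)
  if (length(profiles) == 0) {
    empty_names <- .feature_names(scheme, config, groups)
    out <- c(list(protein_id = character(0), class = character(0)),
             stats::setNames(rep(list(numeric(0)), length(empty_names)),
                             empty_names))
    return(tibble::as_tibble(out))
  }
  rows <- purrr::imap(profiles, function(p, id) {
    fv <- tryCatch(
      extract_features(p$evo, p$struct, scheme = scheme,
                       config = config, groups = groups),
      error = function(e) {
        rlang::abort(sprintf("protein '%s': %s", id, conditionMessage(e)),
                     parent = e)
      })
    tibble::as_tibble_row(stats::setNames(as.numeric(fv), names(fv)))
  })
  feats <- dplyr::bind_rows(rows)
  out <- dplyr::bind_cols(
    tibble::tibble(protein_id = names(profiles)), feats)
  dplyr::left_join(out, labels, by = "protein_id") |>
    dplyr::relocate("class", .after = "protein_id")
}

# canonical column names for an empty table
.feature_names <- function(scheme, config, groups = NULL) {
  L <- 4  # any small length works: names do not depend on L
  evo <- evolutionary_profile(
    "template", "ACDE", matrix(seq_len(L * 20), L, 20))
  struct <- structural_profile("template", matrix(1 / 3, L, 3))
  names(extract_features(evo, struct, scheme, config, groups))
}

#' Map feature-table columns to their feature groups
#'
#' @param feature_names Character vector of feature column names.
#' @return Character vector of group names (`NA` for non-feature columns
#'   such as `protein_id`).
#' @export
feature_groups_of <- function(feature_names) {
  all_groups <- c(.pssm_groups, .spine_groups)
  # longest prefixes first so PSSM_SAC is not shadowed by PSSM_AAC etc.
  ord <- order(nchar(all_groups), decreasing = TRUE)
  out <- rep(NA_character_, length(feature_names))
  for (g in all_groups[ord]) {
    hit <- is.na(out) & startsWith(feature_names, paste0(g, "_"))
    out[hit] <- g
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
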