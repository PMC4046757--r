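# Cumulative-mass segmentation of profile columns and the segmented
# distribution feature groups (PSSM-SD, SPINE-SD).

#' Cumulative-mass segment boundaries of one profile column
#'
#' For a non-negative column with total mass `T`, finds for each
#' k = 1 ... 50/F the maximal prefix length `I_k` (counting rows from the
#' top) whose cumulative mass is less than or equal to `k * F%` of `T`;
#' "less than or equal" means a prefix whose mass exactly equals the
#' threshold is included.  The same scan is repeated from the bottom row
#' upward, giving `bottom` as counts of rows from the last row.  An index
#' may be 0 when the first row alone already exceeds the threshold, and a
#' zero-mass column yields all-zero indices.
#'
#' @param column Non-negative numeric vector (one column of a normalized
#'   profile matrix).
#' @param F Distribution factor, a percentage that must divide 50
#'   (supported values 5, 10, 25).
#' @return List of class `segment_boundaries` with elements `total_mass`,
#'   `factor`, `top` and `bottom` (each an integer vector of length
#'   `50 / F`, values in `0 ... L`).
#' @export
#' @examples
#' boundary_indices(c(0.5, 0.3, 0.1, 0.1), F = 25)
boundary_indices <- function(column, F = 25) {
  if (length(F) != 1 || !is.finite(F) || F <= 0 || 50 %% F != 0) {
    rlang::abort("distribution factor F must be a positive divisor of 50 (5, 10 or 25)")
  }
  column <- as.numeric(column)
  if (any(!is.finite(column)) || any(column < 0)) {
    rlang::abort("column entries must be finite and non-negative")
  }
  n_seg <- as.integer(50 / F)
  total <- sum(column)
  scan <- function(x) {
    if (total == 0) return(rep(0L, n_seg))
    cs <- cumsum(x)
    vapply(seq_len(n_seg), function(k) {
      thr <- (k * F / 100) * total
      sum(cs <= thr)  # prefix length 0 has mass 0 and always qualifies
    }, integer(1))
  }
  structure(
    list(total_mass = total, factor = F,
         top = scan(column), bottom = scan(rev(column))),
    class = "segment_boundaries")
}

#' Segmented distribution features of a profile matrix
#'
#' For each column of the L x m matrix, computes the cumulative-mass
#' boundary indices from both sequence ends ([boundary_indices()]) and
#' emits them — divided by L, so each feature is a normalized segment
#' length in \[0, 1\] — in the order: top segments k = 1 ... 50/F, then
#' bottom segments k = 1 ... 50/F.  Columns are emitted in their fixed
#' matrix order, giving `m * 100/F` features in total (80 for a PSSM at
#' F = 25, 12 for a structural matrix).
#'
#' Features depend only on the relative mass profile of a column:
#' multiplying a column by any positive constant leaves them unchanged.
#'
#' @param m Non-negative numeric L x m matrix (normalized profile).
#' @param F Distribution factor (see [boundary_indices()]).
#' @param normalize If `TRUE` (default) divide boundary indices by L;
#'   `FALSE` emits the raw row counts, for sensitivity checks.
#' @return Named numeric vector of length `m * 100/F`.
#' @export
segmented_distribution <- function(m, F = 25, normalize = TRUE) {
  m <- as.matrix(m)
  L <- nrow(m)
  n_seg <- as.integer(50 / F)
  cols <- colnames(m)
  if (is.null(cols)) cols <- as.character(seq_len(ncol(m)))
  out <- lapply(seq_len(ncol(m)), function(j) {
    b <- boundary_indices(m[, j], F)
    v <- c(b$top, b$bottom)
    if (normalize) v <- v / L
    stats::setNames(v, c(paste0(cols[[j]], "_top", seq_len(n_seg)),
                         paste0(cols[[j]], "_bot", seq_len(n_seg))))
  })
  unlist(out)
}
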