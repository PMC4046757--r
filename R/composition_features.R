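#' Semi-composition: per-column sums of a profile matrix
#'
#' Sums each column of the L x m profile matrix: component j is
#' `sum_i M[i, j]`.  Applied to a normalized PSSM (m = 20) this is the
#' PSSM-AAC group; applied to a secondary-structure probability matrix
#' (m = 3) it is the SPINE-SSEC group.
#'
#' Unlike classical composition there is **no division by L**: the sums
#' keep protein-length information, which is the point of the
#' "semi" variant.  The operation is linear in the matrix.
#'
#' @param m Numeric L x m matrix.
#' @return Named numeric vector of length m (column names of `m` if set).
#' @export
#' @examples
#' semi_composition(diag(3))
semi_composition <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 1)
  colSums(m)
}
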