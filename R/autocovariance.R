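# Lagged auto covariance over whole columns and cumulative-mass segments
# (PSSM-SAC, SPINE-SAC).

#' Lagged auto covariance of a series around a supplied mean
#'
#' Computes `(1 / (n - g)) * sum_{i=1}^{n-g} (x_i - mean)(x_{i+g} - mean)`.
#' The mean is supplied rather than recomputed because segment
#' coefficients deliberately use the whole-column mean, not the segment's
#' own.  Series no longer than the lag return 0 so feature dimensionality
#' never depends on the input.
#'
#' @param x Numeric vector (a column segment).
#' @param mean Centering value (the whole-column mean).
#' @param lag Positive integer lag g.
#' @return A single numeric coefficient.
#' @export
#' @examples
#' auto_covariance(c(1, 0, 1, 0), mean = 0.5, lag = 1)  # -0.25
auto_covariance <- function(x, mean, lag) {
  if (length(lag) != 1 || !is.finite(lag) || lag < 1 || lag != round(lag)) {
    rlang::abort("`lag` must be a positive integer")
  }
  n <- length(x)
  if (n <= lag) return(0)
  d <- x - mean
  sum(d[seq_len(n - lag)] * d[(lag + 1):n]) / (n - lag)
}

#' Segmented auto covariance features of a profile matrix
#'
#' For each column j of the L x m matrix: the column is segmented at the
#' 25% and 50% cumulative-mass breakpoints from both ends (fixed F = 25,
#' see [boundary_indices()]), giving four nested segments — rows
#' `1 ... I_1`, `1 ... I_2` from the top and the last `I'_1`, `I'_2` rows
#' from the bottom.  For each segment, auto covariance coefficients at
#' lags 1 ... K are computed around the **whole-column** mean, followed by
#' the global coefficients over all L rows at lags 1 ... K.  Per column
#' this yields `5K` features in the order seg1, seg2, seg3, seg4, global
#' (lags ascending within each); columns in fixed order, `m * 5K` total
#' (400 for a PSSM at K = 4, 60 for a structural matrix).
#'
#' Empty segments (boundary index 0) and segments no longer than the lag
#' contribute zeros, never errors.
#'
#' @param m Non-negative numeric L x m matrix (normalized profile).
#' @param K Distance factor: maximum lag, integer in 1 ... 10.
#' @return Named numeric vector of length `m * 5 * K`.
#' @export
segmented_auto_covariance <- function(m, K = 4) {
  if (length(K) != 1 || !is.finite(K) || K != round(K) || K < 1 || K > 10) {
    rlang::abort("distance factor K must be an integer in 1..10")
  }
  m <- as.matrix(m)
  L <- nrow(m)
  cols <- colnames(m)
  if (is.null(cols)) cols <- as.character(seq_len(ncol(m)))
  lags <- seq_len(K)
  out <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    mu <- mean(x)
    b <- boundary_indices(x, F = 25)
    segments <- list(
      x[seq_len(b$top[[1]])],
      x[seq_len(b$top[[2]])],
      if (b$bottom[[1]] > 0) x[(L - b$bottom[[1]] + 1):L] else numeric(0),
      if (b$bottom[[2]] > 0) x[(L - b$bottom[[2]] + 1):L] else numeric(0))
    v <- c(
      unlist(lapply(seq_along(segments), function(s) {
        vapply(lags, function(g) auto_covariance(segments[[s]], mu, g),
               numeric(1))
      })),
      vapply(lags, function(g) auto_covariance(x, mu, g), numeric(1)))
    stats::setNames(v, c(
      paste0(cols[[j]], "_seg", rep(1:4, each = K), "_lag", rep(lags, 4)),
      paste0(cols[[j]], "_global_lag", lags)))
  })
  unlist(out)
}
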