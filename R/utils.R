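#' Weighted median with linear interpolation
#'
#' The weighted median of values x with non-negative weights w: the value at
#' which the cumulative weight crosses half the total. When the half-total
#' falls exactly on a boundary between two values, `interpolate = TRUE`
#' (default) averages the two (linear interpolation on ties), while
#' `interpolate = FALSE` breaks the tie toward the lower value — the
#' deterministic convention used inside the weighted-median consensus.
#'
#' @param x Numeric values.
#' @param w Non-negative weights, same length.
#' @param interpolate Interpolate exact boundary ties (default TRUE).
#' @return The weighted median.
#' @export
weighted_median <- function(x, w = rep(1, length(x)), interpolate = TRUE) {
  stopifnot(length(x) == length(w))
  if (any(w < 0)) stop("weights must be >= 0")
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0L) return(NA_real_)
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w)
  half <- sum(w) / 2
  i <- which(cw >= half - 1e-12)[1]
  if (interpolate && abs(cw[i] - half) <= 1e-12 && i < length(x)) {
    return((x[i] + x[i + 1]) / 2)
  }
  x[i]
}

## all compositions of `total` into `k` positive parts (used by the WeMe
## proportion grid: total = 1/step units)
compositions <- function(total, k) {
  if (k == 1L) return(matrix(total, 1, 1))
  out <- list()
  for (first in seq_len(total - k + 1L)) {
    rest <- compositions(total - first, k - 1L)
    out[[first]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}
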